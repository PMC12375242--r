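#' Screening configuration
#'
#' Parameters of the trigger-window screen. Defaults encode the published
#' design rules: windows of 31-33 nt, GC content near 50% (bounds
#' \[0.45, 0.55\]; the worked-example sensor at 17/31 = 0.548 passes), no
#' GGGG or MMMM (M = A/U) motif on the synthesized sensor strand, and an
#' exact shared-15-mer off-target screen against a background transcriptome.
#' The fold ceiling flags (advisory `fold_ok`) sensors whose Nussinov maximum
#' pair count suggests appreciable secondary structure.
#'
#' @param window_lengths Integer set of window lengths.
#' @param gc_lo,gc_hi GC-fraction bounds (open interval (0,1), lo < hi).
#' @param motifs Forbidden motifs (see [find_forbidden_motifs()]).
#' @param fold_ceiling Advisory ceiling on sensor Nussinov pair count.
#' @param k Off-target k-mer length (>= 8).
#' @param exclude_ids Background record ids treated as the intended target.
#' @param motif_on Where motif filters apply: the synthesized `"sensor"`
#'   strand (default) or `"both"` strands.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(window_lengths = 31:33, gc_lo = 0.45, gc_hi = 0.55,
                          motifs = c("GGGG", "MMMM"), fold_ceiling = 6L,
                          k = 15L, exclude_ids = character(),
                          motif_on = c("sensor", "both")) {
  motif_on <- match.arg(motif_on)
  window_lengths <- sort(unique(as.integer(window_lengths)))
  k <- as.integer(k)
  if (!(gc_lo < gc_hi && gc_lo > 0 && gc_hi < 1))
    stop("GC bounds must satisfy 0 < lo < hi < 1", call. = FALSE)
  if (k < 8L) stop("off-target k must be >= 8", call. = FALSE)
  if (any(window_lengths < k))
    stop("window lengths must be >= off-target k", call. = FALSE)
  structure(list(window_lengths = window_lengths, gc_lo = gc_lo, gc_hi = gc_hi,
                 motifs = motifs, fold_ceiling = as.integer(fold_ceiling),
                 k = k, exclude_ids = exclude_ids, motif_on = motif_on),
            class = "screen_config")
}

#' Enumerate candidate trigger windows
#'
#' All windows of every configured length, in (start, length) lexicographic
#' order. For a trigger of length L and window length w there are L - w + 1
#' windows (none when L < w).
#'
#' @param trigger `rna_seq` or string.
#' @param cfg A [screen_config()].
#' @return Data frame with columns `source_id`, `start`, `length`,
#'   `window_seq`.
#' @export
enumerate_windows <- function(trigger, cfg = screen_config()) {
  tr <- as_rna_seq(trigger, id = "trigger", role = "trigger")
  L <- nchar(tr$seq)
  if (L < min(cfg$window_lengths))
    stop(sprintf("trigger '%s' (%d nt) is shorter than the smallest window length (%d)",
                 tr$id, L, min(cfg$window_lengths)), call. = FALSE)
  rows <- list()
  for (w in cfg$window_lengths) {
    if (L < w) next
    starts <- seq_len(L - w + 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      source_id = tr$id, start = starts, length = w,
      window_seq = substring(tr$seq, starts, starts + w - 1L),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Evaluate screening metrics for candidate windows
#'
#' Fills, per window: the derived sensor sequence (reverse complement of the
#' window), GC fraction of the window, forbidden-motif hits on the sensor
#' strand (or both strands with `motif_on = "both"`), the sensor's Nussinov
#' maximum pair count (`fold_score`), and — when a k-mer index is supplied —
#' the number of off-target background records (`offtarget_hits`, `NA` when
#' unscreened).
#'
#' @param windows Output of [enumerate_windows()].
#' @param cfg A [screen_config()].
#' @param index Optional [build_kmer_index()] result.
#' @return The input data frame with columns `sensor_seq`, `gc`,
#'   `motif_hits` (comma-separated `motif@start` tokens, `""` for none),
#'   `fold_score`, `fold_ok`, `offtarget_hits` appended.
#' @export
evaluate_windows <- function(windows, cfg = screen_config(), index = NULL) {
  stopifnot(is.data.frame(windows), nrow(windows) >= 1L)
  n <- nrow(windows)
  sensor_seq <- vapply(windows$window_seq, .rc_chr, character(1), USE.NAMES = FALSE)
  gc <- vapply(windows$window_seq, function(x) gc_fraction(rna_seq(x)), numeric(1),
               USE.NAMES = FALSE)
  motif_hits <- character(n)
  fold_score <- integer(n)
  for (i in seq_len(n)) {
    hits <- find_forbidden_motifs(sensor_seq[i], cfg$motifs)
    if (cfg$motif_on == "both") {
      wh <- find_forbidden_motifs(windows$window_seq[i], cfg$motifs)
      if (nrow(wh)) { wh$motif <- paste0(wh$motif, "(window)"); hits <- rbind(hits, wh) }
    }
    motif_hits[i] <- if (nrow(hits)) paste(sprintf("%s@%d", hits$motif, hits$start),
                                           collapse = ",") else ""
    fold_score[i] <- nussinov_fold(sensor_seq[i])$n_pairs
  }
  offtarget <- rep(NA_integer_, n)
  if (!is.null(index)) {
    for (i in seq_len(n))
      offtarget[i] <- count_offtarget_hits(sensor_seq[i], index,
                                           exclude_ids = cfg$exclude_ids)
  }
  windows$sensor_seq <- sensor_seq
  windows$gc <- gc
  windows$motif_hits <- motif_hits
  windows$fold_score <- fold_score
  windows$fold_ok <- fold_score <= cfg$fold_ceiling
  windows$offtarget_hits <- offtarget
  windows
}

#' Exact k-mer index over a background transcriptome
#'
#' Deterministic exhaustive index mapping every length-k subsequence of the
#' background records to its (record id, position) occurrences. This is the
#' offline, exact replacement for an alignment-based off-target search:
#' a candidate sensor sharing any exact k-mer with a background record is
#' flagged. Records shorter than k are skipped with a warning.
#'
#' @param background List of `rna_seq` (e.g. from [read_fasta()]).
#' @param k k-mer length.
#' @return A list of class `kmer_index`: `k`, `map` (named list of data
#'   frames with `id`, `pos`), `record_ids`.
#' @export
build_kmer_index <- function(background, k = 15L) {
  if (inherits(background, "rna_seq")) background <- list(background)
  if (length(background) == 0L) stop("background is empty", call. = FALSE)
  k <- as.integer(k)
  ids <- character(0); kmer <- character(0); pos <- integer(0)
  used_ids <- character(0)
  for (s in background) {
    s <- as_rna_seq(s, id = if (inherits(s, "rna_seq")) s$id else "background")
    L <- nchar(s$seq)
    if (L < k) {
      warning(sprintf("background record '%s' (%d nt) shorter than k = %d; skipped",
                      s$id, L, k), call. = FALSE)
      next
    }
    st <- seq_len(L - k + 1L)
    kmer <- c(kmer, substring(s$seq, st, st + k - 1L))
    ids <- c(ids, rep(s$id, length(st)))
    pos <- c(pos, st)
    used_ids <- c(used_ids, s$id)
  }
  if (length(kmer) == 0L)
    stop("no background record is at least k nt long", call. = FALSE)
  ord <- order(kmer, ids, pos)
  df <- data.frame(id = ids[ord], pos = pos[ord], stringsAsFactors = FALSE)
  map <- split(df, kmer[ord])
  structure(list(k = k, map = map, record_ids = used_ids), class = "kmer_index")
}

#' Count off-target background hits for a sensor
#'
#' Number of background records — excluding ids named as the intended target —
#' that share at least one exact k-mer with the sensor strand. Matching is
#' strand-agnostic, as in an alignment search over both strands: each sensor
#' k-mer is looked up both as-is and as its reverse complement, so the
#' transcript a sensor hybridizes (which carries the reverse complement of
#' the sensor) is found and must be named in `exclude_ids`. Per-record detail
#' is attached as attribute `per_record`.
#'
#' @param sensor `rna_seq` or string.
#' @param index A [build_kmer_index()] result.
#' @param exclude_ids Record ids not counted (the intended target transcript).
#' @return Integer count, with a `per_record` data-frame attribute
#'   (`id`, `n_kmers`).
#' @export
count_offtarget_hits <- function(sensor, index, exclude_ids = character()) {
  stopifnot(inherits(index, "kmer_index"))
  s <- as_rna_seq(sensor, id = "sensor")
  k <- index$k
  L <- nchar(s$seq)
  if (L < k)
    stop(sprintf("sensor (%d nt) is shorter than k = %d", L, k), call. = FALSE)
  st <- seq_len(L - k + 1L)
  fwd <- substring(s$seq, st, st + k - 1L)
  kmers <- unique(c(fwd, vapply(fwd, .rc_chr, character(1), USE.NAMES = FALSE)))
  hit_ids <- character(0)
  for (km in kmers) {
    occ <- index$map[[km]]
    if (!is.null(occ)) hit_ids <- c(hit_ids, occ$id)
  }
  hit_ids <- hit_ids[!(hit_ids %in% exclude_ids)]
  per <- as.data.frame(table(hit_ids), stringsAsFactors = FALSE)
  if (nrow(per)) names(per) <- c("id", "n_kmers") else
    per <- data.frame(id = character(0), n_kmers = integer(0))
  structure(length(unique(hit_ids)), per_record = per)
}

#' Rank evaluated windows
#'
#' Applies the hard filters — any forbidden-motif hit, GC outside the bounds,
#' or at least one off-target hit when the window was screened — and sorts
#' survivors by the rank score (|GC - 0.5| ascending, then fold score
#' ascending, then 5'-most start), a deterministic total order. An empty
#' survivor set is a legal result.
#'
#' @param windows Output of [evaluate_windows()].
#' @param cfg The [screen_config()] used.
#' @return The survivors, sorted, with a `rank` column (1 = best).
#' @export
rank_candidates <- function(windows, cfg = screen_config()) {
  stopifnot(is.data.frame(windows))
  pass <- windows$motif_hits == "" &
    windows$gc >= cfg$gc_lo & windows$gc <= cfg$gc_hi &
    (is.na(windows$offtarget_hits) | windows$offtarget_hits == 0L)
  surv <- windows[pass, , drop = FALSE]
  if (nrow(surv)) {
    ord <- order(abs(surv$gc - 0.5), surv$fold_score, surv$start, surv$length)
    surv <- surv[ord, , drop = FALSE]
    surv$rank <- seq_len(nrow(surv))
  } else {
    surv$rank <- integer(0)
  }
  rownames(surv) <- NULL
  surv
}

#' Full trigger screen
#'
#' Enumerates, evaluates and ranks windows in one call; returns the full
#' evaluated table with `pass` and `rank` columns (rank `NA` for excluded
#' windows), suitable for the TSV/JSON report writers.
#'
#' @param trigger `rna_seq` or string.
#' @param cfg A [screen_config()].
#' @param background Optional list of `rna_seq` for off-target screening.
#' @return Evaluated, annotated window table.
#' @export
screen_trigger <- function(trigger, cfg = screen_config(), background = NULL) {
  win <- enumerate_windows(trigger, cfg)
  index <- if (!is.null(background)) build_kmer_index(background, cfg$k) else NULL
  ev <- evaluate_windows(win, cfg, index)
  ranked <- rank_candidates(ev, cfg)
  ev$pass <- ev$motif_hits == "" & ev$gc >= cfg$gc_lo & ev$gc <= cfg$gc_hi &
    (is.na(ev$offtarget_hits) | ev$offtarget_hits == 0L)
  ev$rank <- NA_integer_
  if (nrow(ranked)) {
    key <- paste(ev$source_id, ev$start, ev$length)
    rkey <- paste(ranked$source_id, ranked$start, ranked$length)
    ev$rank[match(rkey, key)] <- ranked$rank
  }
  ev
}
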