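#' Seeded synthetic trigger transcript
#'
#' Generates a random RNA transcript at an exact GC target (the G+C count is
#' `round(gc * length)` before implanting, so composition is within rounding
#' of the target at any length), then places the requested implants verbatim.
#' Identical seed and arguments give identical output. Used to exercise the
#' screen without downloading any real transcript.
#'
#' @param length Transcript length (nt).
#' @param gc Target GC fraction.
#' @param implants List of `list(pos = , seq = )`: sequences placed verbatim
#'   at 1-based positions. Overlapping implants are rejected.
#' @param seed Integer seed; every call is self-seeded and restores the RNG
#'   state afterwards.
#' @param id Sequence id.
#' @return An `rna_seq` with role `trigger`.
#' @export
synth_transcript <- function(length, gc = 0.5, implants = list(), seed = 1L,
                             id = "synthetic_trigger") {
  stopifnot(length >= 1L, gc > 0, gc < 1)
  spans <- lapply(implants, function(im) {
    s <- as_rna_seq(im$seq)
    if (im$pos < 1L || im$pos + nchar(s$seq) - 1L > length)
      stop(sprintf("implant at position %d (length %d) exceeds transcript length %d",
                   im$pos, nchar(s$seq), length), call. = FALSE)
    as.integer(c(im$pos, im$pos + nchar(s$seq) - 1L))
  })
  if (length(spans) > 1L) {
    ord <- order(vapply(spans, `[`, integer(1), 1L))
    for (i in seq_along(ord)[-1L]) {
      if (spans[[ord[i]]][1] <= spans[[ord[i - 1L]]][2])
        stop("implants overlap", call. = FALSE)
    }
  }
  ch <- .with_seed(seed, {
    n_gc <- round(gc * length)
    pool <- c(sample(c("G", "C"), n_gc, replace = TRUE),
              sample(c("A", "U"), length - n_gc, replace = TRUE))
    sample(pool, length)
  })
  for (i in seq_along(implants)) {
    im <- implants[[i]]
    s <- as_rna_seq(im$seq)
    ch[im$pos:(im$pos + nchar(s$seq) - 1L)] <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  }
  rna_seq(paste(ch, collapse = ""), id = id, role = "trigger")
}

#' Seeded synthetic background transcriptome
#'
#' Generates decoy transcripts guaranteed, by rejection sampling, to share no
#' k-mer with a protected sequence (so a clean background produces zero
#' off-target hits by construction). Rejection sampling rather than
#' post-editing keeps base composition unbiased; generation fails loudly
#' after `max_attempts` resamples of any one decoy. An off-target can be
#' requested explicitly by implanting a subsequence of the protected
#' sequence into a chosen decoy.
#'
#' @param n Number of decoys.
#' @param lengths Decoy lengths, recycled to `n`.
#' @param gc Target GC fraction.
#' @param protected `rna_seq`/string whose k-mers decoys must avoid (NULL to
#'   skip the guarantee).
#' @param k k-mer length of the guarantee.
#' @param implant Optional `list(record = , pos = , seq = )` placed verbatim
#'   in one decoy after the k-mer-free sampling.
#' @param seed Integer seed.
#' @param max_attempts Resampling cap per decoy.
#' @return A named list of `rna_seq` with role `background`, ids `decoy_1`...
#' @export
synth_background <- function(n, lengths = 300L, gc = 0.5, protected = NULL,
                             k = 15L, implant = NULL, seed = 1L,
                             max_attempts = 1000L) {
  stopifnot(n >= 1L)
  lengths <- rep_len(as.integer(lengths), n)
  forbidden <- character(0)
  if (!is.null(protected)) {
    p <- as_rna_seq(protected)
    if (nchar(p$seq) >= k) {
      st <- seq_len(nchar(p$seq) - k + 1L)
      fwd <- substring(p$seq, st, st + k - 1L)
      # exclude both strands, matching the strand-agnostic off-target lookup
      forbidden <- unique(c(fwd, vapply(fwd, .rc_chr, character(1), USE.NAMES = FALSE)))
    }
  }
  out <- .with_seed(seed, {
    res <- vector("list", n)
    for (i in seq_len(n)) {
      L <- lengths[i]
      for (attempt in seq_len(max_attempts)) {
        n_gc <- round(gc * L)
        pool <- c(sample(c("G", "C"), n_gc, replace = TRUE),
                  sample(c("A", "U"), L - n_gc, replace = TRUE))
        ch <- sample(pool, L)
        seqc <- paste(ch, collapse = "")
        clean <- TRUE
        if (length(forbidden) && L >= k) {
          st <- seq_len(L - k + 1L)
          clean <- !any(substring(seqc, st, st + k - 1L) %in% forbidden)
        }
        if (clean) break
        if (attempt == max_attempts)
          stop(sprintf("could not sample a k-mer-free decoy of length %d in %d attempts",
                       L, max_attempts), call. = FALSE)
      }
      res[[i]] <- seqc
    }
    res
  })
  decoys <- lapply(seq_len(n), function(i)
    rna_seq(out[[i]], id = sprintf("decoy_%d", i), role = "background"))
  names(decoys) <- vapply(decoys, function(s) s$id, character(1))
  if (!is.null(implant)) {
    tgt <- decoys[[implant$record]]
    s <- as_rna_seq(implant$seq)
    if (implant$pos < 1L || implant$pos + nchar(s$seq) - 1L > nchar(tgt$seq))
      stop("background implant exceeds decoy length", call. = FALSE)
    ch <- strsplit(tgt$seq, "", fixed = TRUE)[[1]]
    ch[implant$pos:(implant$pos + nchar(s$seq) - 1L)] <- strsplit(s$seq, "", fixed = TRUE)[[1]]
    decoys[[implant$record]] <- rna_seq(paste(ch, collapse = ""), id = tgt$id,
                                        role = "background")
  }
  decoys
}

# run code with a local, restored RNG state so fixture generation is
# deterministic without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
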