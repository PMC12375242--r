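#' Build the sensor strand from a trigger window
#'
#' The sensor is the reverse complement of a selected trigger-mRNA window, so
#' it can hybridize the trigger. Its first `pair_len` bases (default 23) clamp
#' the core strand; everything 3' of that is the exposed single-stranded
#' toehold where the trigger initiates strand displacement. A 31-33 nt window
#' therefore yields an 8-10 nt toehold.
#'
#' @param window `rna_seq` or string: the trigger window (5'->3' on the mRNA).
#' @param pair_len Number of 5' sensor bases clamped by the core.
#' @return A list of class `sensor_strand`: `seq` (role sensor), `pair_len`,
#'   `toehold` (string), `toehold_range` (c(start, end)).
#' @export
build_sensor <- function(window, pair_len = 23L) {
  w <- as_rna_seq(window, id = "window", role = "trigger")
  n <- nchar(w$seq)
  if (n < pair_len + 1L)
    stop(sprintf(paste0("window of %d nt is too short: the first %d sensor bases pair the ",
                        "core, so at least %d nt are needed to leave a toehold"),
                 n, pair_len, pair_len + 1L), call. = FALSE)
  sensor <- reverse_complement(w)
  sensor$id <- "sensor"; sensor$role <- "sensor"
  structure(list(seq = sensor, pair_len = as.integer(pair_len),
                 toehold = substr(sensor$seq, pair_len + 1L, n),
                 toehold_range = c(pair_len + 1L, n)),
            class = "sensor_strand")
}

#' Build the guide strand of the Dicer substrate
#'
#' Extends a validated siRNA guide at its 5' end to a `pair_len`-base (default
#' 23) pairing region, making the central guide:core duplex a Dicer
#' substrate, followed by a 3' dinucleotide overhang (default UU). A
#' canonical 21-nt siRNA guide already carries its 2-nt 3' overhang (19
#' paired bases + UU), so the overhang is appended only when the input does
#' not already end with it; `includes_overhang` overrides the suffix-based
#' auto-detection. The required extension length is therefore
#' `pair_len + |overhang| - |sirna_guide|` when the overhang is included in
#' the input (a 21-nt UU-ended siRNA needs 4 bases) and
#' `pair_len - |sirna_guide|` otherwise.
#'
#' If `extension` is omitted it is auto-chosen from G/C to maximize
#' nearest-neighbor stability of the extended duplex (ties broken G before
#' C). A supplied extension is validated as GC-rich: at least 3 of 4 bases
#' G/C for the canonical 4-base extension (proportionally,
#' ceiling(3/4 * length), for other lengths).
#'
#' @param sirna_guide `rna_seq` or string; its paired portion must not exceed
#'   `pair_len`.
#' @param extension Optional 5' extension (see above for the required length).
#' @param overhang 3' overhang following the pairing region.
#' @param pair_len Length of the guide:core pairing region.
#' @param enforce_gc_rich Validate a supplied extension as GC-rich.
#' @param includes_overhang Does `sirna_guide` already end with its 3'
#'   overhang? Default `NULL` auto-detects by suffix.
#' @param table [nn_table()] used when auto-choosing the extension.
#' @return A list of class `guide_strand`: `seq` (role guide), `pair_len`,
#'   `extension`, `overhang`.
#' @examples
#' # 21-nt validated siRNA (19 bp + UU overhang) plus a GC-rich 5' extension
#' build_guide("UGUUGUUUGGCUUUUCCUGUU", extension = "CGAG")
#' @export
build_guide <- function(sirna_guide, extension = NULL, overhang = "UU",
                        pair_len = 23L, enforce_gc_rich = TRUE,
                        includes_overhang = NULL, table = nn_table()) {
  g <- as_rna_seq(sirna_guide, id = "sirna_guide", role = "guide")
  ov <- as_rna_seq(overhang, id = "overhang")
  ng <- nchar(g$seq)
  nov <- nchar(ov$seq)
  if (is.null(includes_overhang))
    includes_overhang <- nov > 0L && ng > nov &&
      substr(g$seq, ng - nov + 1L, ng) == ov$seq
  paired <- ng - if (includes_overhang) nov else 0L
  if (paired > pair_len)
    stop(sprintf("siRNA guide contributes %d paired nt, exceeding the %d-base pairing region",
                 paired, pair_len), call. = FALSE)
  need <- pair_len - paired
  if (is.null(extension)) {
    ext <- .auto_extension(substr(g$seq, 1L, paired), need, table)
  } else {
    e <- as_rna_seq(extension, id = "extension")
    if (nchar(e$seq) != need)
      stop(sprintf("extension must have length %d (pairing region %d minus %d paired guide bases), got %d",
                   need, pair_len, paired, nchar(e$seq)), call. = FALSE)
    if (enforce_gc_rich && need > 0L) {
      n_gc <- sum(strsplit(e$seq, "")[[1]] %in% c("G", "C"))
      min_gc <- ceiling(0.75 * need)
      if (n_gc < min_gc)
        stop(sprintf("extension '%s' is not GC-rich: %d of %d bases are G/C (need >= %d)",
                     e$seq, n_gc, need, min_gc), call. = FALSE)
    }
    ext <- e$seq
  }
  body <- if (includes_overhang) g$seq else paste0(g$seq, ov$seq)
  full <- rna_seq(paste0(ext, body), id = "guide", role = "guide")
  structure(list(seq = full, pair_len = as.integer(pair_len),
                 extension = ext, overhang = ov$seq),
            class = "guide_strand")
}

# choose a G/C extension minimizing duplex dG of the extended pairing region;
# exhaustive over {G,C}^need (need is small: canonically 2-4 bases),
# enumerated so that ties resolve with G before C position by position
.auto_extension <- function(guide_core, need, table) {
  if (need == 0L) return("")
  if (need > 12L)
    stop("auto-extension supports at most 12 bases; supply `extension` explicitly",
         call. = FALSE)
  alts <- c("G", "C")
  grid <- do.call(expand.grid, c(rep(list(alts), need),
                                 list(stringsAsFactors = FALSE)))
  # column 1 varies slowest so candidates come out in 5'->3' G-before-C order
  grid <- grid[do.call(order, as.list(grid)), , drop = FALSE]
  best <- NULL; best_dg <- Inf
  for (r in seq_len(nrow(grid))) {
    ext <- paste(unlist(grid[r, ]), collapse = "")
    cand <- paste0(ext, guide_core)
    dg <- duplex_dG(cand, .rc_chr(cand), table)
    if (dg < best_dg - 1e-9) { best_dg <- dg; best <- ext }
  }
  best
}

#' Build the core strand
#'
#' The core carries three segments, 5'->3': the reverse complement of the
#' sensor's 5' block (core 5' overhang), the reverse complement of the guide
#' pairing region (central, the Dicer substrate passenger), and the reverse
#' complement of the sensor's second block (core 3' overhang). For a
#' sensor-pairing region of P bases the split is floor(P/2) / ceiling(P/2)
#' (11/12 at the default P = 23), so the core is floor(P/2) + 23 + ceiling(P/2)
#' nt long.
#'
#' @param sensor A [build_sensor()] result.
#' @param guide A [build_guide()] result.
#' @return A list of class `core_strand`: `seq` (role core), `segments`
#'   (named ranges on the core), `split` (c(floor, ceiling)).
#' @export
build_core <- function(sensor, guide) {
  stopifnot(inherits(sensor, "sensor_strand"), inherits(guide, "guide_strand"))
  p <- sensor$pair_len
  lo <- p %/% 2L
  hi <- p - lo
  s <- sensor$seq$seq
  gp <- substr(guide$seq$seq, 1L, guide$pair_len)
  core <- paste0(.rc_chr(substr(s, 1L, lo)), .rc_chr(gp), .rc_chr(substr(s, lo + 1L, p)))
  nc <- nchar(core)
  seg <- list(overhang5 = c(1L, lo),
              central = c(lo + 1L, lo + guide$pair_len),
              overhang3 = c(lo + guide$pair_len + 1L, nc))
  structure(list(seq = rna_seq(core, id = "core", role = "core"),
                 segments = seg, split = c(lo, hi)),
            class = "core_strand")
}

#' Assemble and verify a conditional siRNA construct
#'
#' Checks, base by base, the three duplexes asserted by the design geometry:
#' core 5' overhang with sensor positions 1..floor(P/2); core central segment
#' with guide positions 1..23; core 3' overhang with sensor positions
#' floor(P/2)+1..P. All duplexes are antiparallel Watson-Crick. Any mismatch
#' is an error reporting the first offending position pair.
#'
#' Strands may be given as builder objects or as bare sequences
#' (`rna_seq`/string), in which case the default geometry (P = 23, guide
#' pairing region 23) is assumed and re-verified.
#'
#' @param guide,sensor,core The three strands.
#' @param pair_len Sensor-core pairing region when bare sequences are given.
#' @param guide_pair_len Guide-core pairing region when bare sequences are given.
#' @return A list of class `cond_sirna`: the three strand objects, `pairing`
#'   (data frame of duplex records), `pair_len`, `split`, and `stats`.
#' @export
assemble_construct <- function(guide, sensor, core, pair_len = 23L,
                               guide_pair_len = 23L) {
  if (!inherits(sensor, "sensor_strand")) {
    s <- as_rna_seq(sensor, id = "sensor", role = "sensor")
    sensor <- build_sensor(reverse_complement(s), pair_len = pair_len)
  }
  if (!inherits(guide, "guide_strand")) {
    g <- as_rna_seq(guide, id = "guide", role = "guide")
    if (nchar(g$seq) < guide_pair_len)
      stop("guide shorter than its pairing region", call. = FALSE)
    guide <- structure(list(seq = rna_seq(g$seq, id = "guide", role = "guide"),
                            pair_len = as.integer(guide_pair_len),
                            extension = NA_character_,
                            overhang = substr(g$seq, guide_pair_len + 1L, nchar(g$seq))),
                       class = "guide_strand")
  }
  if (!inherits(core, "core_strand")) {
    k <- as_rna_seq(core, id = "core", role = "core")
    p <- sensor$pair_len; lo <- p %/% 2L
    nc <- nchar(k$seq)
    seg <- list(overhang5 = c(1L, lo),
                central = c(lo + 1L, lo + guide$pair_len),
                overhang3 = c(lo + guide$pair_len + 1L, nc))
    core <- structure(list(seq = rna_seq(k$seq, id = "core", role = "core"),
                           segments = seg, split = c(lo, p - lo)),
                      class = "core_strand")
  }
  p <- sensor$pair_len
  lo <- core$split[1]
  exp_len <- lo + guide$pair_len + (p - lo)
  if (nchar(core$seq$seq) != exp_len)
    stop(sprintf("core length %d does not match geometry floor(P/2)+%d+ceiling(P/2) = %d",
                 nchar(core$seq$seq), guide$pair_len, exp_len), call. = FALSE)

  duplexes <- data.frame(
    a = "core",
    a_start = c(core$segments$overhang5[1], core$segments$central[1], core$segments$overhang3[1]),
    a_end   = c(core$segments$overhang5[2], core$segments$central[2], core$segments$overhang3[2]),
    b = c("sensor", "guide", "sensor"),
    b_start = c(1L, 1L, lo + 1L),
    b_end   = c(lo, guide$pair_len, p),
    name = c("clamp5", "dicer", "clamp3"),
    stringsAsFactors = FALSE)

  strands <- list(core = core$seq$seq, sensor = sensor$seq$seq, guide = guide$seq$seq)
  for (r in seq_len(nrow(duplexes))) {
    d <- duplexes[r, ]
    .check_duplex(strands[[d$a]], d$a_start, d$a_end,
                  strands[[d$b]], d$b_start, d$b_end, d$a, d$b)
  }
  .check_pairing_disjoint(duplexes)

  stats <- list(
    duplex_lengths = stats::setNames(duplexes$a_end - duplexes$a_start + 1L, duplexes$name),
    toehold = sensor$toehold,
    toehold_length = nchar(sensor$toehold),
    guide_overhang = guide$overhang,
    sensor_paired_bases = p,
    nick_after_core_pos = core$segments$central[2])  # nick between central and 3' overhang

  structure(list(guide = guide, sensor = sensor, core = core,
                 pairing = duplexes, pair_len = p, split = core$split,
                 stats = stats),
            class = "cond_sirna")
}

# verify that a[a1..a2] and b[b1..b2] form a perfect antiparallel WC duplex:
# a[a1 + i] pairs b[b2 - i]
.check_duplex <- function(a, a1, a2, b, b1, b2, aname, bname) {
  la <- a2 - a1 + 1L; lb <- b2 - b1 + 1L
  if (la != lb)
    stop(sprintf("duplex ranges differ in length: %s[%d..%d] vs %s[%d..%d]",
                 aname, a1, a2, bname, b1, b2), call. = FALSE)
  for (i in seq_len(la) - 1L) {
    x <- substr(a, a1 + i, a1 + i)
    y <- substr(b, b2 - i, b2 - i)
    if (.complement_base[[x]] != y)
      stop(sprintf("pairing mismatch: %s position %d (%s) does not pair %s position %d (%s)",
                   aname, a1 + i, x, bname, b2 - i, y), call. = FALSE)
  }
  invisible(TRUE)
}

.check_pairing_disjoint <- function(duplexes) {
  claimed <- list()
  for (r in seq_len(nrow(duplexes))) {
    d <- duplexes[r, ]
    for (side in c("a", "b")) {
      st <- d[[paste0(side, "_start")]]; en <- d[[paste0(side, "_end")]]
      key <- d[[side]]
      pos <- st:en
      prev <- claimed[[key]]
      if (any(pos %in% prev))
        stop(sprintf("position %d of %s claimed by two duplexes",
                     intersect(pos, prev)[1], key), call. = FALSE)
      claimed[[key]] <- c(prev, pos)
    }
  }
  invisible(TRUE)
}

#' @export
print.cond_sirna <- function(x, ...) {
  cat("<cond_sirna construct>\n")
  cat(sprintf("  guide  5'-%s-3' (%d nt)\n", x$guide$seq$seq, nchar(x$guide$seq$seq)))
  cat(sprintf("  sensor 5'-%s-3' (%d nt)\n", x$sensor$seq$seq, nchar(x$sensor$seq$seq)))
  cat(sprintf("  core   5'-%s-3' (%d nt)\n", x$core$seq$seq, nchar(x$core$seq$seq)))
  cat(sprintf("  duplexes %s bp | toehold %s (%d nt) | guide overhang %s\n",
              paste(x$stats$duplex_lengths, collapse = "/"),
              x$stats$toehold, x$stats$toehold_length, x$stats$guide_overhang))
  invisible(x)
}

#' Verification report for an assembled construct
#'
#' Re-derives every duplex with its length and nearest-neighbor Delta-G,
#' lists unpaired regions (toehold, guide 3' overhang) and the nick between
#' the core's central and 3' segments (the putative "middle toehold" locus),
#' and evaluates pass/fail geometry expectations: a 23-bp central Dicer
#' duplex and full pairing of the first `pair_len` sensor bases. Failed
#' advisory expectations (e.g. a non-UU guide overhang) are warnings, not
#' errors.
#'
#' @param construct A [cond_sirna] object.
#' @param table An [nn_table()].
#' @return A list of class `assembly_report` with `duplexes` (data frame with
#'   dG), `unpaired`, `nick_after_core_pos`, `checks` (named logical),
#'   `warnings`, `pass`.
#' @export
verify_assembly <- function(construct, table = nn_table()) {
  stopifnot(inherits(construct, "cond_sirna"))
  strands <- list(core = construct$core$seq$seq,
                  sensor = construct$sensor$seq$seq,
                  guide = construct$guide$seq$seq)
  dup <- construct$pairing
  dup$length <- dup$a_end - dup$a_start + 1L
  dup$dG37 <- vapply(seq_len(nrow(dup)), function(r) {
    a <- substr(strands[[dup$a[r]]], dup$a_start[r], dup$a_end[r])
    b <- substr(strands[[dup$b[r]]], dup$b_start[r], dup$b_end[r])
    duplex_dG(a, b, table)
  }, numeric(1))
  p <- construct$pair_len
  checks <- c(
    dicer_duplex_23bp = unname(construct$stats$duplex_lengths["dicer"]) == 23L,
    sensor_first_p_paired = sum(construct$stats$duplex_lengths[c("clamp5", "clamp3")]) == p,
    toehold_present = construct$stats$toehold_length >= 1L)
  warnings <- character(0)
  if (!identical(construct$stats$guide_overhang, "UU"))
    warnings <- c(warnings, sprintf("guide 3' overhang is '%s', not the conventional UU",
                                    construct$stats$guide_overhang))
  unpaired <- list(
    sensor_toehold = construct$sensor$toehold_range,
    guide_overhang = c(construct$guide$pair_len + 1L, nchar(strands$guide)))
  structure(list(duplexes = dup, unpaired = unpaired,
                 nick_after_core_pos = construct$stats$nick_after_core_pos,
                 checks = checks, warnings = warnings, pass = all(checks)),
            class = "assembly_report")
}

#' @export
print.assembly_report <- function(x, ...) {
  cat(sprintf("<assembly_report> %s\n", if (x$pass) "PASS" else "FAIL"))
  for (r in seq_len(nrow(x$duplexes)))
    cat(sprintf("  %-6s %s[%d..%d]:%s[%d..%d]  %2d bp  dG37 %7.2f kcal/mol\n",
                x$duplexes$name[r], x$duplexes$a[r], x$duplexes$a_start[r],
                x$duplexes$a_end[r], x$duplexes$b[r], x$duplexes$b_start[r],
                x$duplexes$b_end[r], x$duplexes$length[r], x$duplexes$dG37[r]))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}
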