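#' Nearest-neighbor RNA duplex parameters (37 degrees C)
#'
#' Loads the shipped RNA/RNA nearest-neighbor parameter table (Xia et al.
#' 1998, Turner-lab unified Delta-G37 values, kcal/mol): one stacking term per
#' Watson-Crick dinucleotide step, a duplex initiation term, and a per-end
#' terminal A-U penalty. The table ships as a versioned plain-text asset;
#' [duplex_dG()] sums over it.
#'
#' @param path Path to the parameter TSV; defaults to the packaged asset.
#' @return A list of class `nn_table`: `stack` (named numeric, 16 steps),
#'   `init`, `term_au`, `source`, `version`, `temperature_C`.
#' @export
nn_table <- function(path = system.file("extdata", "nn_rna_dG37.tsv",
                                        package = "condsirna")) {
  if (!nzchar(path) || !file.exists(path))
    stop("nearest-neighbor parameter table not found", call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$dG37, tab$step)
  steps <- setdiff(names(vals), c("init", "term_AU"))
  # all 16 dinucleotide steps can occur on the top strand of a WC duplex
  wc <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  missing <- setdiff(wc, steps)
  if (length(missing))
    stop(sprintf("parameter table is missing stack step(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(vals))) stop("non-finite value in parameter table", call. = FALSE)
  src <- sub("^#\\s*source:\\s*", "", grep("^#\\s*source:", hdr, value = TRUE)[1])
  ver <- sub("^#\\s*version:\\s*", "", grep("^#\\s*version:", hdr, value = TRUE)[1])
  structure(list(stack = vals[steps], init = unname(vals[["init"]]),
                 term_au = unname(vals[["term_AU"]]),
                 source = src, version = ver, temperature_C = 37),
            class = "nn_table")
}

#' Free energy of a perfect RNA duplex
#'
#' Nearest-neighbor Delta-G37 of the duplex formed by `a` and `b`, which must
#' be exact reverse complements (all designed duplexes in a conditional siRNA
#' construct are perfect by construction). The value is
#' `init + sum(stacks along a, 5'->3') + term_AU * (number of terminal A-U pairs)`.
#'
#' @param a,b `rna_seq` (or strings); `b` must equal `reverse_complement(a)`.
#' @param table An [nn_table()].
#' @return Delta-G37 in kcal/mol (negative = stable).
#' @export
duplex_dG <- function(a, b, table = nn_table()) {
  a <- as_rna_seq(a); b <- as_rna_seq(b)
  n <- nchar(a$seq)
  if (n < 2L) stop("duplex must be at least 2 bp (no stack defined)", call. = FALSE)
  rc <- .rc_chr(a$seq)
  if (!identical(rc, b$seq)) {
    if (nchar(b$seq) != n)
      stop(sprintf("duplex strands differ in length (%d vs %d)", n, nchar(b$seq)),
           call. = FALSE)
    bm <- strsplit(b$seq, "")[[1]] != strsplit(rc, "")[[1]]
    j <- which(bm)[1]            # position on b; pairs position n - j + 1 on a
    stop(sprintf(
      "strands are not reverse complements: first mismatch at %s position %d (pairs %s position %d)",
      b$id, j, a$id, n - j + 1L), call. = FALSE)
  }
  ch <- strsplit(a$seq, "", fixed = TRUE)[[1]]
  steps <- paste0(ch[-n], ch[-1])
  dg <- table$init + sum(table$stack[steps])
  n_term_au <- sum(ch[c(1L, n)] %in% c("A", "U"))
  dg + table$term_au * n_term_au
}

#' Maximum base-pair secondary structure (Nussinov)
#'
#' Dynamic-programming maximization of nested Watson-Crick base pairs
#' (optionally with G-U wobble) with a minimum hairpin-loop length, plus one
#' optimal structure recovered by a deterministic traceback that prefers
#' pairing the 3' base with its 5'-most admissible partner. This is the
#' secondary-structure screen used on candidate sensors: a strand is "minimal
#' structure" when its maximum pair count is low.
#'
#' @param s `rna_seq` or string.
#' @param min_loop Minimum number of unpaired bases in a hairpin loop.
#' @param wobble Allow G-U pairs.
#' @return A list of class `fold_result`: `id`, `n_pairs`, `structure`
#'   (dot-bracket), `min_loop`.
#' @examples
#' nussinov_fold("GGGAAACCC")  # 3 pairs, "(((...)))"
#' @export
nussinov_fold <- function(s, min_loop = 3L, wobble = FALSE) {
  s <- as_rna_seq(s)
  min_loop <- as.integer(min_loop)
  if (min_loop < 1L) stop("min_loop must be >= 1", call. = FALSE)
  n <- nchar(s$seq)
  ch <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  # pairable[i, j]: can residues i and j form a pair
  pairs_ok <- c("AU", "UA", "CG", "GC", if (wobble) c("GU", "UG"))
  pairable <- if (n >= 1L)
    matrix(outer(ch, ch, paste0) %in% pairs_ok, n, n) else matrix(FALSE, 1, 1)
  canp <- function(i, j) pairable[i, j]
  M <- matrix(0L, nrow = max(n, 1L), ncol = max(n, 1L))
  if (n >= 2L) {
    for (span in seq_len(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- M[i, j - 1L]                       # j unpaired
        if (span > min_loop) {
          ks <- i:(j - min_loop - 1L)              # candidate partners for j
          ks <- ks[pairable[ks, j]]
          if (length(ks)) {
            v <- 1L + M[cbind(ks + 1L, j - 1L)]
            inner <- ks > i
            v[inner] <- v[inner] + M[cbind(i, ks[inner] - 1L)]
            best <- max(best, v)
          }
        }
        M[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  if (n >= 2L) {
    # traceback; when pairing j ties with leaving j unpaired, pair it, with
    # the 5'-most partner k among those achieving the optimum
    stack <- list(c(1L, n))
    while (length(stack)) {
      ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      i <- ij[1]; j <- ij[2]
      if (i >= j) next
      target <- M[i, j]
      paired <- FALSE
      if (j - i > min_loop) {
        for (k in i:(j - min_loop - 1L)) {
          if (canp(k, j)) {
            v <- 1L + M[k + 1L, j - 1L] + if (k > i) M[i, k - 1L] else 0L
            if (v == target) {
              db[k] <- "("; db[j] <- ")"
              if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
              stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
              paired <- TRUE
              break
            }
          }
        }
      }
      if (!paired) stack[[length(stack) + 1L]] <- c(i, j - 1L)
    }
  }
  structure(list(id = s$id, n_pairs = if (n >= 2L) M[1L, n] else 0L,
                 structure = paste(db, collapse = ""), min_loop = as.integer(min_loop)),
            class = "fold_result")
}

.can_pair <- function(x, y, wobble = FALSE) {
  p <- paste0(x, y)
  p %in% c("AU", "UA", "CG", "GC") || (wobble && p %in% c("GU", "UG"))
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("<fold_result> %s: %d pairs (min loop %d)\n  %s\n",
              x$id, x$n_pairs, x$min_loop, x$structure))
  invisible(x)
}

#' Net strand-displacement favorability
#'
#' Quantifies whether the trigger can displace the sensor from the core:
#' Delta-Delta-G = Delta-G(trigger:sensor full duplex) minus the sum of the
#' Delta-G of the two sensor:core clamp duplexes (core 5' overhang and core 3'
#' overhang). A negative net value means displacement is thermodynamically
#' favorable (the full-length trigger:sensor duplex outweighs the clamps).
#'
#' @param construct A [cond_sirna] construct.
#' @param trigger_window `rna_seq`: the trigger window the sensor was designed
#'   against; must be the exact reverse complement of the sensor.
#' @param table An [nn_table()].
#' @return A list of class `displacement_score` with components
#'   `dG_trigger_sensor`, `dG_clamp5`, `dG_clamp3`, `net_ddG`.
#' @export
displacement_ddG <- function(construct, trigger_window, table = nn_table()) {
  stopifnot(inherits(construct, "cond_sirna"))
  w <- as_rna_seq(trigger_window)
  sensor <- construct$sensor$seq
  if (!identical(.rc_chr(sensor$seq), w$seq))
    stop("trigger window is not the reverse complement of the construct's sensor",
         call. = FALSE)
  p <- construct$pair_len
  lo <- construct$split[1]
  dG_ts <- duplex_dG(sensor, w, table)
  s5 <- subseq_rna(sensor, 1L, lo)
  s3 <- subseq_rna(sensor, lo + 1L, p)
  dG5 <- duplex_dG(s5, reverse_complement(s5), table)
  dG3 <- duplex_dG(s3, reverse_complement(s3), table)
  structure(list(dG_trigger_sensor = dG_ts, dG_clamp5 = dG5, dG_clamp3 = dG3,
                 net_ddG = dG_ts - (dG5 + dG3)),
            class = "displacement_score")
}

#' @export
print.displacement_score <- function(x, ...) {
  cat(sprintf(paste0("<displacement_score>\n  dG trigger:sensor  %8.2f kcal/mol\n",
                     "  dG clamp 5'        %8.2f kcal/mol\n",
                     "  dG clamp 3'        %8.2f kcal/mol\n",
                     "  net ddG            %8.2f kcal/mol (%s)\n"),
              x$dG_trigger_sensor, x$dG_clamp5, x$dG_clamp3, x$net_ddG,
              if (x$net_ddG < 0) "displacement favorable" else "displacement unfavorable"))
  invisible(x)
}

#' Optional cross-check against an external folding tool
#'
#' When the ViennaRNA `RNAfold` executable is on the PATH, folds `s` with it
#' and returns the minimum-free-energy structure and energy. This is a
#' comparison hook only: the package's own screen uses [nussinov_fold()]
#' (maximum base pairs), which answers a different question than MFE folding,
#' so the two are expected to agree qualitatively (a strand with few possible
#' pairs has weak MFE structure), not numerically.
#'
#' @param s `rna_seq` or string.
#' @return A list with `structure` (dot-bracket) and `mfe_kcal`, or `NULL`
#'   (with a message) when `RNAfold` is not installed.
#' @export
rnafold_crosscheck <- function(s) {
  s <- as_rna_seq(s)
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    message("RNAfold not found on PATH; skipping external cross-check")
    return(NULL)
  }
  out <- system2(exe, c("--noPS"), input = s$seq, stdout = TRUE)
  line <- out[2]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1]]
  if (length(m) != 3) stop("could not parse RNAfold output", call. = FALSE)
  list(structure = m[2], mfe_kcal = as.numeric(m[3]))
}
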