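#' Nucleic sequence objects
#'
#' `rna_seq()` builds the package's basic sequence object: a named 5'->3'
#' RNA-alphabet sequence with a role tag. Input is normalized on ingest:
#' whitespace is stripped, letters are uppercased, and T is transcribed to U,
#' so DNA-alphabet input (e.g. a GenBank UTR) and the spaced notation used for
#' published oligo sequences are both accepted directly.
#'
#' Positions are 1-based and inclusive throughout the package, and every
#' sequence is written 5'->3'.
#'
#' @param x Character scalar with the sequence, or an existing `rna_seq`.
#' @param id Identifier string.
#' @param role One of `"trigger"`, `"sensor"`, `"guide"`, `"core"`,
#'   `"background"`, `"generic"`.
#' @return An object of class `rna_seq`: a list with elements `id`, `seq`
#'   (single uppercase ACGU string) and `role`.
#' @examples
#' rna_seq("CG AG UGUUGU UUGGC UU UUCCUG UU", id = "guide", role = "guide")
#' rna_seq("acgt")  # -> ACGU
#' @export
rna_seq <- function(x, id = "seq", role = "generic") {
  if (inherits(x, "rna_seq")) {
    x$id <- id
    x$role <- match.arg(role, .rna_roles)
    return(x)
  }
  role <- match.arg(role, .rna_roles)
  stopifnot(is.character(x), length(x) == 1L, !is.na(x))
  raw <- gsub("[[:space:]]", "", x)
  raw <- toupper(raw)
  raw <- chartr("T", "U", raw)
  bad <- regexpr("[^ACGU]", raw)
  if (bad > 0L) {
    stop(sprintf("invalid symbol '%s' at position %d of sequence '%s' (after normalization)",
                 substr(raw, bad, bad), bad, id), call. = FALSE)
  }
  structure(list(id = id, seq = raw, role = role), class = "rna_seq")
}

.rna_roles <- c("generic", "trigger", "sensor", "guide", "core", "background")

#' @export
print.rna_seq <- function(x, ...) {
  cat(sprintf("<rna_seq> %s [%s] %d nt\n", x$id, x$role, nchar(x$seq)))
  s <- x$seq
  if (nchar(s) > 70) s <- paste0(substr(s, 1, 67), "...")
  cat("  5'-", s, "-3'\n", sep = "")
  invisible(x)
}

#' @export
as.character.rna_seq <- function(x, ...) x$seq

#' @export
length.rna_seq <- function(x) nchar(x$seq)

#' Coerce to rna_seq
#'
#' Accepts either an `rna_seq` or a plain character scalar (normalized on the
#' fly). Used by design operations so users can pass bare strings.
#' @param x Sequence input.
#' @param id,role Passed to [rna_seq()] when `x` is a string.
#' @return An `rna_seq`.
#' @export
as_rna_seq <- function(x, id = "seq", role = "generic") {
  if (inherits(x, "rna_seq")) x else rna_seq(x, id = id, role = role)
}

#' Extract a subsequence (1-based, inclusive)
#'
#' @param s An `rna_seq`.
#' @param start,end 1-based inclusive bounds.
#' @return An `rna_seq` covering `[start, end]`.
#' @export
subseq_rna <- function(s, start, end) {
  s <- as_rna_seq(s)
  n <- nchar(s$seq)
  if (start < 1L || end > n || start > end + 1L)
    stop(sprintf("subsequence [%d,%d] out of range for '%s' (length %d)",
                 start, end, s$id, n), call. = FALSE)
  rna_seq(substr(s$seq, start, end), id = sprintf("%s[%d..%d]", s$id, start, end),
          role = s$role)
}

#' Reverse complement
#'
#' Watson-Crick complement (A<->U, C<->G) read 3'->5', returned 5'->3'.
#' An involution: applying it twice returns the input sequence.
#'
#' @param s An `rna_seq` or character scalar.
#' @return An `rna_seq` with the same role, id suffixed with `_rc`.
#' @examples
#' as.character(reverse_complement("CUUCACCACCU"))  # "AGGUGGUGAAG"
#' @export
reverse_complement <- function(s) {
  s <- as_rna_seq(s)
  rc <- .rc_chr(s$seq)
  structure(list(id = paste0(s$id, "_rc"), seq = rc, role = s$role),
            class = "rna_seq")
}

.rc_chr <- function(x) {
  if (nchar(x) == 0L) return(x)
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = ""))
}

.complement_base <- c(A = "U", C = "G", G = "C", U = "A")

#' GC fraction
#'
#' Fraction of G and C residues, the exact rational (#G + #C) / length.
#' Rejects empty sequences.
#'
#' @param s An `rna_seq` or character scalar.
#' @return Numeric in \[0, 1\].
#' @export
gc_fraction <- function(s) {
  s <- as_rna_seq(s)
  n <- nchar(s$seq)
  if (n < 1L) stop("gc_fraction is undefined for an empty sequence", call. = FALSE)
  ch <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  sum(ch == "G" | ch == "C") / n
}

#' Scan for forbidden sequence motifs
#'
#' Finds every occurrence (overlaps included) of each motif, reporting 1-based
#' start positions. Motifs are written in A/C/G/U plus the degenerate symbol
#' `M`, which matches A or U (a run of weak bases). The defaults are the two
#' liabilities screened against in sensor design: `GGGG` (G-quadruplex seed)
#' and `MMMM` (four consecutive A/U).
#'
#' @param s An `rna_seq` or character scalar.
#' @param motifs Character vector of motifs.
#' @return A data frame with columns `motif` and `start`; zero rows means the
#'   sequence passes.
#' @examples
#' find_forbidden_motifs("AGGGGA")          # GGGG at 2
#' find_forbidden_motifs("CAUAUC")          # MMMM at 2
#' @export
find_forbidden_motifs <- function(s, motifs = c("GGGG", "MMMM")) {
  s <- as_rna_seq(s)
  if (length(motifs) == 0L) stop("motif set must be non-empty", call. = FALSE)
  ch <- strsplit(s$seq, "", fixed = TRUE)[[1]]
  out <- list()
  for (m in motifs) {
    mc <- strsplit(toupper(m), "", fixed = TRUE)[[1]]
    if (!all(mc %in% c("A", "C", "G", "U", "M")))
      stop(sprintf("motif '%s' contains symbols outside A/C/G/U/M", m), call. = FALSE)
    w <- length(mc)
    n <- length(ch)
    if (n >= w) {
      starts <- integer(0)
      for (i in seq_len(n - w + 1L)) {
        seg <- ch[i:(i + w - 1L)]
        ok <- all(ifelse(mc == "M", seg %in% c("A", "U"), seg == mc))
        if (ok) starts <- c(starts, i)
      }
      if (length(starts))
        out[[length(out) + 1L]] <- data.frame(motif = m, start = starts)
    }
  }
  if (length(out) == 0L)
    return(data.frame(motif = character(0), start = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read and write FASTA
#'
#' `read_fasta()` reads a (possibly multi-record, wrapped or unwrapped) FASTA
#' file into a list of [rna_seq] objects, normalizing each record to the RNA
#' alphabet; record ids are the first whitespace-delimited token of the
#' header. `write_fasta()` writes a list of `rna_seq` back out. A write-read
#' round trip preserves ids and residues exactly.
#'
#' @param path File path.
#' @param role Role assigned to every record read.
#' @return `read_fasta()`: a named list of `rna_seq`.
#' @export
read_fasta <- function(path, role = "generic") {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop(sprintf("FASTA file has no records: %s", path), call. = FALSE)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop(sprintf("duplicate FASTA id '%s' in %s", dup[1], path), call. = FALSE)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- tryCatch(
      rna_seq(as.character(set[[i]]), id = ids[i], role = role),
      error = function(e) stop(sprintf("record '%s': %s", ids[i], conditionMessage(e)),
                               call. = FALSE))
  }
  names(out) <- ids
  out
}

#' @rdname read_fasta
#' @param seqs A list of `rna_seq` (or a single one).
#' @param width Line-wrap width on write.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (inherits(seqs, "rna_seq")) seqs <- list(seqs)
  stopifnot(length(seqs) >= 1L)
  ids <- vapply(seqs, function(s) s$id, character(1))
  set <- Biostrings::RNAStringSet(vapply(seqs, function(s) s$seq, character(1)))
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path, width = as.integer(width))
  invisible(path)
}
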