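# Worked-example strands (Nppa-sensor / Ppp3ca-guide conditional siRNA) and
# independent oracles used across the suite.

published_guide  <- "CGAGUGUUGUUUGGCUUUUCCUGUU"
published_sensor <- "CUUCACCACCUCUCAGUGGCAAUGCGACCAA"
published_core   <- "AGGUGGUGAAGCAGGAAAAGCCAAACAACACUCGAUUGCCACUGAG"
published_sirna  <- "UGUUGUUUGGCUUUUCCUGUU"   # validated 21-nt siRNA (19 bp + UU)
published_ext    <- "CGAG"

# string reverse complement, coded independently of the package
rc_str <- function(x) {
  if (nchar(x) == 0) return(x)
  chartr("ACGU", "UGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

published_window <- rc_str(published_sensor)  # trigger segment the sensor binds

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# --- folding oracle: explicit enumeration of every well-nested structure ---
# Structures are pair sets built by leftmost decomposition: base i is either
# unpaired or paired with some admissible j'. Returns the maximum pair count.
bf_structures <- function(chars, i, j, min_loop = 3) {
  if (i > j) return(list(integer(0)))
  out <- lapply(bf_structures(chars, i + 1, j, min_loop), identity)  # i unpaired
  if (j - i > min_loop) {
    for (jp in (i + min_loop + 1):j) {
      if (paste0(chars[i], chars[jp]) %in% c("AU", "UA", "GC", "CG")) {
        left <- bf_structures(chars, i + 1, jp - 1, min_loop)
        right <- bf_structures(chars, jp + 1, j, min_loop)
        for (l in left) for (r in right)
          out[[length(out) + 1]] <- c(i, l, r)  # record one pair per opening base
      }
    }
  }
  out
}

bf_max_pairs <- function(seq, min_loop = 3) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  if (n < 2) return(0L)
  max(vapply(bf_structures(chars, 1L, n, min_loop), length, integer(1)))
}

# --- thermodynamic oracle: direct hand-sum over the shipped parameter asset ---
nn_asset <- function() {
  path <- system.file("extdata", "nn_rna_dG37.tsv", package = "condsirna")
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
  setNames(tab$dG37, tab$step)
}

hand_sum_dG <- function(top) {
  vals <- nn_asset()
  ch <- strsplit(top, "")[[1]]
  n <- length(ch)
  total <- vals[["init"]]
  for (i in seq_len(n - 1)) total <- total + vals[[paste0(ch[i], ch[i + 1])]]
  if (ch[1] %in% c("A", "U")) total <- total + vals[["term_AU"]]
  if (ch[n] %in% c("A", "U")) total <- total + vals[["term_AU"]]
  total
}

# --- off-target oracle: naive substring scan over both strands ---
naive_offtarget <- function(sensor, background, k, exclude = character(0)) {
  st <- seq_len(nchar(sensor) - k + 1)
  fwd <- substring(sensor, st, st + k - 1)
  kmers <- unique(c(fwd, vapply(fwd, rc_str, character(1))))
  hits <- 0L
  for (rec in background) {
    if (rec$id %in% exclude) next
    if (any(vapply(kmers, function(km) grepl(km, rec$seq, fixed = TRUE), logical(1))))
      hits <- hits + 1L
  }
  hits
}

# assembled worked-example construct, used by several files
build_published_construct <- function() {
  sensor <- build_sensor(published_window)
  guide <- build_guide(published_sirna, extension = published_ext)
  core <- build_core(sensor, guide)
  assemble_construct(guide, sensor, core)
}
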