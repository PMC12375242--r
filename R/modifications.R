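#' Chemically modified strand
#'
#' A strand plus per-residue sugar chemistry (`ribo`, `2OMe` for 2'-O-methyl,
#' `LNA` for locked nucleic acid), per-linkage backbone chemistry (`PO`
#' phosphodiester, `PS` phosphorothioate; one linkage per adjacent residue
#' pair, so `length(backbone) == length(residues) - 1`), and terminal
#' conjugates (`none`, `cholesterol-TEG`, `fluorophore`). Modification never
#' alters the base sequence.
#'
#' @param seq `rna_seq` or string.
#' @param sugar Character vector, one of ribo/2OMe/LNA per residue.
#' @param backbone Character vector, one of PO/PS per linkage.
#' @param conj5,conj3 Terminal conjugates.
#' @return A list of class `modified_strand`.
#' @export
modified_strand <- function(seq, sugar = NULL, backbone = NULL,
                            conj5 = "none", conj3 = "none") {
  s <- as_rna_seq(seq)
  n <- nchar(s$seq)
  if (is.null(sugar)) sugar <- rep("ribo", n)
  if (is.null(backbone)) backbone <- rep("PO", max(n - 1L, 0L))
  if (length(sugar) != n)
    stop(sprintf("sugar vector length %d != residue count %d", length(sugar), n),
         call. = FALSE)
  if (length(backbone) != max(n - 1L, 0L))
    stop(sprintf("backbone vector length %d != linkage count %d",
                 length(backbone), max(n - 1L, 0L)), call. = FALSE)
  if (!all(sugar %in% c("ribo", "2OMe", "LNA")))
    stop("sugar values must be ribo/2OMe/LNA", call. = FALSE)
  if (!all(backbone %in% c("PO", "PS")))
    stop("backbone values must be PO/PS", call. = FALSE)
  conjs <- c("none", "cholesterol-TEG", "fluorophore")
  conj5 <- match.arg(conj5, conjs)
  conj3 <- match.arg(conj3, conjs)
  structure(list(seq = s, sugar = sugar, backbone = backbone,
                 conj5 = conj5, conj3 = conj3),
            class = "modified_strand")
}

#' @export
print.modified_strand <- function(x, ...) {
  cat(sprintf("<modified_strand> %s (%d nt)\n  %s\n",
              x$seq$id, nchar(x$seq$seq), serialize_notation(x)))
  invisible(x)
}

.conj_tags <- c("cholesterol-TEG" = "Chol-TEG", "fluorophore" = "Fluor")

#' Vendor-style modification notation
#'
#' `serialize_notation()` renders a modified strand as compact order text:
#' `m` before a residue marks 2'-O-methyl, `+` marks LNA, `*` after a residue
#' marks a phosphorothioate linkage to the next residue, and bracketed
#' terminal tags (`[5Chol-TEG]`, `[3Chol-TEG]`, `[5Fluor]`, `[3Fluor]`) mark
#' conjugates. `parse_notation()` inverts it; the round trip is lossless.
#'
#' @param m A [modified_strand()].
#' @return `serialize_notation()`: a character scalar.
#' @examples
#' m <- modified_strand("AC", sugar = c("2OMe", "LNA"), backbone = "PS")
#' serialize_notation(m)  # "mA*+C"
#' @export
serialize_notation <- function(m) {
  stopifnot(inherits(m, "modified_strand"))
  ch <- strsplit(m$seq$seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pre <- c(ribo = "", `2OMe` = "m", LNA = "+")[m$sugar]
  post <- if (n > 1L) c(ifelse(m$backbone == "PS", "*", ""), "") else rep("", n)
  body <- paste0(pre, ch, post, collapse = "")
  tag5 <- if (m$conj5 != "none") sprintf("[5%s]", .conj_tags[[m$conj5]]) else ""
  tag3 <- if (m$conj3 != "none") sprintf("[3%s]", .conj_tags[[m$conj3]]) else ""
  paste0(tag5, body, tag3)
}

#' @rdname serialize_notation
#' @param text Notation text.
#' @param id Identifier for the parsed strand.
#' @export
parse_notation <- function(text, id = "strand") {
  stopifnot(is.character(text), length(text) == 1L)
  rest <- text
  conj5 <- "none"; conj3 <- "none"
  m5 <- regmatches(rest, regexec("^\\[5([A-Za-z-]+)\\]", rest))[[1]]
  if (length(m5)) {
    conj5 <- .parse_conj(m5[2], text, 1L)
    rest <- substr(rest, nchar(m5[1]) + 1L, nchar(rest))
  }
  m3 <- regmatches(rest, regexec("\\[3([A-Za-z-]+)\\]$", rest))[[1]]
  if (length(m3)) {
    conj3 <- .parse_conj(m3[2], text, nchar(text) - nchar(m3[1]) + 1L)
    rest <- substr(rest, 1L, nchar(rest) - nchar(m3[1]))
  }
  bases <- character(0); sugar <- character(0); ps_after <- logical(0)
  pos <- 1L
  chars <- strsplit(rest, "", fixed = TRUE)[[1]]
  i <- 1L
  while (i <= length(chars)) {
    sug <- "ribo"
    if (chars[i] == "m") { sug <- "2OMe"; i <- i + 1L }
    else if (chars[i] == "+") { sug <- "LNA"; i <- i + 1L }
    if (i > length(chars) || !(chars[i] %in% c("A", "C", "G", "U")))
      stop(sprintf("malformed modification notation at position %d of '%s'", i, text),
           call. = FALSE)
    bases <- c(bases, chars[i]); sugar <- c(sugar, sug); i <- i + 1L
    if (i <= length(chars) && chars[i] == "*") {
      ps_after <- c(ps_after, TRUE); i <- i + 1L
    } else ps_after <- c(ps_after, FALSE)
  }
  n <- length(bases)
  if (n == 0L) stop("notation contains no residues", call. = FALSE)
  if (ps_after[n])
    stop("trailing '*' after the last residue (no linkage exists there)", call. = FALSE)
  modified_strand(rna_seq(paste(bases, collapse = ""), id = id),
                  sugar = sugar,
                  backbone = if (n > 1L) ifelse(ps_after[-n], "PS", "PO") else character(0),
                  conj5 = conj5, conj3 = conj3)
}

.parse_conj <- function(tag, text, at) {
  hit <- names(.conj_tags)[.conj_tags == tag]
  if (!length(hit))
    stop(sprintf("unknown conjugate tag '%s' at position %d of '%s'", tag, at, text),
         call. = FALSE)
  hit
}

#' Load a modification preset
#'
#' Presets are data, not code: YAML files mapping named regions of each strand
#' (e.g. sensor toehold, middle toehold, guide pairing region) to sugar,
#' backbone and conjugate assignments. Three presets ship with the package —
#' `firstG` (LNA-stabilized sensor toehold and middle toehold, sparse
#' terminal phosphorothioates), `secondG` (adds 2'-O-methyl across the guide
#' pairing region) and `cholConj` (adds a sensor 3' cholesterol-TEG
#' conjugate). Their exact positions are illustrative defaults intended to be
#' edited for a given synthesis order.
#'
#' @param name Preset name (`firstG`, `secondG`, `cholConj`) or a path to a
#'   preset YAML file.
#' @return A list of class `mod_preset`.
#' @export
load_preset <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "presets", paste0(name, ".yaml"), package = "condsirna")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("unknown preset '%s'", name), call. = FALSE)
  p <- yaml::read_yaml(path)
  if (is.null(p$name)) stop("preset file lacks a name", call. = FALSE)
  if (is.null(p$rules)) p$rules <- list()
  structure(p, class = "mod_preset")
}

# resolve a named region to 1-based residue positions on a strand of the construct
.resolve_region <- function(construct, strand, region) {
  n <- nchar(construct[[strand]]$seq$seq)
  p <- construct$pair_len
  gp <- construct$guide$pair_len
  lo <- construct$split[1]
  r <- switch(paste(strand, region, sep = ":"),
    "sensor:all" = c(1L, n),
    "sensor:pair_region" = c(1L, p),
    "sensor:toehold" = construct$sensor$toehold_range,
    "sensor:middle_toehold" = {
      if (is.null(construct$stats$nick_after_core_pos))
        stop("construct lacks a nick annotation; region 'middle_toehold' cannot be resolved",
             call. = FALSE)
      c(lo, lo + 1L)  # sensor bases flanking the jump between the core's two arms
    },
    "sensor:five_prime_end" = c(1L, 1L),
    "sensor:three_prime_end" = c(n, n),
    "guide:all" = c(1L, n),
    "guide:pair_region" = c(1L, gp),
    "guide:overhang" = c(gp + 1L, n),
    "guide:five_prime_end" = c(1L, 1L),
    "guide:three_prime_end" = c(n, n),
    "core:all" = c(1L, n),
    "core:overhang5" = construct$core$segments$overhang5,
    "core:central" = construct$core$segments$central,
    "core:overhang3" = construct$core$segments$overhang3,
    "core:five_prime_end" = c(1L, 1L),
    "core:three_prime_end" = c(n, n),
    stop(sprintf("region '%s' does not resolve on strand '%s'", region, strand),
         call. = FALSE))
  r[1]:r[2]
}

#' Apply a modification preset to a construct
#'
#' Resolves every rule of the preset on the construct's strands and returns
#' the three modified strands. Unmodified positions default to ribose sugar
#' and phosphodiester backbone. Deterministic and idempotent; the base
#' sequences are never altered.
#'
#' Rule fields: `strand` (guide/sensor/core), `chemistry` (`sugar`,
#' `backbone` or `conjugate`), `value`, and either `region` (a named region,
#' optionally narrowed by `sub`, region-relative indices where negatives
#' count from the region end) or absolute `positions`. Backbone rules address
#' linkage indices (linkage i joins residues i and i+1); a region-addressed
#' backbone rule covers the linkages internal to the region. Conjugate rules
#' use `terminal: five_prime|three_prime`.
#'
#' @param construct A [cond_sirna] object.
#' @param preset A [load_preset()] result (or preset name).
#' @return Named list (`guide`, `sensor`, `core`) of [modified_strand()].
#' @export
apply_preset <- function(construct, preset) {
  stopifnot(inherits(construct, "cond_sirna"))
  if (is.character(preset)) preset <- load_preset(preset)
  stopifnot(inherits(preset, "mod_preset"))
  out <- list()
  for (strand in c("guide", "sensor", "core")) {
    s <- construct[[strand]]$seq
    n <- nchar(s$seq)
    sugar <- rep("ribo", n)
    backbone <- rep("PO", max(n - 1L, 0L))
    conj5 <- "none"; conj3 <- "none"
    for (rule in preset$rules) {
      if (!identical(rule$strand, strand)) next
      if (identical(rule$chemistry, "conjugate")) {
        if (identical(rule$terminal, "five_prime")) conj5 <- rule$value
        else if (identical(rule$terminal, "three_prime")) conj3 <- rule$value
        else stop("conjugate rule needs terminal: five_prime or three_prime",
                  call. = FALSE)
        next
      }
      pos <- if (!is.null(rule$positions)) as.integer(rule$positions) else {
        reg <- .resolve_region(construct, strand, rule$region)
        if (!is.null(rule$sub)) {
          sub <- as.integer(rule$sub)
          sub <- ifelse(sub < 0L, length(reg) + 1L + sub, sub)
          if (any(sub < 1L | sub > length(reg)))
            stop(sprintf("sub-index out of range for region '%s' on %s",
                         rule$region, strand), call. = FALSE)
          reg[sub]
        } else reg
      }
      if (identical(rule$chemistry, "sugar")) {
        if (any(pos < 1L | pos > n))
          stop(sprintf("sugar rule position out of range on %s", strand), call. = FALSE)
        sugar[pos] <- rule$value
      } else if (identical(rule$chemistry, "backbone")) {
        # explicit positions address linkages directly; a region addresses its
        # internal linkages (one fewer than its residues)
        lk <- if (!is.null(rule$positions)) pos else pos[pos < max(pos)]
        if (any(lk < 1L | lk > n - 1L))
          stop(sprintf("backbone rule linkage out of range on %s", strand), call. = FALSE)
        backbone[lk] <- rule$value
      } else {
        stop(sprintf("unknown chemistry '%s' in preset rule", rule$chemistry),
             call. = FALSE)
      }
    }
    out[[strand]] <- modified_strand(s, sugar = sugar, backbone = backbone,
                                     conj5 = conj5, conj3 = conj3)
  }
  out
}

#' Advisory checks on a modified strand
#'
#' Returns warnings only; never blocks export. Flags conjugates on both
#' termini (unusual in an order) and fully phosphorothioated backbones on an
#' RNA strand destined for Dicer processing.
#'
#' @param m A [modified_strand()].
#' @return Character vector of warnings (empty when clean).
#' @export
validate_modified_strand <- function(m) {
  stopifnot(inherits(m, "modified_strand"))
  w <- character(0)
  if (m$conj5 != "none" && m$conj3 != "none")
    w <- c(w, "conjugates on both termini")
  if (length(m$backbone) > 0L && all(m$backbone == "PS"))
    w <- c(w, "fully phosphorothioate backbone")
  if (mean(m$sugar == "LNA") > 0.5)
    w <- c(w, "more than half of residues are LNA; duplex may be overstabilized")
  w
}
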