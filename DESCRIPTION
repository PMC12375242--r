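Package: condsirna
Title: Design Toolkit for Conditional siRNA Riboswitch Constructs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs three-strand conditional siRNA (Cond-siRNA) riboswitch
    constructs in which siRNA activity is gated by a trigger mRNA through
    toehold-mediated strand displacement. Screens trigger transcripts for
    31-33 nucleotide sensor windows by GC content, sequence-motif and
    secondary-structure criteria, excludes off-targets with an exact k-mer
    index over a background transcriptome, assembles the sensor, core and
    guide strands with verified duplex geometry, evaluates duplex free
    energies with a nearest-neighbor model and a Nussinov base-pair
    maximization fold, and annotates strands with chemical modifications
    (LNA, 2'-O-methyl, phosphorothioate, terminal conjugates) in a
    round-trippable notation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
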