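Package: aaremine
Title: Discovery Toolkit for Aminoacyl Radical Enzymes in the Glycyl Radical Enzyme Superfamily
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines glycyl radical enzyme (GRE) superfamily sequences for
    noncanonical homologs in which the catalytic glycine is replaced by
    alanine, serine or threonine (aminoacyl radical enzymes, AAREs).
    Provides fingerprint-motif scanning with catalytic-residue
    classification, conserved-cysteine and radical-SAM activase motif
    checks, gene-neighborhood adjacency rules, genetic-code codon-graph
    distances and mutational paths between catalytic residues,
    continuous-wave EPR powder-spectrum simulation with isotropic
    hyperfine structure and spin quantitation by double integration,
    neighbor-joining phylogenetics with bootstrap monophyly tests, and
    seeded synthetic-data generators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    ape,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
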