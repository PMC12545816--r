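Package: plantcns
Title: Discovery and Characterization of Conserved Non-Coding Sequences in
    Plant Gene Promoters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable, tested pipeline for finding and characterizing deeply
    conserved non-coding sequences (CNSs) upstream of gene-family homologs
    across a species panel. Extracts strand-normalized upstream regions from
    genomes and annotations under truncated/full promoter rules, discovers
    over-represented ungapped motifs with a zero-or-one-occurrence-per-sequence
    (ZOOPS) expectation-maximization model with Monte-Carlo E-values, rescans
    promoters with exact position-specific scoring matrix p-values and
    Benjamini-Hochberg q-values plus orientation and clade-prevalence filters,
    classifies promoter motif architecture (colinearity, co-occurrence, spacer
    distances), delineates CNS boundaries from progressive alignments of
    motif-anchored windows with identity-enrichment statistics, quantifies
    per-CNS chromatin-accessibility enrichment from per-cell-type coverage
    tracks, scans for canonical G-quadruplex patterns, and ships a synthetic
    family generator that plants CNS structure along a species tree so every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
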