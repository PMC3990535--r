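Package: cnvseg
Title: Array-CGH Copy Number Segmentation and Cohort Recurrence Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A pipeline for two-channel array comparative genomic
    hybridization (aCGH) copy-number analysis: q-spline between-channel
    normalization and LOESS spatial artifact correction, least-squares
    dynamic-programming segmentation of per-probe log2 ratios, threshold
    based five-way copy-number calling
    (amplification/gain/unchanged/loss/deletion), minimal-common-region
    recurrence analysis across tumor cohorts, interval-based gene and
    miRNA annotation with Circos track export, hypergeometric gene-set
    over-representation with kappa-similarity annotation clustering, and
    2^-dCt relative-quantification analysis of validation qPCR data.
    Includes a seeded synthetic-data generator emulating NimbleGen-style
    tiling arrays so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
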