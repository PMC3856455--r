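Package: ricecnv
Title: Copy Number Variant Discovery from Two-Channel Tiling Array CGH
Version: 1.0.0
Authors@R:
    person("ricecnv", "developers", email = "maintainer@example.com",
           role = c("aut", "cre"))
Description: A complete analysis pipeline for genome-wide copy number
    variant (CNV) discovery from two-channel tiling-array comparative
    genomic hybridization (aCGH) in selfing crop panels such as Asian
    cultivated rice. Simulates probe layouts and noisy two-channel scans
    with planted CNVs, corrects spatial artifacts by LOESS, normalizes
    dye bias by quantile-spline matching, segments log2 ratios by exact
    penalized least-squares change-point dynamic programming, calls
    losses and gains under a stringent filter cascade, consolidates
    calls across samples into copy-number-variable regions (CNVRs), and
    computes population-genetic summaries (Nei gene diversity, Fst,
    average-linkage clustering on uncentered correlation), gene and
    repeat annotation overlaps, and hypergeometric GO enrichment with
    Benjamini-Hochberg false-discovery-rate control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
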