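Package: c19mctools
Title: Palindromic p53-Box Landscapes, p53 Transcription-Competence
    Stratification, and Coverage-Gap Fusion Inference Around C19MC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the regulatory landscape of the chromosome 19
    microRNA cluster (C19MC) in hepatocellular carcinoma. Scans genomic windows
    for reverse-complement palindromic p53 response-element boxes (CDKN1A and
    GADD45 consensus sub-elements) and Sp1 zinc/nickel boxes and summarises
    them on a percent-coordinate landscape; stratifies expression cohorts into
    p53 transcription-competent (TC) versus transcription-incompetent (TI)
    groups from a 30-gene signature with nonparametric group comparison;
    screens ligand mRNAs for correlation with cluster miRNAs under a
    significance mask with hierarchical ordering; infers focal deletions from
    RNA-seq coverage gaps, assigns breakpoints to gene introns, decomposes
    fusion-junction amplicons into flank matches plus a non-templated linker,
    and computes expected PCR product sizes across the rearrangement. A
    synthetic-data generator with planted ground truth stands in for the
    original tumour-cohort and cell-line inputs so every stage is testable
    offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
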