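Package: methtriad
Title: Tri-Omics Integration of DNA Methylation, miRNA and mRNA Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for integrating whole-genome
    bisulfite methylation, small-RNA and mRNA expression data from a
    two-condition design, as used to study heat-shock-induced microspore
    embryogenesis. Summarises per-cytosine methylation by sequence context
    (CG/CHG/CHH), calls differentially methylated regions by sliding-window
    Fisher exact tests with coverage, level-difference and fold-change
    filters, computes regional and metagene methylation profiles, performs
    CPM-normalised t-test differential expression for miRNAs and threshold
    based calling for mRNAs, associates DMRs with gene sub-features and
    miRNA loci with methylated cytosines, classifies gene-DMR-miRNA triads
    by their negative-correlation pattern to nominate key genes, and tests
    gene sets for term over-representation. Ships a fully seeded synthetic
    data generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    edgeR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
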