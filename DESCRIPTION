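Package: vascpath
Title: Pathway Scores and Preranked Enrichment for Vascular Injury Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for bulk RNA-seq time courses of vascular
    injury (bypass grafting, transient ligation). Takes a gene-by-sample
    count matrix through median-of-ratios normalization and a negative
    binomial Wald test, computes a per-pathway activity score (mean log2
    fold change of a gene set normalized by its standard deviation) with
    top/bottom-decile significance calls, runs a from-scratch preranked
    gene set enrichment analysis on the signed -log10(p) gene ranking
    (weighted running-sum statistic, permutation null, NES, FDR), maps
    human gene symbols to mouse orthologs for MSigDB-style GMT catalogs,
    and quantifies qPCR data by the 2^-delta-delta-CT method. Includes a
    negative binomial simulator with planted transient-inflammation and
    persistent-suppression signals for validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    DESeq2,
    fgsea,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
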