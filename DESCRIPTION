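Package: mirlame
Title: Blood miRNA Biomarker Analysis for Cattle Lameness Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for small RNA-seq biomarker analysis of
    lameness phenotypes in feedlot cattle from a miRNA read-count matrix:
    reads-per-million normalization and expression calling, detection of
    phenotype- and time-point-specific miRNAs by group prevalence rules,
    negative-binomial Wald differential expression with Benjamini-Hochberg
    false discovery control, fuzzy C-means clustering of longitudinal
    expression profiles with up/none/down trend classification, per-marker
    ROC/AUC evaluation with predictiveness bands, and delta-delta-Ct
    relative quantification for qPCR concordance. A negative-binomial
    synthetic-data generator emulates the study's count structure with
    planted, fully recorded ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    e1071,
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
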