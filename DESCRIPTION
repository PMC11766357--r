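Package: evsmallrna
Title: Plasma Extracellular-Vesicle Small-RNA Biomarker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for discovering diagnostic small-RNA biomarkers
    in plasma extracellular vesicles. Starting from a feature-by-sample count
    matrix and sample metadata, the package performs correlation/PCA-based
    sample quality control against technical negative controls,
    negative-binomial differential-expression screening (unpaired Wald and
    paired exact Wilcoxon contrasts), per-feature ROC diagnostic profiling
    with confusion-matrix metrics and candidate filtering, exhaustive
    pairwise biomarker-panel evaluation with a linear support-vector machine
    under leave-one-out cross-validation plus SVM-RFE ranking, stability-based
    qPCR reference selection, and delta-delta-Ct relative quantification with
    exact nonparametric group tests. A seeded synthetic-data generator
    emulating the cohort structure supports calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2
Config/testthat/edition: 3
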