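Package: evlongevity
Title: Dual-Track Differential Analysis and Longevity Prediction from
    Plasma Extracellular Vesicle Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for label-free quantified plasma
    extracellular-vesicle (EV) peptide data from long-lived versus
    short-lived older adults. Peptides are stratified by detection
    status and analysed on two tracks: Wilcoxon rank-sum tests on the
    quantitative values of fully observed peptides and chi-squared
    tests on the group missing rates of partially observed peptides,
    each with Benjamini-Hochberg false discovery rate control. A
    penalized logistic model predicts longevity from three peptide
    encodings (continuous, missingness-as-binary, zero-imputed) with a
    stratified discovery/holdout split and cross-validated AUC.
    Differential peptides are mapped onto protein chain and
    anaphylatoxin annotations, and EV surface-marker percentages are
    compared between groups and correlated with peptide abundance. A
    synthetic cohort generator with an abundance-dependent (MNAR)
    detection mechanism and ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    BiocGenerics,
    IRanges,
    Biostrings,
    glmnet,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
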