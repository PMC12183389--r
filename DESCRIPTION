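Package: evsig
Title: Extracellular-Vesicle Proteome Biomarker Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discovery and evaluation of plasma extracellular-vesicle (EV)
    protein biomarker signatures from tandem-mass-tag proteomic intensity
    matrices. Implements group-wise presence filtering, volcano-style
    differential-expression selection, per-biomarker least-squares boosting
    with RMSE ranking, a hybrid convolutional-network/support-vector-machine
    four-class classifier, exhaustive logistic multi-marker panel search with
    ROC evaluation (AUC, DeLong confidence intervals, sensitivity at fixed
    specificity), and Kaplan-Meier/Cox survival analysis of score-defined
    risk groups. A seeded synthetic-cohort generator reproduces the
    statistical structure the pipeline assumes so every stage is testable
    without access to raw mass-spectrometry data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
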