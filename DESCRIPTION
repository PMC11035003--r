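Package: adctex
Title: First-Order Texture Analysis of ADC Maps for Chemotherapy Response
    Prediction in Rectal Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying non-responders to neoadjuvant chemotherapy
    in locally advanced rectal cancer from apparent diffusion coefficient
    (ADC) maps. Computes first-order texture features (mean, standard
    deviation, variance, skewness, excess kurtosis, histogram entropy) on
    masked regions of interest at pre- and post-treatment timepoints, filters
    features by inter-reader intraclass correlation, builds a random-forest
    texture model on Gini-selected features alongside a forward
    likelihood-ratio logistic model on manual ADC measurements, and compares
    models and subjective radiologist calls with ROC analysis, the DeLong
    test for correlated AUCs, and Cohen's kappa. Includes a synthetic cohort
    generator that realizes group-level feature statistics as pixel data by
    polynomial moment matching, so the entire pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    randomForest,
    glmnet,
    jsonlite,
    png,
    RNifti
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
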