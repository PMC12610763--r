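Package: riskoverlap
Title: Threshold-Based Overlap of Breast Cancer High-Risk Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Five-year absolute breast cancer risk from a parsimonious Gail
    model and from a polygenic risk score (PRS), projected against age-banded
    incidence and competing-mortality hazards. Tools to evaluate
    discrimination (AUC with DeLong intervals), association (odds ratios from
    logistic regression), age interaction, and calibration (model-based ROC
    curves with mean-calibration, ROC-equality and unified tests) in
    case-control data stratified by ancestry and age, and to quantify the
    overlap and case enrichment of high-risk classification by PRS, Gail and
    family history across absolute-risk thresholds. Includes a synthetic
    case-control cohort generator so every stage of the analysis is testable
    without access to consortium data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    vcfR
Config/testthat/edition: 3
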