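Package: petresponse
Title: Quantitative PET Therapy-Response Assessment with Metabolic
    Metrics and Two-Frame Factor Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the metabolic response of tumours to
    therapy from serial FDG-PET scans. Implements the six standard
    per-lesion metrics (SUVmax, SUVpeak, SUVmean, metabolic volume,
    total lesion glycolysis, standardized added metabolic activity)
    on top of a contrast-oriented adaptive-threshold segmentation,
    rigid block-matching registration of serial scans, a voxel-level
    parametric image of significant tumour change derived from
    two-frame factor analysis (SULTAN), responder/non-responder
    classification per lesion and per patient under PERCIST and
    ROC-optimized thresholds, and the associated diagnostic evaluation
    machinery (ROC/AUC, Youden index, confusion statistics, chi-squared
    association, paired AUC comparison). A synthetic phantom generator
    produces paired scans with known lesion responses, scanner blur,
    noise, and misalignment for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    pROC,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
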