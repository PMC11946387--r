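Package: ftvresponse
Title: Functional Tumor Volume Response Modeling for Neoadjuvant Breast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes functional tumor volume (FTV) from serial dynamic
    contrast-enhanced breast MRI using percent-enhancement and signal
    enhancement ratio thresholding inside a fixed volume of interest, fits
    HR/HER2 subtype-specific logistic regression models predicting pathologic
    complete response from FTV trajectories with cross-validated AUC-driven
    predictor selection, and selects predicted-probability thresholds under
    minimum positive-predictive-value constraints to drive per-patient
    early-surgery recommendations. Includes a synthetic-data module that
    generates DCE phantoms with known ground truth and cohort tables matching
    the I-SPY 2 neoadjuvant cohort's subtype and response structure, so the
    full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
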