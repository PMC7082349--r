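Package: epiradiomics
Title: 3D Radiomics Signature Pipeline for Glioma-Related Epilepsy Type
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end 3D radiomics pipeline for predicting the type
    (generalized versus focal) of epilepsy associated with low-grade glioma
    from a T2-like MRI volume and a tumor mask. Implements a 734-feature
    extraction engine (location features relative to the anterior commissure,
    first-order statistics, mesh-based shape features, GLCM/GLRLM/GLSZM/NGTDM
    texture matrices, and Coiflet-1 wavelet sub-band features), train-cohort
    feature screening (Pearson test and univariate AUC), a LASSO-logistic
    signature with leave-one-out lambda tuning, and an evaluation stage with
    DeLong AUC confidence intervals, Hosmer-Lemeshow calibration, decision
    curve analysis, an AIC-selected multivariable model and a nomogram.
    Ships a synthetic phantom cohort generator with a planted, calibrated
    feature-label effect so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
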