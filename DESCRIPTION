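Package: radsig
Title: CT Radiomic Signatures for Binary Survival Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and evaluates CT-radiomics prognostic signatures for a
    binary overall-survival endpoint. Provides image preprocessing (3D
    Gaussian denoising, isotropic cubic B-spline resampling), extraction of
    536 radiomic features (shape, first-order, grey-level co-occurrence and
    run-length texture, and undecimated 3D wavelet sub-bands), feature
    stability screening by intraclass correlation under region-of-interest
    translations, redundancy pruning by Spearman correlation, univariate AUC
    filtering, SMOTE class balancing, LASSO feature selection and a
    cubic-kernel support vector machine with ROC-based threshold selection,
    plus evaluation against clinical baseline classifiers with Wilson score
    intervals. Includes a synthetic-cohort generator with a planted survival
    signal so the whole pipeline can be exercised and validated without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    glmnet,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
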