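Package: aaostab
Title: Bootstrap Stability Selection for Age-at-Onset Prediction Models
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying psychosocial predictors of the age at onset
    of bipolar disorder with penalized regression. Provides a from-scratch
    coordinate-descent elastic-net/LASSO solver with cross-validated lambda
    selection, bootstrap stability selection with inclusion-frequency ranking
    and modal-coefficient reporting, held-out calibration evaluation (R
    squared, exponentiated mean absolute error, LOESS calibration curves),
    a synthetic mixed-type cohort generator with a Gaussian-copula correlation
    structure for fully reproducible testing, and a single-call pipeline that
    orchestrates preprocessing, selection and evaluation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
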