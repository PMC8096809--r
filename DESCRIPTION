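Package: oncorecur
Title: Weakly Supervised Prediction of Breast Cancer Recurrence from
    Clinical Note Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for predicting distant breast-cancer recurrence one year
    in advance from longitudinal streams of free-text clinical notes.
    Implements lexicon-normalised text preprocessing, skip-gram word
    embeddings with tf-idf-weighted note vectors, a stacked many-to-many
    LSTM sequence classifier trained under traditional and weak
    (NLP-derived, noisy-label) supervision strategies, a gradient-boosted
    single-note baseline, note-level ROC evaluation with patient-level
    bootstrap uncertainty, and a synthetic note-corpus generator so the
    whole pipeline can be exercised end-to-end without access to protected
    health data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    Matrix,
    xgboost,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
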