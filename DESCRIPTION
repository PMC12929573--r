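Package: docapen
Title: Diagnosis of Disorders of Consciousness from Approximate-Entropy EEG Topographies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for classifying vegetative
    state / unresponsive wakefulness syndrome (VS/UWS) versus minimally
    conscious state (MCS) from 16-channel resting-state and music-stimulation
    EEG. Channel-wise approximate entropy (ApEn) is computed with a sliding
    window, spatially interpolated into scalp topographies, tiled into RGB
    images and classified by a four-block convolutional network; linear SVM
    and generalized regression neural network (GRNN) baselines operate on
    ANOVA-screened electrode-condition mean-ApEn features. Includes a
    calibrated synthetic-cohort generator (MIX-family signals with CRS-R
    coupling), EDF input/output, and a full evaluation suite: confusion-matrix
    metrics with exact binomial confidence intervals, ROC/AUC, and DeLong
    tests for correlated AUCs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    e1071,
    jsonlite,
    png,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
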