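Package: accelhar
Title: Accelerometer-Based Recognition of Walking, Running and Jumping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying walking, running and jumping from raw
    triaxial accelerometer signals, aimed at activity-specific mechanical
    loading assessment in bone health research. Provides reading and windowing
    of raw 100 Hz acceleration recordings, a 54-feature extractor per 1 s
    window (time-domain statistics, FFT spectral features, cross-axis
    correlations and low-pass-filtered orientation angles), participant-level
    train/test splitting with leakage guards, grid-searched Random Forest,
    RBF Support Vector Machine and K-Nearest Neighbors classifiers under
    grouped 5-fold cross-validation, and a full evaluation suite (percent
    agreement, Cohen's Kappa, one-vs-all ROC-AUC, confusion matrices,
    permutation feature importance). A seeded synthetic signal simulator
    generates labeled walking/running/jumping recordings so the whole
    pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    lhs,
    ranger,
    e1071,
    caret,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
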