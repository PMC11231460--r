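Package: fnirsdx
Title: Feature-Based Classification of Resting-State fNIRS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discriminating clinical groups from multichannel
    resting-state functional near-infrared spectroscopy (fNIRS) recordings.
    Provides a synthetic two-class cohort simulator with physiological
    oscillations and motion artifacts, signal conditioning (modified
    Beer-Lambert conversion, channel quality pruning, simplified motion
    correction), a 792-dimensional temporal/spectral feature extractor,
    an ensemble of filter and embedded feature-ranking methods with a
    two-of-three top-percentile vote, wrapper and genetic-algorithm feature
    subset search driven by cross-validated classifier accuracy, and
    logistic-regression evaluation under stratified k-fold cross-validation
    with accuracy, precision, recall, F1 and AUC reporting.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    glmnet,
    signal,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
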