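Package: fibrocnn
Title: Staging Hepatic Fibrosis from Ultrasound Backscattered RF Signals with a 1-D CNN
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative-ultrasound pipeline for noninvasive staging of liver
    fibrosis (METAVIR F0-F4) from raw backscattered radiofrequency (RF)
    signals. Provides RF frame and cohort-manifest I/O, a scatterer-ensemble
    phantom simulator producing scanner-realistic synthetic frames with
    stage-dependent backscatter statistics, B-mode reconstruction and ROI
    extraction, min-max normalization with class-balancing sliding-window
    augmentation, a compact one-dimensional convolutional neural network
    (four convolutional, four max-pooling and four fully connected layers,
    Tanh activations) trained with Adam and cross-entropy, majority-vote
    frame-level prediction, and ACC/SEN/SPE/ROC/AUC evaluation with DeLong
    confidence intervals.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pROC,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
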