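Package: eegarousal
Title: Sleep-Arousal Detection from Single-Lead EEG with Stacking
    Ensemble Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects sleep-arousal events from a single-lead (C3-M2)
    electroencephalogram sampled at 200 Hz.  Provides low-pass FIR
    preprocessing and 30-second segmentation, multitaper (DPSS) band-power
    features, expert-defined time- and frequency-domain statistics (Hjorth
    parameters, kurtosis, skewness), four base classifiers (a 1D
    convolutional network on the raw waveform, a bidirectional LSTM on the
    band-power sequence, a random forest on the expert features, and a
    pre-merged CNN+LSTM network), and a logistic-regression stacking
    meta-classifier fitted by gradient descent.  A synthetic-EEG generator
    with known per-sample arousal ground truth makes the full pipeline
    testable without polysomnography data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
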