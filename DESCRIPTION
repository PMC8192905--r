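Package: premscore
Title: Automated Scoring of Mouse Sleep Stages from Single-Channel EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated classification of mouse sleep stages (Wake, NREM,
    pre-REM, REM, artifact) from a single EEG channel. Provides signal
    preprocessing (zero-phase Butterworth anti-alias filtering and
    linear-interpolation resampling to 64 Hz), stochastic training-time data
    augmentation (amplitude scaling, sign flip, window warping, time shift),
    class rebalancing by per-epoch resampling with replacement, a
    one-dimensional convolutional network trained with Adam under a
    warm-up/cool-down learning-rate protocol with gradient clipping and
    F1-based early stopping, evaluation via confusion matrices, per-class
    precision/recall/F1 and Markov transition matrices, and a synthetic
    EEG/hypnogram generator so the whole pipeline can be exercised without
    access to animal recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
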