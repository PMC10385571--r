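Package: hapr
Title: Human Activity Prediction from Forecasted IMU Accelerometer Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A human activity prediction (HAP) pipeline for wearable
    accelerometer data. Reads PAMAP2-format inertial measurement unit (IMU)
    recordings or simulates quasi-periodic activity signals, preprocesses them
    (edge trimming, artifact repair, zero-phase low-pass filtering, global
    normalization, moving-average smoothing, overlapping 5.12 s epoch
    segmentation), forecasts the next 2.56 s of six-channel signal with
    sequence-to-sequence recurrent networks -- including an encoder-decoder
    LSTM augmented with sinusoidal positional encoding and multi-head
    scaled dot-product attention -- and classifies the forecasted signal into
    one of five daily activities with a bidirectional LSTM. Includes forecast
    metrics (RMSE, Pearson correlation), one-vs-rest classification reports,
    broom-style tidiers, and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
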