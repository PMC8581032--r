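Package: gazenogo
Title: Response and Gaze Behavior Analysis for Go/NoGo Eye-Tracking Sessions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing response and gaze behavior recorded during a
    Go/NoGo inhibitory-control game played in front of a screen-mounted eye
    tracker. The package simulates seeded cohorts of sessions, validates and
    round-trips session logs in a plain-text dialect, preprocesses them
    (median-absolute-deviation response-time outlier removal, downsampling,
    Savitzky-Golay smoothing), extracts 24 spatial response and gaze features
    including sample, histogram, kernel-density and spectral entropies, fits
    second-order autoregressive models to per-trial gaze-to-stimulus distance
    series and extrapolates gaze-adjustment velocity, runs a two- and
    three-group statistical battery with Benjamini-Hochberg control, and
    evaluates a neighborhood-component-analysis plus AdaBoost classification
    protocol under nested stratified cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    jsonlite,
    rlang,
    ggplot2,
    generics,
    signal,
    MASS,
    e1071,
    pROC,
    rpart,
    yaml,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
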