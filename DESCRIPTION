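Package: eitgest
Title: Electrical Impedance Tomography Gesture Recognition with a
    Fold-ASPP-GRU Spatio-Temporal Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for hand-gesture recognition from
    16-electrode electrical impedance tomography (EIT) armband
    measurements. Provides a finite-element forward solver for the
    adjacent current-drive protocol on a circular forearm domain, a
    synthetic phantom and session generator emulating gesture-evoked
    conductivity changes under three confounding factors (limb-position
    change, slow temporal drift, armband rotation), Tikhonov-regularized
    time-difference image reconstruction, sliding-window sequence
    datasets, a fold/atrous-spatial-pyramid-pooling/GRU (FASPP-GRU)
    sequence classifier with KNN, SVM and CNN-LSTM baselines, and a
    per-condition evaluation harness with confusion matrices, macro-F1,
    Friedman model comparison and 2-D feature embeddings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    data.table,
    e1071,
    Rtsne,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
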