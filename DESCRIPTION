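Package: gaitphase
Title: Gait-Phase Identification from Surface EMG with Compact Sequence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for frame-wise stance/swing gait-phase identification from
    multichannel surface electromyography (sEMG) recorded during
    exoskeleton-assisted walking. Implements the full methodology on top of a
    synthetic gait generator: EMG preprocessing (rectification,
    Savitzky-Golay smoothing, MVIC normalization, 3:1 decimation),
    kinematics-based stance/swing labeling with an anticipatory 120 ms label
    advance, sliding-window sequence datasets, five declarative sequence-network
    architectures (BiLSTM, GRU, residual dilated temporal convolution,
    multi-head self-attention) with exact learnable-parameter accounting and a
    receptive-field design rule, an RcppArmadillo training engine with Adam and
    early stopping, Gaussian-process Bayesian hyperparameter optimization with
    an expected-improvement-plus acquisition, a logistic Trade-Off Score for
    cost-performance model selection, and a streaming-inference simulator with
    per-window latency accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    signal,
    data.table,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
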