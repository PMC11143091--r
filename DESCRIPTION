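Package: p300net
Title: Simulation, Compact-CNN Decoding and Saliency Analysis of P300 Oddball EEG
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying single-trial decoding of P300 oddball
    event-related potentials from small-montage EEG. Provides a synthetic
    oddball-paradigm generator with controllable ERP components (P200, P300),
    scenario and session effect structure and 1/f background noise; a
    zero-phase Butterworth band-pass and 50 Hz notch preprocessing chain with
    epoch segmentation, target-adjacent trial censoring and linear
    detrending; a compact depthwise-separable convolutional network
    classifier trained with focal loss under 1:7 class imbalance, including
    exact input gradients; gradient saliency maps with spatial and temporal
    attribution profiles, sliding-window latency estimation and
    session-trend statistics; a windowed-ERP logistic-regression baseline;
    and a seeded end-to-end pipeline with leave-one-subject-out evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
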