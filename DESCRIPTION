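Package: echolv
Title: Automated Left-Ventricular Linear Dimensions from Echocardiographic
    Keypoints with Multi-Expert Consensus Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Localizes the four anatomical keypoints that define the
    interventricular septum, left-ventricular internal diameter and free
    wall on long-axis echocardiographic frames, using Gaussian-heatmap
    regression with a compact U-Net backbone, a pseudo-line collinearity
    target and sub-pixel heatmap decoding, then derives the three
    caliper measurements in centimetres from per-axis pixel spacing.
    Includes a synthetic long-axis phantom generator with a stochastic
    multi-rater labeling simulator, and a multi-reader consensus
    validation framework (per-frame consensus, deviation dispersion,
    Levene dispersion comparison and paired-t bias testing) for judging
    any candidate measurer against a panel of experts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    png,
    Rcpp,
    rlang,
    stats,
    tibble,
    tiff,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    car,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
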