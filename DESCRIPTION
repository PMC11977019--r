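Package: cagewatch
Title: Training-Free Detection, Tracking and Evaluation for Home-Cage Primate Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for monitoring macaques in home-cage video without a
    trained detector: a background-elimination detector (percentile/median
    background synthesis, frozen Gaussian foreground segmentation,
    morphological refinement and convex-hull merging), a constant-velocity
    Kalman tracker with Hungarian assignment and bounded coasting, an
    IoU-based detection evaluation harness with ignore-region handling,
    confidence-threshold sweeps, nonparametric model comparison (Friedman,
    exact Wilcoxon signed-rank, Benjamini-Hochberg), and a seeded synthetic
    home-cage scene generator with exact ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    clue,
    dplyr,
    EBImage,
    ggplot2,
    jsonlite,
    matrixStats,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
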