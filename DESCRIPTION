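Package: swaysom
Title: Self-Organizing Map Analysis of Postural Sway Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies whole-body postural control during lateral
    weight-shifting (sway) tasks from multi-segment skeleton recordings.
    Provides a synthetic cohort generator for Kinect-like lateral-sway
    trials, preprocessing (cubic-spline resampling, sway-cycle
    segmentation, time normalization to a fixed posture array), a
    per-segment amplitude-equalizing normalization, a from-scratch
    Kohonen self-organizing map with sequential training, the Total
    Trajectory Variability (TTvar) statistic with phase-resolved
    variability ellipses, Mann-Whitney group comparisons, and a
    repeated-split k-nearest-neighbor classifier of best-matching-unit
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
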