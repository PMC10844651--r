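Package: dyadsync
Title: Quantifying and Modelling Perceived Dyadic Motor Synchrony
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying motor synchrony in dyadic movement from
    pose-keypoint time series and for modelling how observers perceive it.
    Provides readers for OpenPose-style keypoint output, Savitzky-Golay
    trajectory smoothing, pose-distance-matrix similarity, sample-entropy
    predictability, stimulus segmentation with counterbalanced
    experimental designs and trial schedules, hierarchical Bayesian models
    of rating accuracy (distributional Gaussian) and enjoyment (two-part
    hurdle), and a synthetic-data generator for leader-follower mirror-game
    dyads and simulated rater panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
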