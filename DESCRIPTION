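Package: pualpha
Title: Positive-Unlabeled Learning: Class-Prior Estimation, Calibration and
    Classification with PULSCAR and PULSNAR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the fraction of true positives hidden among the
    unlabeled examples of positive-unlabeled (PU) data under both SCAR
    (selected completely at random) and SNAR (selected not at random)
    labeling.  The PULSCAR estimator combines out-of-fold gradient-boosted
    classifier probabilities, beta-kernel density estimation on the unit
    interval, and slope-change detection on a log mixture-gap objective.
    The PULSNAR estimator clusters labeled positives on gain-scaled
    important features with a full-covariance Gaussian mixture, picks the
    cluster count at the BIC knee point, and sums per-cluster PULSCAR
    estimates.  Also provides histogram-matched label-flip probability
    calibration (isotonic or sigmoid), alpha-guided relabeling to improve
    downstream classification, and seeded SCAR/SNAR synthetic data
    generators so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    xgboost,
    pROC,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    yaml,
    optparse
Config/testthat/edition: 3
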