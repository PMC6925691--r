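Package: vitalvar
Title: Vital-Sign Variability Features for Early Sepsis Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies short-term instability of bedside-monitor vital signs
    (mean arterial pressure, heart rate, respiratory rate, temperature) through
    trend-change features extracted from local extrema of 10-minute sampled
    series, and uses them to predict sepsis onset hours ahead of clinical
    detection. Provides a calibrated synthetic ICU cohort generator (piecewise
    linear instability skeletons with group-dependent extrema rates and swing
    magnitudes, moment-matched to published group statistics), the five-feature
    variability extractor with a descriptive-statistics comparator, permutation
    importance based feature selection, five standard classifiers (logistic
    regression, linear/RBF/polynomial support vector machines, single hidden
    layer neural network) with stratified splitting and cross-validated tuning,
    ROC/PR evaluation, and collection-interval and prediction-horizon sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    kernlab,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
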