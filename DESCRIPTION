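Package: hydrans
Title: Detecting Mild Dehydration from Autonomic Responses to Cognitive Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to detect mild dehydration from wearable-style physiological
    recordings of autonomic responses to cognitive stress. Extracts nine
    electrodermal activity (EDA) and pulse rate variability (PRV) indices from
    synchronized skin-conductance and photoplethysmography (PPG) signals
    recorded during a rest/test (Stroop) protocol: skin conductance level and
    non-specific response rate via nonnegative sparse deconvolution, spectral
    EDA power via Welch periodograms, a time-varying sympathetic index via
    variable-frequency complex demodulation, and spectral PRV band powers from
    spline-resampled pulse intervals. Provides rest-versus-test statistical
    comparison, a leave-one-subject-out classification study over all feature
    subsets and nine classifier families with minority up-sampling, and a
    synthetic wet/dry cohort simulator with ground-truth logs so every stage
    can be validated against analytic oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    Matrix,
    splines,
    signal,
    pracma,
    jsonlite,
    glmnet,
    MASS,
    e1071,
    rpart,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
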