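Package: rhythmMTL
Title: Behavioral-Rhythm Features and Multi-Task Learning for Momentary
    Symptom Prediction
Version: 0.1.0
Authors@R:
    person("Rhythm", "Maintainers", email = "maintainers@rhythm-mtl.org",
           role = c("aut", "cre"))
Description: Tools for predicting ecological momentary assessment (EMA)
    symptom scores from behavioral-rhythm features extracted from
    smartphone sensing streams.  Implements windowed rhythm metrics
    (multiscale sample entropy, periodogram band power, M10/L5,
    rest-activity relative amplitude, deviation from a 24-h activity
    template, interday stability and intraday variability), single-task
    LASSO, l2,1-norm multi-task regression coupling symptoms or patients,
    multi-output least-squares support vector regression, the associated
    cross-validation protocols and paired statistical comparisons, and a
    heterogeneity/subtype analysis of the fitted weights.  A synthetic
    cohort generator with planted rhythm structure, sparse weight supports
    and patient subtypes supports end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
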