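Package: cews
Title: Centile-Based Early Warning Scores from Vital-Sign Distributions
Version: 1.0.0
Authors@R: person("CEWS", "Maintainers", email = "maintainers@cews.example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating band-based early warning score
    (EWS) systems for hospital vital-sign data. Score-band thresholds are
    derived in an unsupervised way from the centiles of kernel-smoothed
    vital-sign distributions; shipped scoring systems include manual and
    continuous centile-based EWS definitions and the National Early Warning
    Score as a comparator. Includes observation-set preprocessing
    (plausibility filtering and score-neutral mean imputation), composite
    adverse-outcome labelling within a configurable horizon, discrimination
    metrics (ROC/AUC with DeLong confidence intervals, precision-recall with
    average precision), threshold-substitution analysis, and a synthetic
    ward-cohort generator with analytic marginal quantiles for end-to-end
    testing without hospital data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
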