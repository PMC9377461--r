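Package: fallstay
Title: Causal and Decision-Analytic Modelling of Fall-Related Extended Hospital Stay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the extension of hospital stay attributable to
    inpatient falls and converts fall-risk predictions into expected
    reductions in hospital days and medical costs. Provides a synthetic
    cohort generator with covariate-driven fall risk and confounded
    length of stay, multiple imputation by chained equations, propensity
    score matching (one-to-one nearest neighbor with replacement) with
    balance diagnostics and bootstrap confidence intervals for the
    average treatment effect on the treated, Rosenbaum sensitivity bounds
    (worst-case one-sided P values and Hodges-Lehmann point-estimate
    bounds under hidden bias), classifier evaluation (ROC/AUC, Youden
    cutoff, confusion-matrix metrics, net reclassification improvement),
    and a decision-analytic model of per-intervention-day net reduced
    hospital days and cost savings under prevention scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
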