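---
title: "Estimating fall-attributable hospital stay and the value of prediction-based prevention"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating fall-attributable hospital stay and the value of prediction-based prevention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fallstay)
```

## The problem

Inpatient falls among elderly hospitalized patients extend hospital stays,
but fallen and unfallen patients differ systematically: patients who fall
are older, frailer, and sicker, and would have stayed longer even without
falling. A naive comparison of mean stays therefore overstates the causal
effect. `fallstay` implements a complete observational-causal workflow for
this problem — multiple imputation, propensity score matching, hidden-bias
sensitivity analysis — together with the evaluation of a fall-risk
classifier and a decision-analytic model that converts a classifier's
confusion matrix into the hospital days and costs a prevention program
could save.

Because the kind of cohort this analysis needs (one row per
hospitalization, a fall indicator, length of stay, and tens of mostly
binary clinical covariates) comes from electronic health records that
cannot be shared, the package includes a synthetic-cohort generator that
reproduces the statistical structure the analysis assumes. Every stage of
the pipeline is therefore testable offline against known ground truth.

## The causal estimand and the matching estimator

The quantity of interest is the average treatment effect on the treated
(ATET): the mean extension of stay among fallen patients relative to the
counterfactual stay they would have had without falling,

$$\tau = E[Y(1) - Y(0) \mid T = 1],$$

where $T$ is the fall indicator and $Y$ the length of stay in days.
Identification assumes falls are ignorable given the observed covariates
$X$; the propensity score $e(X) = P(T = 1 \mid X)$ is estimated by
logistic regression (`fit_propensity()`), and each fallen case is paired
with the unfallen case with the nearest score by one-to-one
nearest-neighbor matching **with replacement** (`match_nn_replacement()`).
With replacement matters at low prevalence: good controls near the
high-risk tail are scarce, and allowing reuse keeps match quality high at
the price of mildly correlated pairs. The ATET estimate is the mean
treated-minus-matched-control difference; its confidence interval is a
percentile bootstrap over matched pairs (default 1,000 resamples).

Matching quality is diagnosed with standardized mean differences
(`standardized_difference()`, `balance_report()`): the two-sample
Cohen-style $d$ with averaged variances, using $p(1-p)$ variances for
binary covariates. $|d| < 0.1$ for every covariate after matching is the
conventional adequacy criterion, and the packaged generator defaults
satisfy it.

Design choices made where the design was genuinely open:

* **Tie-breaking.** Equidistant controls resolve to the lowest control
  index — deterministic and stable under reordering of treated units.
* **No caliper by default.** A caliper is exposed as an option of
  `match_nn_replacement()` but off by default; with a large control
  reservoir and good overlap it is unnecessary.
* **Confidence interval.** The percentile bootstrap resamples treated
  units with their matched controls. It is assumption-light, but it treats
  pairs as independent and ignores propensity-estimation noise, so its
  intervals are known to run slightly narrow for matching with
  replacement; the coverage study in the test suite quantifies this at the
  default study conditions.
* **Per-imputation analysis.** With missing covariates, matching and
  estimation run separately on each completed dataset and point estimates
  are averaged (`pool_scalar_over_imputations()`); no Rubin's-rules
  variance pooling is attempted, since only point estimates and bounds are
  pooled downstream.

## Hidden-bias sensitivity: Rosenbaum bounds

Matching removes observed confounding only. Rosenbaum's sensitivity
analysis asks how strong an *unobserved* covariate would have to be to
overturn the conclusion. If hidden bias can shift the within-pair odds of
falling by at most $\Gamma \ge 1$, the probability that the member with
the larger response is the fallen one is at most
$p^{+} = \Gamma/(1+\Gamma)$. The signed-rank statistic
$T$ (zeros dropped, midranks for ties) is then stochastically bounded by a
distribution with mean $p^{+}\sum_i r_i$ and variance
$p^{+}(1-p^{+})\sum_i r_i^2$, giving a worst-case one-sided P value
(`rosenbaum_pvalue_bound()`). The worst-case effect size is the minimum
Hodges–Lehmann estimate (`hodges_lehmann_bound()`): the shift $\tau$ at
which the signed-rank statistic of the shifted differences crosses its
$\Gamma$-bound expectation.

Numerical choices:

* The normal approximation is used at all sample sizes (no continuity
  correction), the standard practice at the scale this analysis targets
  (on the order of a thousand pairs); an exact sign-pattern enumeration
  is kept in the test suite as an oracle for small $n$ and verifies that
  at $\Gamma = 1$ the bound collapses to the exact Wilcoxon signed-rank
  test.
* Because the statistic is a step function of $\tau$, the crossing is an
  interval. `hodges_lehmann_bound()` brackets both edges by bisection
  (tolerance $10^{-6}$ days) and returns the midpoint, which at
  $\Gamma = 1$ equals the classical Hodges–Lehmann estimate — the median
  of the Walsh averages — rather than the interval's lower edge.
* Zero differences are dropped before ranking; tied absolute differences
  receive midranks, and the variance uses $\sum r_i^2/4$, which equals
  the classical tie-adjusted formula.

`sensitivity_table()` evaluates both bounds over a $\Gamma$ grid per
imputed dataset and averages across imputations; the maximum P value is
non-decreasing and the minimum Hodges–Lehmann estimate non-increasing in
$\Gamma$, which the tests assert as invariants.

## Classifier evaluation

Risk scores are evaluated threshold-free by the midrank Mann–Whitney AUC
(`auc()`, identical to the trapezoidal ROC area and invariant under
monotone transforms) and at an operating point chosen by the Youden index
(`youden_cutoff()`): the observed score maximizing sensitivity +
specificity − 1 under the rule *score ≥ threshold predicts a fall*, with
ties broken toward the lowest threshold — in a fall-screening context the
more sensitive operating point is preferred. `metrics_from_confusion()`
reports sensitivity, specificity, precision and F1, returning `NA` (not
zero) for metrics with empty denominators. Two classifiers are compared by
the categorical net reclassification improvement (`nri()`), with the usual
asymptotic z test. `average_metric_sets()` supports fold-averaged
reporting for temporal cross-validation designs.

## The decision model

Given a confusion matrix at an operating point, stay parameters
(`stay_parameters()`: fallen mean stay $L_f$, unfallen mean stay $L_u$,
daily cost) and a scenario (`scenario()`: assumed stay extension $A$ and
prevention rate $r$), `evaluate_scenario()` computes, per day of
intervention:

$$D = r\,\mathrm{TP}\,(L_f - A) + (1-r)\,\mathrm{TP}\,L_f +
\mathrm{FP}\,L_u$$

intervention days (prevented true positives stay $L_f - A$ days,
unprevented ones $L_f$, false positives $L_u$), reduced days
$r\,\mathrm{TP}\,A$, days lost to missed cases $r\,\mathrm{FN}\,A$, and
the net reduction and cost saving per intervention day. The treat-everyone
policy (`treat_all_matrix()`) is the baseline: all fallen cases become
true positives, all unfallen cases false positives. `policy_sweep()`
traces net savings over every observed threshold with sensitivity above a
floor, including the treat-all endpoint, which is how one sees whether —
and where — a prediction model beats indiscriminate intervention.

Reporting rounds days/day to three decimals and currency to whole units,
half away from zero (`round_half_up()`); all internal arithmetic is
unrounded. The bundled worked-example inputs
(`example_confusion_matrix()`, `example_stay_parameters()`,
`example_scenarios()`) reproduce a published four-scenario cost table to
printed precision, with one caveat: the source tables' "reduced days"
cells for the two 25%-prevention rows are inconsistent with their own
net = reduced − lost identity (and between a table and a figure caption
the scenario-3 cost differs by one Yen, the unrounded value falling
between); the package reports the internally consistent arithmetic.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, with
defaults chosen once to mirror a realistic elderly acute-care cohort:

* **Scale and prevalence.** 50,000 hospitalizations (the order of
  magnitude of a multi-year single-center cohort), fall prevalence 2.4%,
  calibrated exactly by solving the logistic intercept.
* **Covariates.** Scaled age (uniform over 65–99 years, stored on
  $[0,1]$) plus 48 binary covariates with marginal prevalences spread over
  0.05–0.50, the range typical of comorbidity and medication flags.
* **Fall model.** Log-odds 1.5 for scaled age and a repeating
  $\{0.6, 0.3, 0, -0.3\}$ pattern over the binaries — modest effects that
  give good treated/control overlap and a propensity AUC near 0.7–0.8, the
  regime in which matching is informative.
* **Length of stay.** Lognormal with marginal mean 10.6 and SD 6.8 days
  (right-skewed, strictly positive). The covariates shift the log-mean
  with coefficients $0.25\times$ the fall coefficients, so fall risk and
  stay length are genuinely confounded; the covariate shift's variance is
  absorbed into the total log-variance so the marginal moments still hit
  their targets. Fallen subjects receive an additive `true_atet` days, so
  the generator's ATET is exact by construction. Stays are kept
  continuous; rounding to whole days is a reporting concern.
* **Missingness.** MCAR, or MAR driven only by the always-observed fields
  (age and fall status) with a calibrated marginal rate — emulating
  lab-panel blocks missing for up to ~20% of admissions.
* **Risk scores.** Binormal: non-events standard normal, events shifted
  by $\delta = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})$, so the expected AUC
  equals the target exactly.

What the generator does *not* emulate: covariate correlation structure
(covariates are independent given the margins), informative missingness in
the outcome, time-varying risk within an admission, and clinical-text
features. Passing tests on synthetic cohorts therefore demonstrate the
estimators' correctness under the stated assumptions, not robustness to
every feature of real EHR data.

## Multiple imputation

`mice_impute()` implements chained equations with the conventional
choices: binary covariates by a logistic posterior draw, continuous ones
by Bayesian linear regression with type-1 predictive mean matching
(k = 5 donors, keeping imputed values inside the observed support, robust
to skewed lab-style variables). Predictors are all other covariates plus
the fall indicator, preserving the covariate–outcome relationship the
propensity model needs. Defaults are 20 imputations and 10 cycles;
per-imputation seeds derive from the master seed by index, so any single
imputation is reproducible in isolation. Observed cells are never
modified, and columns with no observed values are rejected rather than
guessed.

## Problem sizes and determinism

The test suite exercises the full pipeline at cohort sizes of 1,500–50,000
with a 50-replicate coverage study at n = 30,000 for the matched-pair
bootstrap — sizes chosen so the whole suite runs in about a minute while
keeping Monte-Carlo error well inside every stated tolerance. All
randomness flows from explicit integer seeds: `run_pipeline()` with an
identical configuration writes byte-identical outputs, and the manifest
records the configuration fingerprint and seeds of every run.

## Known limitations

* Ignorability given the observed covariates is assumed, not testable;
  the Rosenbaum bounds quantify, but cannot remove, sensitivity to hidden
  bias.
* The pair bootstrap underestimates uncertainty slightly when controls
  are reused heavily or the propensity model is noisy; an
  Abadie–Imbens-type analytic variance is deliberately out of scope.
* The decision model is linear in counts and treats stay parameters as
  fixed constants; no uncertainty is propagated into the cost table.
* The categorical NRI is implemented for binary reclassification only.
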