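# fallstay

Causal and decision-analytic modelling of fall-related extended hospital
stay.

Inpatient falls among patients aged 65 and over extend hospital stays, but
patients who fall are systematically frailer than those who do not, so the
naive difference in mean stays overstates the causal effect. `fallstay`
implements the full observational workflow for estimating the stay
extension attributable to falls and for valuing a fall-prediction model as
a screening tool:

* **Synthetic cohorts** (`generate_cohort()`): hospitalizations with
  covariate-driven fall risk at ~2.4% prevalence, a right-skewed length of
  stay confounded by the same covariates, an exactly known additive
  treatment effect on the treated, block-wise missingness, and binormal
  risk scores at a configurable AUC — so every downstream stage is
  testable against ground truth.
* **Multiple imputation** (`mice_impute()`): chained equations with
  logistic draws for binary covariates and predictive mean matching for
  continuous ones.
* **Propensity score matching** (`fit_propensity()`,
  `match_nn_replacement()`, `estimate_atet()`, `balance_report()`):
  logistic propensity scores, one-to-one nearest-neighbor matching with
  replacement, standardized-difference balance diagnostics, and the
  average treatment effect on the treated (ATET)

  `ATET = mean(LOS_treated) − mean(LOS_matched controls)`

  with a percentile-bootstrap confidence interval.
* **Rosenbaum sensitivity bounds** (`rosenbaum_pvalue_bound()`,
  `hodges_lehmann_bound()`, `sensitivity_table()`): worst-case one-sided
  signed-rank P values and minimum Hodges–Lehmann effect estimates when an
  unobserved confounder can shift within-pair treatment odds by Γ.
* **Classifier evaluation** (`auc()`, `youden_cutoff()`,
  `metrics_from_confusion()`, `nri()`): midrank AUC, Youden-index cutoff,
  confusion-matrix metrics, and categorical net reclassification
  improvement.
* **Decision model** (`evaluate_scenario()`, `scenario_table()`,
  `treat_all_matrix()`, `policy_sweep()`): converts a confusion matrix,
  mean stays and a daily cost into net reduced hospital days and currency
  saved per day of intervention, under scenarios for the assumed stay
  extension `A` and the prevention rate `r`:

  ```
  intervention days  D = r·TP·(L_f − A) + (1−r)·TP·L_f + FP·L_u
  net days per day     = (r·TP·A − r·FN·A) / D
  cost per day         = net days per day × daily cost
  ```

`run_pipeline()` wires the stages together (simulate → impute → match →
sensitivity → evaluate → decide), writing every artifact as delimited text
or JSON with a manifest, and reproduces byte-identical outputs under a
fixed configuration.

## Worked example

The package ships the confusion matrix of a fall-prediction model at its
Youden cutoff (TP = 168, FP = 1638, FN = 60, TN = 8520 over 10,386
hospitalizations), mean stays of 30.3 / 10.6 days for fallen / unfallen
cases, a daily cost of 40,000 Yen, and four intervention scenarios:

```r
library(fallstay)
cm        <- example_confusion_matrix()
params    <- example_stay_parameters()
scenarios <- example_scenarios()
scenario_table(cm, params, scenarios, rounded = TRUE)
#>        label atet prevention_rate reduced_per_day lost_per_day net_per_day cost_per_day
#> 1 scenario_1 17.8            1.00           0.154        0.055       0.099         3951
#> 2 scenario_2 17.8            0.25           0.034        0.012       0.022          886
#> 3 scenario_3  8.6            1.00           0.069        0.025       0.044         1768
#> 4 scenario_4  8.6            0.25           0.016        0.006       0.011          420
```

Reading the first row: if every predicted fall were prevented and a fall
extends a stay by 17.8 days, interventions on the 1,806 predicted-positive
cases would net 0.099 fewer hospital days — about 3,951 Yen — per day of
intervention; at a 25% prevention rate and a conservative 8.6-day effect
(the hidden-bias bound at Γ = 2) the break-even cost is 420 Yen/day.

The causal pipeline end to end, on a synthetic cohort with a known 12-day
effect and missing covariates:

```r
cfg <- pipeline_config(
  cohort     = cohort_config(n_subjects = 20000, true_atet = 12,
                             missingness_rates = c(x01 = 0.2, x02 = 0.1),
                             seed = 7),
  imputation = imputation_spec(m = 5, n_cycles = 5, seed = 7),
  n_boot = 500, gammas = c(1, 1.5, 2, 3), seed = 7)
res <- run_pipeline(cfg, "demo_run")
#> [simulate] n=20000, prevalence=0.0245, missing cells=5947
#> [impute] m=5 completed datasets
#> [match] ATET=12.10 d (CI 11.13-13.11), PS AUC=0.794
#> [sensitivity] 4 gamma levels, max_p(1)=3.83e-59
#> [evaluate] AUC=0.835, Youden cutoff=0.681, F1=0.132
#> [decide] 4 scenarios, best net=0.085 days/day

res$sensitivity
#>   gamma        max_p    min_hl
#> 1   1.0 3.825668e-59 12.195259
#> 2   1.5 8.859914e-37 10.435770
#> 3   2.0 1.074015e-25  9.162858
#> 4   3.0 8.118030e-15  7.301181
```

The matched estimate (12.10 days, CI 11.13–13.11) recovers the simulated
12-day effect, and the sensitivity table shows how the worst-case effect
estimate erodes as stronger hidden bias is allowed: even at Γ = 3 the
bound stays positive and significant.

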