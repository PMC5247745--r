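# mblater

Derivation and evaluation of clinical risk scores for **very late
recurrence of atrial fibrillation** (VLRAF) — recurrence documented more
than 12 months after radiofrequency catheter ablation, in patients who
appeared arrhythmia-free at the one-year landmark.

The package is built around the **MB-LATER score**:

| Component | Points |
|---|---|
| **M**ale sex | 1 |
| **B**undle branch block | 1 |
| **L**eft **A**trium ≥ 47 mm | 1 |
| **T**ype of AF (paroxysmal / persistent / long-standing persistent) | 0 / 1 / 2 |
| **ER**AF (early recurrence within the 3-month blanking period) | 1 |

Total 0–6 points. Six comparator scores are implemented with the same
interface: APPLE (0–5), ALARMc (0–5), BASE-AF2 (0–6), CHADS₂ (0–6),
CHA₂DS₂-VASc (0–9) and HATCH (0–7).

## What the package does

* **Scoring** (`score_mb_later()`, `score_apple()`, …, `score_all()`):
  pure, vectorised functions mapping a patient-level cohort table to
  integer points, with per-component breakdowns.
* **Synthetic cohorts** (`cohort_config()`, `simulate_cohort()`): a seeded
  generator with the derivation cohort's covariate marginals, an
  exponential (optionally Weibull) proportional-hazards recurrence process
  on the MB-LATER components, uniform administrative censoring, and the
  landmark selection flow (blanking period → exclusion of 3–12-month
  recurrences → inclusion beyond 12 months).
* **Survival machinery** (`km_curve()`, `cum_incidence()`,
  `logrank_test()`, `cox_fit()`): product-limit estimation with Greenwood
  variance, two-group log-rank, and univariate Cox fits (Efron ties,
  Newton with step-halving, separation detection) written from first
  principles and cross-checked against the `survival` package in the
  test suite.
* **Score evaluation** (`eval_auc()`, `youden_cutoff()`,
  `confusion_metrics()`, `fit_risk_mapping()`, `idi()`, `nri()`,
  `decision_curve()`): AUC by the midrank Mann–Whitney formulation with
  DeLong intervals, Youden-optimal cutoffs, category-free (and optional
  categorical) net reclassification improvement, integrated
  discrimination improvement, and decision-curve net benefit
  NB(pₜ) = TP/n − (FP/n)·pₜ/(1−pₜ).
* **Pipeline** (`screen_candidates()`, `assemble_score()`,
  `run_study()`, `write_report()`): the end-to-end derivation procedure —
  univariate Cox screen of clinical candidates, ROC-based dichotomization
  of continuous ones, additive score assembly, full evaluation, and a
  reproducible JSON/CSV report bundle. A thin command-line wrapper lives
  in `inst/cli/mblater.R`.

All user-facing functions take a data frame first and return tibbles, so
analyses chain with the pipe; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

```r
library(mblater)

report <- run_study(config = cohort_config(), seed = 1)
report
```

```
Study report (seed 1): 128 patients, 27 events (21.1%)

Score performance:
# A tibble: 7 × 7
  label          auc conf_low conf_high cutoff sensitivity specificity
  <chr>        <dbl>    <dbl>     <dbl>  <int>       <dbl>       <dbl>
1 MB-LATER     0.772    0.679     0.866      2        70.4        76.2
2 APPLE        0.645    0.542     0.749      1        88.9        36.6
3 ALARMc       0.645    0.547     0.743      1        96.3        27.7
4 BASE-AF2     0.564    0.447     0.681      4        14.8        94.1
5 CHADS2       0.610    0.509     0.712      1        92.6        31.7
6 CHA2DS2-VASc 0.541    0.426     0.656      2        59.3        48.5
7 HATCH        0.637    0.532     0.743      1        88.9        34.7

Reclassification vs mb_later:
# A tibble: 6 × 6
  reference comparator     idi      idi_p   nri      nri_p
  <chr>     <chr>        <dbl>      <dbl> <dbl>      <dbl>
1 mb_later  apple        0.155 0.000567    49.7 0.0139
2 mb_later  alarmc       0.165 0.000238    56.6 0.00664
3 mb_later  base_af2     0.184 0.00000531  87.3 0.00000902
4 mb_later  chads2       0.173 0.000157    93.2 0.00000177
5 mb_later  cha2ds2_vasc 0.198 0.0000160   93.2 0.00000177
6 mb_later  hatch        0.167 0.000422    93.2 0.00000177

Log-rank across mb_later strata: chi-square 25.10, p = 5.43e-07
```

Reading this: one simulated 128-patient cohort (a draw at the study's own
scale, so the event fraction fluctuates around its 15% target) gives
MB-LATER the highest discrimination (AUC 0.772), a Youden-optimal cutoff
of ≥ 2 points, positive IDI and continuous NRI against every comparator,
and a strongly significant separation of recurrence-free survival between
the < 2 and ≥ 2 strata. Cumulative incidence from the same report:

```r
report$cum_incidence
#      at estimate conf_low conf_high extrapolated
#   <dbl>    <dbl>    <dbl>     <dbl> <lgl>
# 1    24    0.160   0.0877     0.232 FALSE
# 2    36    0.284   0.187      0.381 FALSE
```

i.e. 16% cumulative recurrence at 2 years and 28% at 3 years since
ablation in this draw. `write_report(report, "out/")` serialises the
report to `report.json` plus KM / ROC / decision-curve CSVs.

## Vignette

`vignettes/mblater-methods.Rmd` documents the statistical methods, the
generative model behind the synthetic cohorts, the numerical choices
(tie handling, convergence, separation, tie-breaking at cutoffs) and the
known limitations.
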