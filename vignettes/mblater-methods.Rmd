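---
title: "Methods behind mblater: scores, simulation and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mblater: scores, simulation and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

After catheter ablation for atrial fibrillation (AF), most recurrences
happen within the first year. Patients who reach the 12-month landmark
arrhythmia-free are often treated as cured, yet a substantial minority
experience *very late* recurrence (VLRAF) afterwards — a distinction that
matters for anticoagulation, monitoring intensity and redo-ablation
decisions. `mblater` implements a family of integer clinical risk scores
for this endpoint, the machinery to evaluate and compare them, and a
synthetic-cohort generator so that every stage is testable without
patient-level data.

## Scoring conventions

Each score is a pure function of named covariates; all other columns are
ignored, and totals are sums of component points. Three conventions are
worth stating because they are easy to get subtly wrong:

* **Inequality strictness is taken literally from the published
  definitions.** The left-atrial thresholds of MB-LATER (≥ 47 mm) and
  APPLE (≥ 43 mm) are inclusive; APPLE's age (> 65), ALARMc's LA index
  (> 23 mm/m²) and all BASE-AF2 thresholds (BMI > 28 kg/m², LA > 40 mm,
  history > 6 years) are strict. The test suite audits every boundary.
* **eGFR is carried on two scales** — absolute ml/min for ALARMc and
  body-surface-normalised ml/min/1.73 m² for APPLE — as two separate
  fields. No conversion happens inside a scorer, because the two scores
  genuinely threshold different quantities. Likewise the LA diameter
  index (mm/m²) is a stored field, not recomputed from diameter and body
  surface area at scoring time.
* **Complete-case only.** A missing field or missing value is rejected
  with the field named. The scores were derived on a complete-case
  cohort and silent imputation would change their meaning.

For the thromboembolic-risk scores reused here as comparators, age
boundaries follow their original definitions: ≥ 75 for CHADS₂ and
CHA₂DS₂-VASc (with 65–74 scoring one point on the latter), and strictly
\> 75 for HATCH as conventionally tabulated.

## The synthetic cohort generator

`simulate_cohort()` emulates a single-centre ablation cohort observed
through a 12-month landmark design.

**Covariates.** Each candidate patient draws independent covariates from
marginals matching the derivation cohort's baseline table: 63.9% male,
4.4% bundle branch block, AF type in proportions 92/32/9 (paroxysmal /
persistent / long-standing persistent), 18.8% early recurrence, LA
diameter Normal(40.2, 5.2) mm, and so on (see `cohort_config()` for the
full list). Continuous covariates are truncated normals with
physiologically sensible bounds. Independence is the default because no
correlation structure is published for this cohort; a Gaussian-copula
hook (`correlation =`) exists for sensitivity analyses. The absolute
eGFR is drawn from its reported moments and the normalised scale derived
through a simulated body surface area, which keeps the two renal fields
consistent within a patient.

**Recurrence process.** Latent recurrence time follows a
proportional-hazards model whose linear predictor is the sum of log
hazard ratios over the five MB-LATER component indicators, with defaults
ln(3.37) for male sex, ln(6.08) for BBB, ln(4.27) for LA ≥ 47 mm,
ln(6.63) for non-paroxysmal AF and ln(3.00) for early recurrence — the
published univariate associations. The baseline hazard is constant
(exponential) by default; cumulative recurrence in this setting accrues
steadily, consistent with a near-constant hazard, and the memoryless
property also makes the landmark conditioning exact. A Weibull shape
parameter is available for decreasing- or increasing-hazard sensitivity
runs. Time is counted from the end of the 3-month blanking period.

**Early recurrence.** ERAF is drawn as a Bernoulli covariate that enters
the recurrence hazard through its own coefficient. This reproduces the
ERAF–VLRAF association quantitatively while keeping the generative model
a coherent proportional-hazards process; we preferred this to post-hoc
inflation of the ERAF probability for patients with short latent times,
which would couple the covariate to the outcome outside the hazard model.

**Selection flow and censoring.** Candidates whose latent recurrence
falls in the (3, 12]-month window (late recurrence) are excluded;
blanking-period behaviour never excludes. Survivors receive an
administrative censoring time uniform on 13–48 months, so follow-up has
mean ≈ 29–30 months, and `followup_months = min(latent, censoring)` with
the event indicator accordingly. By construction no emitted event time
is ≤ 12 months.

**Calibration.** Two defaults were fixed once, by large-N Monte Carlo,
to the study's own scale: `baseline_rate = 0.00115` events/month makes
the *selected* cohort's event fraction ≈ 15%, and `n_candidates = 150`
yields ≈ 133 selected patients. They are stated conditions of the
emulated design, not tuning knobs.

**What the generator does not emulate.** Covariates are independent
(real comorbidities cluster); the published marginals are applied to the
*pre-selection* candidates, so the selected cohort's marginals drift
slightly (high-risk patients are preferentially excluded as late
recurrences — e.g. the selected male fraction sits a little below
63.9%); event times are continuous, whereas clinic follow-up detects
recurrence at visit granularity; and procedural covariates (ablation
lesion sets, fluoroscopy and RF times) are not generated at all, since
the scores use only clinical variables. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean
proportional-hazards world, not fidelity to any real cohort.

## Survival machinery: numerical choices

* **Kaplan–Meier.** Product-limit with Greenwood variance; censorings at
  an event time remain in that time's risk set. When the estimate hits
  zero its variance is reported as zero (absorbing state). Cumulative
  incidence is 1 − S(t) with a plain normal-scale interval from the
  Greenwood variance; queries beyond the last observed time return the
  last value flagged `extrapolated`.
* **Log-rank.** Two-group statistic with the hypergeometric variance at
  each distinct event time. The chi-square is label-invariant; the
  signed square root (`direction`) is positive when the first group by
  label sort order has more events than expected.
* **Cox.** Single-covariate partial likelihood maximised by Newton's
  method with step-halving, Efron correction for ties (tied event months
  are natural at clinical follow-up granularity, and Efron is less
  biased than Breslow there), convergence at |Δβ| < 1e-9, at most 50
  iterations. The covariate is centred internally for stability. A
  monotone likelihood (complete separation) is detected when the
  coefficient runs past |β| > 15 or the information degenerates; the fit
  is then flagged unconverged with the runaway direction rather than
  reporting a meaningless Wald interval. P-values are Wald, matching the
  defaults of the mainstream commercial packages such analyses are
  typically run in. The score statistic at β = 0 is exposed; on tie-free
  binary data it equals the log-rank chi-square, which the tests verify.
* **Time origin.** All subjects share the 12-month landmark, so times
  since ablation and times since landmark differ by a constant shift;
  risk sets, and hence all rank-based statistics, are identical either
  way. Fractional months are accepted throughout.

## Evaluation: definitions and defaults

* **AUC** uses the midrank Mann–Whitney formulation (tied pairs count
  ½), with DeLong's placement-value variance for the interval, normal on
  the AUC scale and clipped to [0, 1]. Reporting precision follows the
  field's convention of three decimals on AUC and one on percents.
* **Cutoffs** maximise Youden's J over observed score values, with
  "score ≥ cutoff" as the positive rule; ties in J break toward the
  lower (more sensitive) threshold, the natural choice for a
  rule-out-oriented score. Degenerate direction (best J ≤ 0) is flagged.
* **Confusion rates** are exact ratios on the percent scale; a
  zero-denominator rate is `NA` (undefined), never 0.
* **Risk mapping.** Integer scores enter IDI and decision curves through
  a one-variable logistic calibration. Under separation (or a constant
  score) the mapping falls back to clamped empirical per-stratum event
  rates with linear interpolation. This bridge is an implementation
  device: the reclassification quantities are defined on probabilities,
  and some probability model for "score → risk" is unavoidable.
* **NRI** is category-free by default: net proportion of events moving
  up plus net proportion of non-events moving down, ties counting to
  neither side, reported as a percentage in [−200, 200]. The continuous
  version is the default because the method's reference framework does
  not fix categories for this endpoint and observed improvements on the
  order of 50–95% fit the continuous scale; a categorical variant with
  user-supplied cut-points is provided. P-values for NRI and IDI use the
  standard asymptotic (paired, two-component) standard errors.
* **Decision curves** report NB(pₜ) = TP/n − (FP/n)·pₜ/(1−pₜ) for the
  model, treat-all and treat-none over a default grid of 0.05–0.50 in
  steps of 0.01 — the clinically plausible range for a ~15%-prevalence
  endpoint. Net benefit can never exceed prevalence, which the tests
  assert alongside the closed-form references.

## The derivation pipeline

`screen_candidates()` fits a univariate Cox model per candidate.
Continuous candidates are screened twice — as continuous covariates, and
dichotomized at their Youden cutoff with the direction taken from the
sign of the continuous coefficient — because integer point scores need
binary (or ordinal) components. Selection takes clinical allow-listed
candidates whose usable form has p < 0.05. `assemble_score()` gives one
point per selected binary component and upgrades non-paroxysmal AF to
the ordinal 0/1/2 assignment over the three AF types.

Two statistical caveats are documented deliberately:

* **Dichotomizing at an outcome-optimised cutoff and then testing the
  same data is anti-conservative.** The Youden-dichotomized form's
  p-value does not hold its nominal level. The package's type-I
  calibration checks therefore measure the false-selection rate on the
  pre-specified binary candidates, where the Cox Wald test is the only
  inferential step; the dichotomized re-screen is a score-construction
  device, not a calibrated test.
* **Univariate hazard ratios are non-collapsible.** When several
  components drive the hazard simultaneously, the marginal univariate
  coefficient of each is attenuated relative to its generating value
  even with independent covariates. Parameter-recovery checks therefore
  simulate one generating coefficient at a time, where the univariate
  model is correctly specified; under the all-components-on default the
  screen still selects the right variables (the attenuated associations
  remain strong), which is checked separately.

## Problem sizes used by the checks

The test suite exercises: exhaustive oracles (pairwise AUC,
redistribute-to-the-right KM, independent log-rank) on instances of up
to 12 subjects; Cox coefficient recovery on 20 cohorts of 5,500
candidates (one generating coefficient each, ≥ 18/20 interval coverage);
type-I calibration of the screen over 500 null replicates of 400
candidates; and the discrimination ordering of the MB-LATER score
against all six comparators by majority over 20 default-scale cohorts.
These sizes were chosen to make Monte-Carlo noise small relative to the
assertions while keeping the default test run quick.

## Known limitations

* The generator's independence default understates real covariate
  clustering (e.g. hypertension with age); the copula hook exists but no
  published correlation targets are available to set it from.
* Reclassification p-values are asymptotic; no bootstrap is provided.
* The ROC analysis treats final event status as the label regardless of
  censoring time, as a fixed-landmark design implies; time-dependent
  AUC is out of scope.
* Only two-group log-rank and single-covariate Cox are implemented —
  the derivation procedure needs nothing more — so multivariable
  modelling and proportional-hazards diagnostics are deliberately
  absent.
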