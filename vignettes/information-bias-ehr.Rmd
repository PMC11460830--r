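---
title: "Information bias in EHR-based association studies: model, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information bias in EHR-based association studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrbias)
```

## The problem

A computable phenotype classifies a patient as diseased when their record
contains enough coded evidence, and as non-diseased otherwise.  Absence
of evidence is treated as absence of disease.  For a rare condition in
young adults this gives near-perfect specificity — spurious diabetes
codes are unusual — but sensitivity that depends on how much record
there is to search.  Two mechanisms make that dependence differential:

* **Informed presence.**  Each encounter is an opportunity for a true
  condition to be coded, so sensitivity rises with encounter count; and
  chronic disease itself raises the encounter rate.  When exposure and
  outcome are both EHR phenotypes, utilization is a common cause of both
  *observed* indicators even when the diseases are weakly related.
* **Diagnostic suspicion.**  Laboratory screening is not uniform:
  subgroups screened more (or less) accumulate more (or less) evidence,
  shifting subgroup-specific sensitivity.

The package implements a synthetic EHR whose causal structure contains
exactly these paths with every true parameter known, the phenotypes that
read events back into indicators, four estimation strategies, a
design-based survey benchmark, and a replicated evaluation harness.

## Generative model

For patient $i$ with covariates $X_i$ (age 18–44, sex, race/ethnicity,
Medicaid, neighborhood poverty stratum):

1. **True disease.**  Obesity, then asthma, then diabetes are drawn from
   logistic models; the diabetes model includes true obesity and true
   asthma, so `exp(true_log_or$diabetes["asthma"])` (default **1.4**) is
   the conditional odds ratio every estimator targets.  Baseline
   prevalences are specified at the reference pattern (White, female,
   age 31, non-Medicaid, lowest poverty, no comorbidity).
2. **Utilization.**  Encounter counts are negative binomial (default
   mean 13, dispersion size 0.5 — heavily overdispersed, matching
   encounter SDs well above their means in real in-care cohorts) with
   log-linear multipliers: true diabetes ×1.9, true asthma ×1.4, plus
   small demographic effects.  An in-care sample has at least one
   encounter (`min_encounters = 1`).
3. **Documentation.**  Per encounter, independently: a diabetes
   diagnosis code with probability 0.08 *only if truly diabetic*
   (likewise asthma, 0.08); a diabetes-related lab order (0.06, ×1.3
   for Black and Latino patients, ×0.8 for Asian patients, ×2 for true
   obesity — the diagnostic-suspicion block); an endocrinology
   review-of-systems flag (0.06, with a neighborhood random intercept,
   SD 0.3, standing in for catchment-area continuity of care); a routine
   exam flag; a BMI measurement (0.30).  A1c values are Normal(7.5, 1)
   for true diabetics and Normal(5.4, 0.4) otherwise, truncated at 3, so
   the 6.5% threshold is discriminative.
4. **Observation.**  Race/ethnicity is unrecorded with probability 0.19
   (completely at random by default; optionally utilization-dependent);
   BMI is missing if never measured.

Because disease codes and disease-specific prescriptions are emitted only
for true cases, phenotype specificity is exactly 1 by construction and
all misclassification is false-negative, concentrated in low utilizers.

The defaults were chosen once to emulate a large urban academic-center
young-adult cohort: observed diabetes ≈ 2.4%, observed asthma ≈ 4.5%,
observed obesity ≈ 16%, ~39% of records sufficient, mean encounters ≈ 14
(SD ≈ 21) overall and ≈ 45 vs ≈ 13 by observed diabetes status, 19%
missing race, 70–80% with a recorded BMI.  They are a scenario
definition, not estimates; everything is configurable.

## Estimands and estimators

All four strategies model observed diabetes `DM*`.  For the asthma
question the adjustment set is age, sex, race/ethnicity, Medicaid,
*observed* obesity and poverty stratum; for the race/ethnicity question,
age and sex.  Reference levels: White, female, lowest poverty stratum.

* **Naive** — all patients, unweighted.  Subject to the full
  informed-presence confounding of the observed indicators.
* **Sufficiency** — restricted to records flagged sufficient
  (endocrinology review of systems or classified diabetic).  Treats the
  insufficient records' outcomes as missing rather than negative.
  Because every classified diabetic is sufficient, this resembles
  case-control selection: valid for the odds ratio when control
  selection is exposure-independent given the model covariates, biased
  (collider) when utilization drives both selection and exposure.
* **IPW** — the sufficient subset reweighted by stabilized weights
  $w_i = \bar p / \hat p_i$, where $\hat p_i$ comes from a logistic
  sufficiency model on demographics, utilization (log1p encounters,
  duration, routine-exam and lab indicators) and neighborhood.  Robust
  sandwich variance, weights treated as known.
* **DAG** — all patients, with encounter count added to the naive model
  as a proxy for the informed-presence path.

### Why the encounter adjustment uses quartile bins

Encounter count is simultaneously the misclassification driver
(confounder of the observed indicators) and a common *effect* of the two
true diseases (collider).  Empirically, with the overdispersed default
counts, entering `log1p(encounters)` conditions finely enough on the
collider that the adjusted estimate overshoots below the truth by more
than the sufficiency method's residual bias; quartile bins remove the
bulk of the confounding while limiting that amplification, leaving the
smallest absolute bias of the four methods.  `log1p` and `linear`
remain available (`encounter_transform=`).  This is a deliberate design
choice: with a sensitive phenotype or weaker utilization effects the
smooth transform can be preferable, and users comparing transforms are
seeing a real bias-bias trade-off, not a numerical artifact.

### Sufficiency model details

Fixed neighborhood dummies are the default cluster mode: with a few
dozen clusters of hundreds of patients each they are cheap and make the
fit reproducible without integration error.  Neighborhood-level
covariates (the poverty stratum) are then dropped from that model as
exactly collinear with the dummies.  An approximate random-intercept
mode (`lme4::glmer`, `nAGQ = 0`) is available; with a single
neighborhood the cluster term is dropped with a warning.

### Numerical choices

* IRLS convergence: relative deviance change < 1e-10, ≤ 100 iterations;
  fits are performed at mean-normalized weights (point estimates are
  invariant to the weight scale; survey-magnitude weights otherwise
  destabilize IRLS) and variances are computed at the original weights.
* Perfect separation is detected (fitted probabilities collapsed onto
  the outcome, or a coefficient diverging past ±15) and raised as an
  error naming the term; an optional ridge fallback (λ = 1e-4,
  intercept unpenalized) is off by default.
* Wald 95% intervals on the log-odds scale, $z = 1.959964$.
* Stabilized weights error on fitted probabilities of exactly 0 or 1
  unless quantile truncation is enabled (off by default).
* Missing race at fit time: `surrogate_imputation` (default) draws once
  from the generator's known neighborhood-conditional race distribution
  — a stand-in with known probabilities for surname/geocoding-based
  imputation, which is out of scope — seeded from the dataset
  configuration so analysis tables are deterministic; `complete_case`
  drops the rows.

## Survey benchmark

`fit_survey_logistic()` computes the weighted pseudo-MLE and a
Taylor-linearized variance under the with-replacement approximation:
weighted score contributions are summed to PSU totals, centered within
stratum, and scaled by $n_h/(n_h-1)$.  PSU ids are interpreted within
stratum, as in public-use designs.  Single-PSU strata contribute zero
variance with a warning (`single_psu = "center"`) or raise an error.  A
delete-one-PSU jackknife is available and agrees with the linearized
SEs within 10% on small stratified designs in the test suite.  With one
stratum, unit weights and each row its own PSU the fit reduces exactly
to ordinary logistic regression with heteroskedasticity-robust variance
(up to the $n/(n-1)$ factor).

Recipes for the 2019 BRFSS and pooled 2013–March 2020 NHANES public-use
files are shipped as editable YAML: inclusion (ages 18–44; for BRFSS,
having a personal health care provider), diabetes from self-report or —
for NHANES — elevated labs (A1c ≥ 6.5% or fasting glucose ≥ 126),
obesity from BMI ≥ 30, race/ethnicity, insurance and income recodes.
Don't-know/refused handling is an explicit recipe option (`on_unknown`:
drop with a logged count, `na`, or error).  Multi-cycle NHANES weights
must be pre-pooled by the user; cycle-combination rules vary by analyte
and are deliberately not automated.

## The evaluation harness and its reference scenarios

`run_replicates()` runs generate → phenotype → estimate for seeds
`base_seed + 1, ..., base_seed + R` and `summarize_bias()` reports mean
log-OR bias with Monte Carlo SE ($SD/\sqrt R$), empirical and mean
model SEs, and 95% CI coverage of the generating odds ratio.
Non-converged fits are excluded and counted; the run fails if more than
5% of fits are lost.

Two scenarios anchor the test suite:

* **No misclassification** (`config_no_misclassification()`):
  documentation probabilities 1, at least two encounters (so every true
  case can accrue the two codes the rule requires), BMI always
  recorded, race fully observed, and utilization independent of disease
  *and of every covariate* (all encounter multipliers and the
  neighborhood sufficiency SD set to 0).  The independence matters:
  when the probability that a non-case is flagged sufficient is the
  same for everyone, restriction or reweighting shifts only the model
  intercept and all four estimators target the same conditional odds
  ratio.  With covariate-dependent utilization, sufficiency-based
  selection is exposure-dependent and the restricted estimators are
  biased even without misclassification — which would test the
  selection geometry, not estimator correctness.  Under this scenario
  the suite requires all four mean estimates within 3 Monte Carlo SEs
  of OR 1.4 and coverage in [0.92, 0.98] (200 replicates of 20,000
  patients).
* **Default informed presence**: the calibrated defaults above.  The
  suite requires the naive estimate to exceed the truth in ≥ 95% of 100
  replicates, the utilization-adjusted bias to be at most half the
  naive bias, and the restriction/reweighting strategies in between.

Problem sizes used throughout (20,000 patients per replicate; 200/100
replicates; 50,000 patients for the weight-calibration check) are the
package's chosen simulation scale: large enough that Monte Carlo error
is well below the biases of interest, small enough to iterate on.

## What the synthetic benchmark does and does not show

The generator reproduces the *mechanisms* — false-negative-only
misclassification driven by utilization and screening — with all truth
known, so passing tests demonstrate that the estimators behave as
theory predicts under those mechanisms.  Real EHR data differ in ways
the generator deliberately omits: calendar time and care episodes,
correlated documentation across encounters, imperfect specificity,
coded-rather-than-true comorbidity adjustment sets, cross-system record
fragmentation, selection into the cohort itself, and race-dependent
imputation error.  Residual bias in real applications can therefore be
larger or structured differently; the harness's benchmark-referenced
percent differences (`relative_difference()`) are the tool for
comparing against external estimates rather than simulated truth, and
the two references need not coincide.

## Known limitations

* The IPW variance treats weights as known; uncertainty from the
  sufficiency model is not propagated.
* The sufficiency and IPW strategies inherit the assumption that
  classified cases are never false positives; the generator satisfies
  it by construction, real phenotypes only approximately.
* The random-intercept sufficiency mode uses `nAGQ = 0` (penalized
  quasi-likelihood-like accuracy), adequate for prediction of
  $\hat p$, not for inference on its coefficients.
* Raw fixed-width/transport survey file parsing is out of scope; the
  recipes consume pre-converted CSV.
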