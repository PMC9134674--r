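---
title: "Validating the 5A hypothermia mortality score: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating the 5A hypothermia mortality score: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fivea)
```

## The score and its probability model

Accidental hypothermia — an unintentional drop of core body temperature to
35 °C or below — carries high in-hospital mortality, concentrated in older,
frail patients. The 5A score summarises five admission predictors, each
beginning with "A", into a 0–9 point total:

| Predictor | Rule | Points |
|---|---|---|
| Age | 60–69 / 70–79 / ≥ 80 years | 1 / 2 / 3 |
| ADL disturbance | needs partial or total assistance in daily activities | 1 |
| Arrest | cardiac arrest, or systolic blood pressure ≤ 60 mmHg | 2 |
| Acidemia | blood-gas pH in [7.20, 7.35] / below 7.20 | 1 / 2 |
| Albumin | serum albumin ≤ 3.0 g/dL | 1 |

Totals map to four risk bands: 0–3 low, 4 mild, 5 moderate, 6–9 high. Two
band-edge conventions deserve note. The published pH bands leave the exact
values 7.20 and 7.35 unassigned; `fivea_points()` treats both bands as
closed, so pH = 7.20 and pH = 7.35 each earn one point, giving contiguous,
non-overlapping bands over the whole line. The albumin cut-off is stated in
mg/dL in some printed material, but the clinical range of serum albumin
(and the cohort median of about 3.5) make g/dL the only coherent unit; the
package uses g/dL throughout. Cardiac arrest dominates the arrest rule: an
arrested patient scores 2 points regardless of any recorded pressure, and
by registry convention arrest patients carry SBP = 0.

Predicted in-hospital mortality is a logistic function of the total score,
`plogis(intercept + slope_per_point × total)`. The derivation study's
coefficients live in its supplement and are not reproduced here, so the
probability map is *configuration*: `probability_model()` accepts any
intercept/slope pair or a 10-entry per-score lookup table.
`reference_model()` supplies a documented stand-in obtained by fitting a
logistic regression of outcome on score to the exact-table synthetic
cohort described below (for that cohort it yields an intercept near −2.77
and a slope near 0.41 log-odds per point); every probability-dependent
output should be read as conditional on the chosen coefficients.

## Validation battery

`validate_5a()` computes, from predicted probabilities and observed 0/1
outcomes:

* **C-statistic** — (concordant + 0.5 × tied) / (all death–survivor
  pairs), computed by midranks. The interval is a percentile bootstrap over
  patients (default 2000 resamples, seeded) because the source analysis
  does not state its interval method and the bootstrap is assumption-light;
  a DeLong asymptotic interval is available via `ci_method = "delong"`.
* **Brier score** — mean squared prediction error.
* **Nagelkerke R²** — the Cox–Snell likelihood-ratio R² against the
  constant-prevalence prediction, rescaled by its maximum. Because the
  predictions are externally supplied rather than refit, probabilities are
  clamped to [1e−12, 1 − 1e−12] before any log-likelihood.
* **Calibration slope and intercept** — the slope is the coefficient from
  a maximum-likelihood logistic refit of outcome on logit(prediction); the
  intercept is calibration-in-the-large, the intercept of a refit with
  logit(prediction) as a fixed offset. Several intercept conventions exist
  in the literature; the offset form is used because it isolates overall
  over- or under-prediction from the slope. Perfect separation is reported
  as non-converged rather than silently returning huge coefficients.
* **Risk-group table** — per band: n, deaths, observed rate, mean
  predicted probability with a normal-approximation CI of the mean (the
  symmetric intervals printed in validation reports of this kind are means,
  not percentile ranges). Empty bands are kept as n = 0 rows.
* **Smoothed calibration curve** — tricube-weighted local *linear*
  regression of outcome on prediction (default span 0.75), evaluated at
  each distinct predicted value, i.e., one point per attained score. The
  implementation reproduces `stats::loess(degree = 1, surface = "direct")`
  to machine precision, which the test suite uses as an independent
  cross-check.

Whether the original C-statistic was computed on the raw 0–9 score or on
the mapped probabilities is unstated; the two are identical whenever the
probability map is monotone increasing, which every sensible configuration
is, so the package computes it on the probabilities and does not guess
further.

## Decision-curve analysis

`net_benefit()` implements TP/n − (FP/n) · p\_t/(1 − p\_t) with the
positivity rule `prediction ≥ threshold` (ties treat — boundary patients
can flip counts, so the convention is fixed and documented).
`decision_curve()` compares the score model with treat-all, treat-none,
and age-only / body-temperature-only comparators. The comparators are
*univariable logistic refits* on the evaluation cohort, giving each its
best-calibrated probability scale; thresholding the raw covariate would
handicap them by miscalibration rather than by discrimination. The default
grid is 0.01–0.60 by 0.01 — the clinically relevant range for mortality
decisions — and is configurable.

## Missing data

Albumin is typically unmeasured in registry data and is estimated from
total calcium, to which it is linearly related. `albumin_estimator()`
defaults to a slope of 1.25 g/dL per mg/dL — the inverse of the classic
0.8 mg/dL-per-g/dL dependence of total calcium on albumin from the
calcium-correction literature — with the intercept anchored so a typical
total calcium of 9.4 mg/dL maps to 3.54 g/dL. Both numbers are
configuration, and sensitivity analyses should sweep alternative
equations. Estimates are clipped to the plausible 1.0–6.0 g/dL range.
Worst-case scenarios bypass estimation entirely: every patient with
unmeasured albumin receives the albumin point (`worst_case_high`) or not
(`worst_case_low`), bounding every downstream result, since the scenarios
differ by exactly one point per affected patient.

Remaining missing predictors are resolved by `iterative_impute()`, a
chained random-forest imputer: mean/mode initialisation, then field-wise
forest re-prediction in order of increasing missingness until the
normalised change in imputed values stops decreasing (at most 10 sweeps),
fully reproducible under its seed. Observed cells are never altered. This
satisfies the same contract as the missForest procedure without
reproducing its internals — the analysis of interest is downstream of the
imputation, not the imputer itself. Categorical fields outside the score
are not imputed at all; unknown levels are kept as `"Unknown"`.

Scoring itself refuses missing predictors loudly: resolution is the
pipeline's job, and `run_validation()` makes the ordering explicit
(inclusion filter → albumin estimation or worst-case scenario → chained
imputation → scoring → metrics → decision curves).

## The synthetic cohort generator

The registry behind the validation is not publicly deposited, so the
package ships a generator rather than data. Its defaults are the
registry's published marginals: age median 79 (IQR 68–87), 54.9% male,
22% ADL disturbance, 8.9% cardiac arrest, SBP 117 (87–144) mmHg, pH 7.29
(7.18–7.35), albumin 3.54 (3.23–3.77) g/dL, body temperature 30.9
(28.2–33.4) °C.

Design choices, each a fidelity trade-off:

* **Marginals, not moments.** Only medians and IQRs are published, so each
  continuous covariate is drawn from a two-piece (split) normal matched
  exactly to its (Q1, median, Q3) triple — a two-parameter-per-side skewed
  family. Values are clamped at plausibility bounds; clamping only moves
  mass beyond the matched quartiles, so the targets survive. At the 35 °C
  inclusion boundary this leaves a small point mass at exactly 35, which
  real thermometry would smear.
* **Independence.** Covariates are drawn independently — the registry's
  joint distribution is unpublished — except that total calcium is derived
  from albumin by inverting the default estimator plus noise, so the
  albumin–calcium structure the estimation step relies on exists in the
  data. Real age–ADL or arrest–pH correlations are absent, which is the
  main reason passing tests here do not certify performance on real
  registries.
* **Outcomes from the model.** Mortality is Bernoulli from the configured
  probability model applied to each patient's true score, making parameter
  recovery (calibration slope 1, intercept 0) a testable ground truth.

`exact_table_cohort()` is different in kind: a *deterministic* assembly of
1139 patients reproducing the published risk-group × outcome table —
483/334/193/129 patients and 60/59/63/89 deaths in the low/mild/moderate/
high bands (271 deaths, 23.8%). Within a band, patients are spread
uniformly over the band's score values and deaths over score cells by
largest-remainder apportionment (only band totals are published).
Covariates come from per-score templates verified to round-trip through
the scoring rules to exactly their target score. This cohort anchors the
tests that check the pipeline reproduces the printed table bit-exactly,
and is the fitting data for `reference_model()`.

## Numerical choices and problem sizes

Probabilities are clamped before logs; local-regression weight matrices
fall back to a weighted mean when the local design is degenerate (all
neighbours at one x); the bootstrap and every simulation save and restore
the caller's RNG state so seeded pipelines compose. Monte-Carlo test sizes
were chosen so each check's tolerance is roughly three standard errors at
that n: marginal checks at n = 50 000 (±2%), calibration recovery at
n = 5000 (±0.15 on slope and intercept), imputation RMSE at n = 800 with
10% holes, decision-curve dominance at n = 6000. The whole suite runs in
well under a minute on one CPU.

## Known limitations

The reference probability model is a stand-in fitted to band-level counts,
not the derivation study's patient-level coefficients; registry-level
quantities that depend on those coefficients (the published C-statistic of
0.736, the predicted band probabilities) are therefore not reproduced
here, only the machinery that would compute them given the real
coefficients and data. The generator's independence assumption understates
real covariate clustering, and the smoother is evaluated only at attained
scores — ten support points at most — so curve shape between scores is
interpolation.
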