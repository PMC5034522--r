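---
title: "Correcting self-report bias in adolescent height and weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correcting self-report bias in adolescent height and weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmicorrect)
```

## The model and its assumptions

Adolescent self-reported (SR) height and weight carry systematic bias:
height tends to be over-reported and weight under-reported, most strongly
among those with overweight or obesity. Where a survey wave contains both
measured and self-reported anthropometrics, the conditional expectation of
the measured value given self-report and covariates can be estimated and
then applied to waves that carry self-report only.

`bmicorrect` models that conditional expectation as a single linear
equation per outcome,

$$\mathrm{measured} = \beta_0 + \beta_1\,\mathrm{SR} +
  \boldsymbol{\beta}^\top \mathbf{x} + \varepsilon ,$$

fitted separately for weight and height by probability-weighted least
squares. The covariate vector $\mathbf{x}$ holds age in months, perceived
pubertal timing (1–5), weight status implied by the self-reported BMI
(UW/HW/OW/OB, reference HW), body-size self-estimation (collapsed to
UW / about-right / OW, reference about-right), a dieting indicator,
depressive symptoms (CES-D, 0–60), self-rated health (1–5), self-esteem
(1–5), race/ethnicity (reference White), sex (reference male), and parent
education (reference college degree). Class variables are dummy-coded so a
single equation serves all subgroups.

Assumptions worth stating plainly: the measurement relationship is linear
on the chosen scale; residuals are homoskedastic enough for AIC and
model-based standard errors to be informative; and — crucially when the
equation fitted on one wave is applied to an earlier one — the reporting
behaviour is stable across waves. Covariate values of the application wave
are used as-is. The correction is conservative by construction: it shifts
predictions toward the conditional mean and cannot repair idiosyncratic
large discrepancies.

## Published coefficients and their unit system

`published_models()` bundles a published final coefficient pair (weight
model $R^2 = 0.91$, height model $R^2 = 0.89$) at its printed two-decimal
precision. Two encoding decisions were genuinely open:

* **Units.** The source tables do not state the measurement units of the
  equations. The survey's native pounds/inches are assumed; the unit
  system is an explicit, serialised model attribute (`units`), cohort
  storage is always metric (cm/kg), and conversion happens inside
  `apply_model()` using exact definitions (1 in = 2.54 cm,
  1 lb = 0.45359237 kg). Predictions from the printed coefficients carry
  rounding error of order 0.005 times the covariate magnitudes, so exact
  reproduction of the original study's corrected values is not possible
  from the printed table alone.
* **Parent education.** The printed height model shows a single
  coefficient (0.08) against the college-degree reference although the
  covariate has three levels. It is encoded here as one "below college
  degree" indicator; refits treat parent education as a full three-level
  class variable.

The height model's sex coefficient (0.65) is the female indicator against
the male reference. The weight model omits race/ethnicity, sex, and parent
education entirely (removed during the original selection); the height
model retains individually non-significant race levels because the class
variable as a whole contributed.

Models serialise to versioned JSON (`format: 1`) with coefficients stored
as decimal strings, so published values round-trip bit-exactly and refit
models round-trip through full-precision (`%.17g`) strings.

## Weight-status classification

BMI is weight/height² (kg/m²; the imperial convention 703·lb/in² is also
provided). Below 240 months of age, classification goes through
BMI-for-age: the LMS transform
$z = ((\mathrm{BMI}/M)^L - 1)/(LS)$ (log branch at $L = 0$) against a
sex/age reference table, percentile $= 100\,\Phi(z)$, and the half-open
cutoffs UW < 5th ≤ HW < 85th ≤ OW < 95th ≤ OB. At 240 months and above,
adult BMI cutoffs apply with inclusive lower bounds
(18.5 / 25 / 30, WHO convention; the source tables only pin down
"BMI ≥ 25" and "BMI ≥ 30").

Numerical choices: LMS parameters are interpolated *linearly in age*
between tabulated rows (reference implementations do not document their
exact scheme; discrepancies are sub-percentile), and queries outside a
table's covered age range raise an explicit range error rather than
extrapolating — ages 19–20 at a chart's edge are surfaced to the user, not
silently clamped.

## Fitting, selection, and screening conventions

* **Weights.** Sampling weights are probability weights, normalised to sum
  to $n$ inside the pseudo-log-likelihood, making AIC invariant to weight
  scale. $\mathrm{AIC} = 2k - 2\log L$ with $k$ counting intercept, slopes,
  and the error variance. Model-based standard errors
  $\widehat{\mathrm{Var}}(\hat\beta) = s^2 (X^\top W X)^{-1}$ are used;
  design-based (stratum/PSU) variance is out of scope.
* **Selection.** Backward elimination over whole blocks: at each step the
  single block whose removal lowers AIC the most is dropped; elimination
  stops when no removal lowers AIC. The self-report analogue of the
  outcome is mandatory. Determinism is fixed by evaluating blocks in
  declared order and keeping a block on an exact AIC tie.
* **Interactions.** "Significant predictors" eligible for two-way
  interaction screening are the blocks retained by selection (not p-value
  thresholds — the published models themselves keep individually
  non-significant terms as contributing factors). All pairwise product
  blocks are tested by the same AIC rule, added greedily, and kept only if
  AIC decreases.
* **Missing data.** Complete cases only, mirroring the source study's
  analytic-sample construction; dropped counts are reported
  (`n_dropped`), and nothing is imputed.
* **Pooled vs sex-specific.** The published equations are pooled with sex
  as a covariate; because sex-specific estimates are sometimes preferred,
  `fit_stratified()` refits the full pipeline within each sex. Neither
  mode is asserted as canonical.
* The schema accepts self-esteem scores on 1–5; source descriptions of
  that instrument are internally inconsistent (4-point scoring vs 1–5
  response categories), so the wider range is taken and consumed as a
  score.

## Evaluation conventions

Misclassification tables are oriented rows = assigned (SR or corrected),
columns = reference (measured); "above the diagonal" therefore means the
reference status exceeds the assigned one, i.e. underestimation. Cells are
weighted percentages summing to 100 (tolerance 1e-9 internally; re-entered
printed panels, which round to one decimal, use a looser constructor
tolerance). Under + over + diagonal = 100 exactly.

Threshold diagnostics dichotomise both BMI axes at the cutoff (positive =
BMI ≥ threshold), with weighted cells. Confidence intervals use the Wilson
score method by default (better small-sample behaviour than Wald);
Clopper–Pearson is available by flag. The effective sample size behind an
interval is Kish's approximation $(\sum w)^2 / \sum w^2$ on the relevant
margin. Published CIs may derive from survey-design methods, so small
discrepancies against re-computed intervals are expected. Display rounding
is one decimal for table percentages and three for diagnostics; internal
values are never rounded.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` emulates the validation-wave design: ages 144–263
months (the study population's 12–22 years; ages ≥ 240 months use adult
cutoffs), even sex split, heights from per-sex age curves, and BMI drawn
*through* the LMS reference itself (a z-score with mean 0.25 and SD 1.1,
giving obesity prevalence near the 10% range reported for this
population). Drawing BMI through the reference guarantees cohort and
reference are mutually consistent; z-scores are truncated to [−3.5, 3.4]
to keep the Box–Cox transform inside its domain, a tail distortion of
order 10⁻³ in probability.

Self-report bias defaults are seeded from published stratum means: female
weight under-report of 1.02 kg in the OW and OB strata (0.5 kg at HW, 0 at
UW) and male 0.19 kg (0.1 / 0), rising with status as the literature
reports; height over-report of 0.7 cm for both sexes; reporting noise SDs
of 1.5 kg and 1.2 cm. Dieting and an "overweight" body-size
self-assessment add 0.4 and 0.3 kg of further under-report, so covariates
carry correctable signal. Covariates are generated with declared loadings
on true status (logistic for dieting, Gaussian with clamping for CES-D,
self-rated health, and self-esteem; a noisy coarsening of true status for
body-size estimation); race/ethnicity and parent education follow
plausible population proportions and carry *no* generative effect — which
is what makes them honest noise blocks for selection tests. Sampling
weights are log-normal (SD 0.3). These generative forms are package
inventions, documented so tests state their own assumptions; they claim no
fidelity to any real survey's joint distribution.

All randomness flows from one seed through per-variable substreams, so
adding a covariate leaves earlier draws unchanged and cohorts are
byte-identical across runs. Not emulated: school-cluster sampling
structure, realistic population pyramids, longitudinal growth
trajectories, item non-response patterns. Passing tests on these cohorts
demonstrates the *machinery* — encoding, estimation, selection,
classification, evaluation — under a known generative model; it does not
demonstrate that any particular coefficient set transfers to a real
population.

## Parameter-recovery design

The recovery harness (`oracle_refit_check()`) constructs the outcome as an
explicit linear function of generated design columns plus Gaussian noise
(SD 4 kg), rather than regressing measured weight on the bias generator's
self-reports: reporting noise on the regressor side attenuates slopes
(errors-in-variables), so only a forward-simulated outcome admits exact
recovery claims. At n = 10 000 all generative slopes are recovered within
3 standard errors, and a pure-noise five-level class variable is excluded
by AIC in the large majority of replicates (the theoretical exclusion
probability for a 4-dummy block is $P(\chi^2_4 < 8) \approx 0.91$). The
test and acceptance workloads use n = 10 000 with 20 replicates for
exclusion rates and 10 seeded cohorts of n = 4 000 for the
direction-of-effect check; these sizes put Monte-Carlo error comfortably
below the margins being asserted.

## Known limitations

* The printed coefficient precision bounds how faithfully the bundled
  equations can reproduce the original corrected values (order 0.1 lb /
  0.1 in for typical covariate ranges).
* Probability-weighted point estimation only; variance estimation under
  complex survey designs (strata, PSUs, Taylor linearisation) is
  deliberately out of scope.
* The correction targets the conditional mean: it improves sensitivity for
  overweight/obesity detection but offers little for underweight or
  healthy-weight identification, and should be applied selectively.
* The growth reference is an input; the bundled generator produces a
  synthetic one for testing, and users supply a real table (CDC-layout
  CSV, `sex,agemos,L,M,S`) for substantive work.
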