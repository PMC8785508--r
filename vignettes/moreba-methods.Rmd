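---
title: "MOREBA: model, scoring rules and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MOREBA: model, scoring rules and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moreba)
```

## The scoring model

MOREBA treats musculoskeletal-disorder risk as driven by a latent *strain*
construct onto which 14 physical risk factors load. The structural model
behind the method estimates a standardized loading (direct effect) for
each factor and a single strain-to-symptoms path coefficient of 0.783; a
factor's equation weight is the product of the two (its indirect effect on
symptoms). The score is then a plain weighted sum of the observed factor
values:

```{r}
moreba_weights()
```

Two modelling assumptions matter in practice. First, linearity: a one-step
increase on any rating scale contributes the same amount to the score
wherever it occurs, which makes the score strictly monotone in every
factor (a property the test suite checks by perturbation). Second,
compensability: high exposure on one factor can be offset by low exposure
elsewhere — there is no interaction or max-type aggregation, unlike the
lookup-table logic of classic REBA.

### Factor scales

The two posture factors are the classic REBA table A (trunk/neck/legs) and
table B (upper arm/lower arm/wrist) outputs, taken *without* REBA's
load/coupling adjustments: the published account estimates group scores
"by tables of the REBA method" and then rates load, force and coupling as
separate factors, so adding REBA's adjustments on top would double-count
them. This reading is a design decision of this package; the source text
does not state it explicitly.

The remaining factors are 0–4 ratings. Two are derived sub-scores with
unit-bearing rubrics:

* load: `L = (t_L * W_L) / 4`, carrying time (0 = never … 4 = over 6 h)
  times maximum load weight (0 = under 5 kg … 4 = over 20 kg);
* force: `F = (t_w * V_F) / 4`, work time (0 = under 2 h … 4 = over 8 h)
  times maximum force (0 = under 1 kg … 4 = over 6 kg).

The published work-time rubric lists "4 to 6 h" for rating 2 and
"4 to 8 h" for rating 3; the package documents rating 3 as 6–8 h, the only
reading that keeps the scale ordered and non-overlapping. The product form
means a heavy load carried never, or a trivial load carried all day, both
contribute nothing — exposure requires magnitude *and* duration.

Profiles are validated against these closed integer ranges; both posture
scores accept 1–9 (the full range a REBA table can emit), with a warning
for posture B above 8 because the development cohort never observed 9
there.

### Risk classification

The default cutoffs 12.37, 16.51 and 24.35 partition scores into four
levels. The published cutoff table ("12.37 to 16.50", "16.51 to 24.35")
leaves the semantics of a continuous score between 16.50 and 16.51
implicit; `classify_risk()` realizes the partition as
low `< 12.37 <=` moderate `< 16.51 <=` high `<= 24.35 <` very high,
which is total and disjoint over the real line and reproduces every
printed anchor. Cutoffs are data (`moreba_thresholds()`), not code, as are
the equation weights (`inst/extdata/moreba_weights.json`), so alternative
coefficient sets can be loaded without touching the package.

### Rounding

Printed coefficients carry three decimals, so derived weights are rounded
half-up (half away from zero) at three decimals — `round_half_up()` rather
than R's banker's rounding — which reproduces all 14 published indirect
effects exactly. Scores in output tables are reported to three decimals;
internally full precision is kept.

## Classic REBA and the comparison bridge

The REBA lookup tables A, B and C ship as plain-text CSV fixtures
(transcribed from the original REBA publication, with provenance noted in
each file) and `reba_score()` runs the standard chain: table A + load/force
→ score A, table B + coupling → score B, table C, + activity → final score
1–15. `reba_action_level()` condenses REBA's five published action levels
to four by merging the two lowest (scores 1–3), since four-level
side-by-side comparisons need a common grid; the breakpoints are
configurable because the original five-to-four binning used for published
comparisons is not documented.

Synthetic cohorts carry factor profiles, not joint-level observations, so
classic REBA is reconstructed from the profile by `reba_from_profile()`:
posture table scores pass through unchanged, maximum load weight maps to
REBA's 0–2 load/force adjustment (+1 shock when rapid/sudden movement is
rated 3+), coupling is capped at 3, and the activity adjustment adds one
point each for static, repetitive or rapid activity rated 2+. This bridge
is artifact plumbing for the method comparison, not part of either
published method.

## CMDQ scoring

Per body region the questionnaire's frequency, severity and interference
answers are weighted (0/1.5/3.5/5/10, 1–3, 1–3) and multiplied, then
summed over regions; totals are banded at 450, 900 and 1350. Band
boundaries are taken left-closed (a total of exactly 450 is band 2) — the
source does not state inclusivity, so this is a documented convention,
configurable via the `boundaries` argument. Both a 12-region and an
18-region bilateral layout are provided (`cmdq_regions()`): the instrument
is described with 12 regions, yet observed totals above `12 * 90 = 1080`
imply bilateral items were scored; the exact region list behind the
observed maximum is not derivable and is deliberately left configurable.

## The synthetic cohort generator

`generate_profiles()` emulates the *distributional shape* of the
development cohort — 300 male steel-factory workers — via a Gaussian
copula: latent multivariate-normal draws with the published 14×14
inter-factor correlation matrix, each margin discretized onto its integer
scale using truncated-normal cell probabilities with the published
mean/SD. Two calibrations are worth spelling out:

* **Moment-matched locations.** Discretizing a truncated normal whose raw
  location equals the target mean biases skewed margins upward (factors
  sitting near the scale floor, e.g. coupling, by up to +0.2). The
  generator therefore root-finds the latent location per factor so the
  *discretized* mean equals the target; SDs are used as printed. Sample
  means at n = 10 000 then sit within ±0.1 of every target.
* **Latent-scale correlations.** The copula correlation is specified on
  the latent scale; discretization attenuates it (the posture A–B
  correlation of 0.843 is observed around 0.82), which is why fidelity
  checks use a ±0.07 band. An optional iterative pre-inflation step
  (`inflate_latent = TRUE`) compensates; it is off by default so that the
  published matrix is used as-is.

The typed-in correlation matrix is checked for positive semi-definiteness
and repaired by eigenvalue clipping only for mild rounding-induced
indefiniteness (smallest eigenvalue above −0.05); as typed it is already
positive definite, so the repair is a guard. Load and force factors are
decomposed back into raw components by pegging the time rating at 4
whenever the factor is non-zero, so the sub-score reproduces the drawn
value exactly — a convenience, not a claim about real time/weight joint
distributions.

CMDQ outcomes come from a latent-strain model: the MOREBA score itself is
the strain, and the outcome is affine in it plus Gaussian noise,
`y = a + b s + e`. Slope and intercept target the published outcome mean
and SD (536.82, 511.51); the noise SD follows the closed form
`sd(e) = sqrt(b^2 var(s) (1 - R2) / R2)` so the infinite-sample OLS R²
equals `target_r2` (default 0.67). Negative draws are floored at 0,
matching the instrument's minimum; at the default calibration about 15%
of draws floor, which attenuates the measured R² by roughly 0.015 —
still within the ±0.03 calibration-recovery band the tests enforce. The
published CMDQ-to-factor correlations are *not* used to drive the
outcome; the latent-strain model replaces them by construction.

What the generator does **not** emulate: demographic covariates (age, BMI
— the underlying structural model does not use them), measurement error in
the ratings, within-worker task heterogeneity, or any non-linear
dose-response. Consequently, pipeline results on synthetic cohorts —
including the MOREBA-vs-REBA R² gap, which is partly built in because the
outcome is generated from the MOREBA score — demonstrate that the
machinery is correct and stable, not that the method generalizes to new
field data.

## Validation computations

* `sample_size()` implements the standard Fisher-z formula
  `n = ((z_a + z_b) / w)^2 + 3`. As typeset in the source the z-sum/w
  ratio is not squared, which would give ≈ 82, contradicting the printed
  minimum of 259; the squared (textbook) form with the printed
  `w = 0.203` reproduces 259 and is what the package implements. The
  unrounded transform `fisher_z(0.2) = 0.20273` gives 260, so the
  function accepts a `w` override for printed-precision inputs.
* `auc()` is the Mann–Whitney estimator (midranks, ties counted half);
  the suite pins it against an exhaustive pairwise oracle at n ≤ 12 and
  against an established ROC implementation at n = 200.
* `optimal_cutoff()` takes candidate thresholds at midpoints between
  consecutive sorted unique scores, predicts positive at
  `score >= threshold`, and minimizes the Euclidean distance to the ideal
  (sensitivity = specificity = 1) corner — the source names
  "nearest to the ideal state" but no metric; Euclidean is the default,
  Youden's J an alternative. Exact ties break toward the lower cutoff.
* `derive_thresholds()` binarizes the CMDQ total at each band boundary
  (positive = at or above) and demands three strictly increasing finite
  cutoffs; degenerate inputs (a band with a single outcome class,
  constant scores) are errors, not silent results.
* `r_squared()` is the squared Pearson correlation (one-predictor OLS
  R²); zero-variance input returns 0 with a warning by convention.
* `measurement_quality()` computes AVE = mean(λ²) and
  CR = (Σλ)² / ((Σλ)² + Σ(1−λ²)) from the loadings. On the packaged
  loadings these evaluate to ≈ 0.483 and ≈ 0.923; the published rounded
  values are 0.50 and 0.91, consistent at the precision three-decimal
  loadings allow, which is why the tests use a ±0.03 band.

## Problem sizes and determinism

Generator fidelity and calibration checks run at n = 10 000, where
binomial noise on a 0–4 mean is well under the ±0.1 band; cutoff-stability
checks use 20 cohorts of n = 300, the development-cohort size; oracle
comparisons enumerate n ≤ 12. Every stochastic step is driven by a single
integer seed (`population_spec(seed = )`), and a fixed spec reproduces its
cohort bit-for-bit; output files record package version, seed and a config
fingerprint in their headers.

## Known limitations

* The equation weights are consumed as published; the structural model is
  not re-estimated, and model fit indices are out of scope.
* The four-level REBA binning and the profile-to-REBA bridge are
  conventions of this package, configurable but unvalidated against field
  practice.
* Synthetic validation cannot reproduce field operating points (published
  per-band AUCs and regression fits were estimated on the unreleased
  development data); it checks internal consistency and stability only.
* The CMDQ region list that yields the published observed maximum total
  is not derivable from the available description; both shipped layouts
  are approximations.
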