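---
title: "Shoot-chamber flux inference and driver analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shoot-chamber flux inference and driver analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shootflux)
```

This vignette documents the science implemented in `shootflux`: the flux
model and its assumptions, the tunable parameters and their defaults, what
the synthetic-data generator does and does not emulate, the numerical
choices, and the places where the design was genuinely open and a decision
had to be made.

## The measurement and its model

A conifer shoot is sealed in a transparent chamber (5.2 l including the
analyser loop); headspace air recirculates through a greenhouse-gas
analyser for 7–10 minutes. Under the non-steady-state chamber assumption —
well-mixed headspace, constant air amount `n = pV/(RT)`, emission constant
over the short closure — the dry CH₄ mixing ratio evolves linearly and the
chamber flux is

F = dC/dt · (pV/RT) · M · 3600,

with dC/dt in mol fraction s⁻¹, M the molar mass (1.604 × 10¹⁰ ng mol⁻¹
for CH₄, 4.401 × 10⁴ mg mol⁻¹ for CO₂), p assumed 101 325 Pa and T the
sample temperature entering the analyser, averaged over the fitting
window. The ppm → mol-fraction factor (10⁻⁶) is applied inside
`fit_linear_slope()`; this is the only reading under which the constants
above are dimensionally closed, and it is fixed as the internal slope
unit.

CO₂ is taken up by the shoot, so its trajectory saturates toward an
asymptote; `fit_exponential()` fits C(t) = C_lim + (C₀ − C_lim)·e^(−kt) by
Levenberg–Marquardt and the flux-relevant quantity is the initial slope
−k·(C₀ − C_lim). When k·duration is small the trajectory is numerically
indistinguishable from a line (a ridge in (C_lim, k) space); the initial
slope is still identified, and if the optimizer degenerates the function
falls back to the linear slope with `converged = FALSE`. The fit is
unconstrained in sign: uptake versus emission is carried by (C₀ − C_lim).

Dry-weight normalization divides the chamber flux by the needle mass in
the chamber on that date: m(date) = m_Y1 + rel(date) · m_Y0,final, where
the current-year (Y0) cohort grows over the campaign. Relative growth is a
two-parameter logistic in cumulative growing degree days above 5 °C,
min–max rescaled so it is 0 at the campaign start and exactly 1 at the
end; when measured shoot elongation exists it takes precedence, linearly
interpolated between observation dates. The logistic form is a design
decision: the cited elongation model is not reproduced in the source, and
a minimal monotone S-curve in thermal time with exposed parameters
(midpoint `g50 = 150` °C·day, steepness `0.03` per °C·day) is the least
committal choice consistent with degree-day-driven elongation.

## Water-vapour spectral interference

The analyser's internal water correction leaves a residual cross-talk:
reported dry CH₄ drifts by a factor f (ppm CH₄ per ppm H₂O) as humidity
rises. The correction is pointwise, CH4_corr = CH4_raw − H2O·f, linear
and exactly invertible. `estimate_f()` reproduces the calibration
protocol: replicated water injections into a small dry chamber sweep H₂O
over ≥ 5000 ppm while true dry CH₄ stays constant; f is the mean of
per-replicate OLS slopes with a t-distribution CI of the mean. Whether the
original estimate pooled replicates or averaged slopes is not documented;
both modes are provided (`method = "mean_of_slopes"` (default) or
`"pooled"`) and the mode used is recorded in the calibration object.

The synthetic injection runs include a between-replicate slope scatter
(`run_effect_sd`, default 4.3 × 10⁻⁸): replicate injections differ through
mixing and residual droplets, and this scatter — not analyser noise —
dominates the width of a realistic 6-replicate confidence interval.
Replicate slopes are iid around the true factor, so CI coverage is
unaffected.

## Trimming and quality control

Field practice adjusts each closure's fitting window graphically, cutting
the initial mixing transient and any segment disturbed by leakage or
mis-recorded closure times. Reproducibility demands an algorithm, so
`trim_closure()` automates the judgement:

1. a fixed deadband (default 30 s) is always removed;
2. a provisional robust line is fitted by the repeated-median estimator
   (50 % breakdown, deterministic; series longer than 200 points are
   thinned for the O(n²) pairwise slopes since the fit is only
   provisional);
3. the noise scale σ is estimated from *differenced* residuals
   (MAD(Δr)/√2) so that the structure to be removed does not inflate its
   own threshold;
4. leading/trailing runs whose rolling residual median exceeds `mad_k`·σ
   (default 4) are cut back with hysteresis to where they first left the
   1σ band, so an unstable segment is removed from its onset;
5. steps 2–4 iterate to convergence. The window is half-open
   `[t_start, t_end)` in seconds from closure start; trimming never widens
   the window and is idempotent.

QC (`qc_closure()`) labels rather than deletes, with three explicit,
configurable rules standing in for an unspecified "poor data quality"
criterion: post-trim span < 120 s; robust residual spread above
`spread_max_ppm` (default 0.01 ppm, ~7× the default analyser noise);
systematic curvature (quadratic peak deviation) above `drift_k`× the
residual MAD. On noiseless synthetic closures the pass rate is 100 %.
Trimming and QC operate on the interference-corrected CH₄ when available —
`run_process()` corrects first — because with very low noise the smooth
H₂O cross-talk component would otherwise register as structure.

## Background and detection limits

Chamber materials emit a small apparent CH₄ flux. `fit_background()`
regresses empty-chamber fluxes on global radiation (diagnostically also on
air temperature and time) and selects, via a two-sided t-test on the
radiation slope at α = 0.05, either a radiation regression (background
predicted per closure from its mean global radiation) or the campaign
mean. Subtraction happens on the chamber scale, before dry-weight
normalization, so it cancels identically between shoots measured under
equal radiation.

The detection-limit ladder is: per chamber, 3× the sample SD (n−1) of the
empty-chamber fluxes after their own H₂O correction and without background
subtraction; per measurement, divided by the species' average shoot dry
weight; per period, further divided by √n replicate closures. Full
precision is carried internally. Report rounding follows "3 significant
figures, capped at 2 decimal places": plain 3-significant-figure rounding
reproduces all published-style values except the smallest per-period limit
(0.7318 → 0.732, conventionally displayed 0.73), and the 2-decimal cap
reproduces every value. The two campaigns' per-chamber limits appear with
swapped year labels in running text versus the tabulated ladder in the
source material; the package follows the tabulated assignment
(120.9 ng h⁻¹ with the 23.6 g pine year), which is the only one consistent
with the printed per-measurement values (120.9/23.6 = 5.12).

## Driver statistics

All repeated-measures models use a per-tree random intercept, fitted by
REML with `lme4`. Fixed effects are tested with Wald z statistics — the
named design choice; with as few as 4 trees these are mildly liberal
(simulated type-I error ≈ 5.5–6 % at nominal 5 %), which the calibration
tests bound within their Monte-Carlo bands. When the grouping factor has
one level, or the response is degenerate, the fit reduces exactly to OLS
and is flagged.

- `compare_period_means()`: 2-week chronological bins (half-open, anchored
  at the first measurement date), Tukey simultaneous tests on period means
  via `multcomp::glht`, encoded as a compact letter display. Tukey
  family-wise correction is the standard pairing with a CLD.
- `ttest_vs_empty()`: Welch's unequal-variance t-test per shoot on
  chamber-scale, background-uncorrected fluxes (shoot and empty-chamber
  variances clearly differ; the comparison against empties must happen
  before subtracting the empty-derived background). This convention is
  recorded in the analysis report metadata.
- `par_split_regression()`: temperature response fitted separately below
  and above 500 µmol m⁻² s⁻¹ PAR; rows at exactly 500 belong to both
  strata, matching the overlapping "≤ 500 and ≥ 500" convention.
- `temp_bin_interaction()`: PAR × temperature-bin interaction with Helmert
  contrasts (each bin's PAR slope versus the mean of colder bins), bins of
  5 °C from 0–20 °C, sparse bins (< 5 rows) merged into their colder
  neighbour; per-bin slopes and SEs come from linear combinations of the
  fitted coefficients and their covariance.
- `residual_disentangle()`: the two residual regressions (flux~T residuals
  on PAR and vice versa) that separate collinear drivers.

## The synthetic campaign generator

The generator is the package's ground-truth source, and its defaults *are*
the emulated study conditions:

- **Schedule**: 4 pine + 3 spruce chambers, 3 measurement days per week, 3
  rounds per day, an empty-chamber control leading every round; all pines
  per round with a 0.18 skip probability and one spruce per round in
  rotation. Over 6 weeks this yields ≈ 180 pine, 54 spruce and 54 empty
  closures, matching the reported first-campaign totals (181/53/55).
- **Emission truth**: F = base + (α₀ + α₁·T_air)·PAR + tree intercept, in
  ng gDW⁻¹ h⁻¹, with α₀ = 0.002, α₁ = 0.0002 (PAR slope 0.004 at 10 °C,
  the first campaign's fitted value), base 1.1, tree-intercept SD 0.5.
- **Background**: every closure — empty or shoot — includes the
  chamber-material emission, mean 27.4 ng h⁻¹ with closure-to-closure SD
  40 ng h⁻¹ (reproducing the reported empty-chamber mean ± SE and the
  ~120 ng h⁻¹ per-chamber detection limit); optionally
  radiation-dependent.
- **Closure physics**: dry CH₄ accumulates linearly at the rate implied by
  inverting the flux equation (optionally with first-order leakage toward
  ambient, default off — leakage is only qualitatively attested); CO₂
  follows the exponential model; H₂O rises as a saturating exponential
  toward a dew-point ceiling (Magnus formula), mirroring loop air
  approaching saturation; the *reported* CH₄ adds f_true·H₂O(t); Gaussian
  analyser noise (CH₄ SD 0.0015 ppm, the typical 1-s precision of this
  analyser class; CO₂ SD 0.5 ppm) is added last.
- **Meteorology**: clipped diel PAR sinusoid with a seasonal ramp and
  lognormal day-level cloudiness; air temperature as seasonal ramp +
  phase-shifted diel cycle + noise, with configurable day-level coupling
  to cloudiness; global radiation = PAR / 2.1 µmol J⁻¹ with small
  proportional noise — only the collinearity (R² > 0.97) matters to the
  analysis. Sample temperature during a closure is held at ambient: any
  within-closure chamber warming is unquantified in the source setting
  and is deliberately not simulated.

What the generator does **not** emulate: needle-temperature dynamics,
stomatal or radiative-transfer processes inside the chamber, instrument
drift beyond the linear H₂O term, autocorrelated weather beyond the
diel/seasonal structure, or ecological differences between species other
than biomass and scheduling. Passing round-trip tests therefore show that
the *pipeline* is correct and well calibrated under the stated noise
model — not that real campaigns are free of the unmodelled effects.

## Numerical choices and degenerate inputs

- Seeds: every generator takes an integer seed and runs on a private RNG
  stream, so identical configuration + seed gives byte-identical output
  and library calls cannot perturb the sequence.
- Time base: seconds from closure start; all windows half-open.
- Linear fits use the closed-form centered OLS expressions; the
  exponential fit initializes C₀ from the first value, C_lim from the
  last, k from the linear-slope decrement, with a floor of 10⁻⁸ s⁻¹ and a
  fallback to the linear slope on the degenerate ridge.
- `fv_fm()` implements (F_m − F₀)/F_m — the universal definition — for the
  ambiguously typeset fluorescence ratio, and rejects F₀ > F_m.
- Degenerate inputs: constant GDD is "no growth signal" (error rather than
  a silent constant); identical samples give t = 0, p = 1; a constant
  response collapses the mixed model to OLS with zero residual SD; QC
  never raises.

## Problem sizes used in the shipped checks

The test suite and acceptance script use 1–6-week synthetic campaigns
(≈ 50–280 closures), 200-closure recovery batches, 500-repeat calibration
coverage runs, and 150–300-repeat null/power simulations with 120–400
rows. These sizes give Monte-Carlo standard errors of ~1 percentage point
on rates near 5 % while keeping any single check in seconds to a couple of
minutes.

## Known limitations

- Wald z inference is mildly anticonservative with very few trees; a
  Satterthwaite correction could be layered on where exact sizes matter.
- The trimming algorithm assumes at most one unstable segment per edge;
  pathological closures with interior artefacts are left to the QC spread
  and drift rules.
- The background model is campaign-pooled, not per chamber, and the
  pressure is assumed constant at 101 325 Pa.
- Real-data regression coefficients from the source campaigns are not
  reproducible without the archived deposit; the file-ingest path accepts
  its dialect through a column mapping, and all quantitative checks run on
  synthetic ground truth instead.
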