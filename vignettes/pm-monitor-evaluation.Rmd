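---
title: "Evaluating and correcting low-cost PM monitors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating and correcting low-cost PM monitors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmevalkit)
```

## The problem

Low-cost optical PM2.5 monitors estimate mass concentration from scattered
light, which makes their response depend on everything that changes the
optical properties or dynamics of the aerosol: the material (refractive
index, density, shape), the exposure pattern, temperature, relative
humidity, the power source, slow drift, and unit-to-unit manufacturing
variation. At high concentrations many sensors additionally *roll over*:
the reported value declines while the true concentration still rises, so
the monitor-versus-reference relation folds into a "half-circle" in which
one reference value corresponds to two monitor values. Before such devices
can be used for occupational exposure screening (a 0–5000 µg/m³ respirable
range with a ≤50% relative-uncertainty target is a reasonable working
envelope), a laboratory evaluation must (i) find the concentration range
in which the output is usable at all, (ii) decide which *evaluation
variables* actually affect the readings, (iii) build a correction model
that maps monitor output back to reference concentration, and (iv) verify
the corrected accuracy. pmevalkit implements that workflow end to end,
together with a fully specified simulator of the chamber experiments it
consumes, so every stage is testable without access to laboratory data.

## The chamber simulator

`simulate_experiment()` generates one experiment from a true-concentration
profile (plateaus at 333/666/1000/2500/5000 µg/m³ held ≥15 min, or
transient 0→5000→0 µg/m³ peaks over ~30 min, three per experiment by
default, at a 15 s sampling cadence — the reference instrument's native
rate). The reference reading is `true * (1 + e)` with `e` i.i.d. normal,
SD 0.10 — the manufacturer-style 10% relative uncertainty. The monitor's
expected reading below any rollover limit is `G * true` with

```
log G = log(base_gain * material_gain)
      + temp_slope * (T - 20) + rh_slope * (RH - 50)
      + power_shift * 1{battery} + pattern_shift * 1{transient}
      + drift_slope * session_hours + unit_effect,
unit_effect ~ N(0, device_sd^2)
```

so every condition acts multiplicatively on the response (equivalently,
additively on the log scale, which keeps simulated readings positive).
Readings are multiplied by mean-one log-normal noise with coefficient of
variation `noise_cv`; the default 0.15 is a mid-range value for consumer
optical sensors (good units are nearer 0.10, poor ones 0.25). Above a
rollover limit `L` the expected reading declines linearly,
`g(L) - k (true - L)` clipped at zero, with `k` equal to the pre-rollover
slope by default — a smooth symmetric fold that reproduces the half-circle
shape. Gravimetric samples are the time-average of the true concentration
with 3% relative noise (a typical filter-weighing precision; the
evaluation does not hinge on this value). Transient ramps are linear by
default (an exponential shape is available; the choice is not identified
by anything downstream).

All randomness flows from one root seed through named substreams (per
experiment, per unit, per purpose), so a device unit keeps a single random
effect across every experiment of a design, and identical seeds give
bit-identical tables.

What the generator deliberately does *not* emulate: aerosol physics
(coagulation, settling, hygroscopic growth), instrument-specific firmware
(internal averaging, hard concentration caps), autocorrelated or
heteroscedastic sensor noise, and spatial chamber gradients beyond a
location tag. Passing tests therefore demonstrate that the *analysis
machinery* behaves correctly under the stated statistical structure, not
that any particular commercial monitor obeys that structure.

## Reference processing

The reference instrument counts particles per aerodynamic-diameter bin.
Mass needs a density and shape correction: a particle of density ρ and
dynamic shape factor χ with aerodynamic diameter d has volume-equivalent
diameter `d_ve = d * sqrt(chi * rho0 / rho)` (ρ₀ = 1 g/cm³), and
per-particle mass `rho * (pi/6) * d_ve^3`. With diameters in µm, density
in g/cm³ and sample volume in cm³ the unit factors cancel and the result
is directly in µg/m³. Whether a laboratory applies χ through the diameter
or divides the spherical mass by χ directly is ambiguous in practice, so
both are implemented (`shape_mode`), diameter-based by default; the two
differ by a known factor (χ^{3/2} versus χ) that the tests pin down. The
default materials are the three mineral dusts of a typical evaluation —
Arizona road dust, quartz and aluminium oxide, χ = 1.5, densities
2.6/2.6/3.95 g/cm³.

The respirable convention is the cumulative log-normal with median
4.25 µm and GSD 1.5 (weight 1 at 0 µm, 0.5 at the median, <1% above
~15 µm). Calibration against gravimetric samples is an ordinary
least-squares line (intercept retained — forcing the origin is a stronger
assumption than the data warrant), and `invariance_check()` regresses
varied-condition gravimetric values on the default-condition calibration's
predictions: a slope near 1 with high R² says the reference itself does
not react to the varied conditions.

## Screening: rollover cutoffs and normalization

For each experiment, `smooth_experiment()` fits a loess curve of monitor
on reference. A negative correlation is declared when the fitted curve
declines after its apex by more than 5% of the apex value (the tolerance
that separates rollover from smoothing wiggle — necessarily a convention),
and the per-experiment concentration limit is the apex fitted reading, in
*monitor-output* units (the true concentration above the rollover is
unknowable from the monitor side). A unit receives a cutoff only when at
least 10% of its experiments are flagged — isolated artefact experiments
should not truncate a device — and the cutoff is the 10th percentile
(type-7 interpolation) of all pooled per-experiment limits, a
conservative "maximal reliable concentration". Pooling is per unit by
default; pooling across units of a monitor type is a caller-level choice
(apply `pool_cutoff()` to the union of limits).

Three numerical choices here deserve their rationale:

* **Loess degree 2, span 0.3.** A broad locally-linear window flattens
  the curve's turning point and biases the limit low by 10–16% on sharp
  folds; a locally-quadratic fit with a moderate span tracks the apex to
  within a few percent while still averaging the reading noise. Both are
  configuration parameters.
* **Reference pre-smoothing (11-sample running mean, ~2.5 min).** The
  chamber concentration evolves on minute scales while the reference's
  10% noise is per-sample. Left in place, that noise acts as error in the
  regressor and attenuates the fitted apex (classical regression
  dilution); a short time-average removes most of it without touching
  the monitor readings being screened.
* **Apex edge-exclusion (final 15% of the grid, half the loess span).**
  Inside the boundary half-window the local fit rests on few points and
  spurious dips of >5% occur in a few percent of clean experiments —
  enough to breach the 10% flagged-share gate with one false flag when a
  unit has under a dozen experiments. A genuine half-circle turns over in
  the interior of the observed range, so boundary apexes are not flagged.

Truncation removes rows above the cutoff and reports the count. The
normalization transform is then chosen among identity, log10, square
root, Box–Cox, Yeo–Johnson and ordered-quantile normal scores by the
Pearson χ² normality statistic divided by its degrees of freedom — scored
*out-of-fold* (repeated k-fold cross-validation on a fixed internal
substream), because the rank-based ordered-quantile map is perfectly
normal in-sample by construction and would otherwise always win. The
λ-estimating candidates (Box–Cox, Yeo–Johnson) are charged one degree of
freedom in the denominator so a data-fitted λ cannot edge out a fixed
transform it merely imitates. Ties break by candidate order (identity
first, log10 second). Non-positive values under log-type candidates are
offset by half the smallest positive value, recorded in the parameters.
On log-normally distributed concentrations this procedure selects log10 —
the transform the modelling stage assumes by default.

## Correction models and the three-criterion test

The correction model regresses the transformed reference on the
transformed monitor reading. Evaluation variables enter as *slope
modifiers* of the monitor term: fixed slopes for drift
(`x:session_time`), temperature (`x:(T-20)`), humidity (`x:(RH-50)`),
exposure pattern and power supply (indicator interactions), and random
slopes without random intercepts for device unit and material
(`(0 + x | unit)`, `(0 + x | material)`) — devices and materials are
samples from larger populations, while the other conditions have fixed,
repeatable levels. Models with random terms are fitted with `lme4::lmer`;
with none, ordinary least squares (whose estimates coincide with the ML
fit). Everything uses maximum likelihood, *not* REML, so likelihood-ratio
tests and AIC comparisons across fixed-effect structures are valid.

A variable is tested by fitting the model with and without it on a data
subset in which all other non-structural variables sit at their defaults
(battery, 20 °C, 50% RH, transient), and passes only if all three hold:

1. likelihood-ratio p < 0.05 — for a random slope the statistic sits on
   the boundary of the parameter space, so the reference distribution is
   the 50:50 mixture of a point mass at zero and χ²(1);
2. AIC decreases;
3. the mean absolute error *on the back-transformed µg/m³ scale*
   decreases. The back-transform is naive (no smearing correction) so the
   reported MAE corresponds to what the model actually outputs; a
   half-variance log-normal correction is available behind
   `bias_correct = TRUE` in `predict_concentration()`.

Variables are tested in priority order — between-device, within-device
drift, material, then the remaining four — and each structural variable
that passes is carried into later tests, with its arms included in the
later subsets so its term stays estimable. The exact carry-forward subset
is one consistent reading of a procedure that is under-determined when
described informally; the chosen rule is logged per test via the model
objects. The final model contains every passed term and is fitted on the
union of screening experiments. A singular random-effect fit (variance
component estimated at zero) is refitted without the offending term and
the removal recorded in `fit_log`; predictions for unseen random-effect
levels return the population-level slope and are flagged.

One modelling subtlety is worth stating plainly. The generator's condition
effects are multiplicative gains, which on the log scale are *intercept*
shifts; the correction model codes effects as *slope* modifiers of the
monitor term, the field's convention for sensor corrections. Slope terms
capture gain shifts well but not exactly, so parameter-recovery validation
(`simulate_model_data()`) generates data directly from the slope-coded
model with known coefficients — the correct way to test the fitting
machinery — while chamber-based tests assert detection rates, error folds
and operating characteristics rather than coefficient equality.

## Verification

Predictions on a full-factorial verification design (3 materials × 3
temperatures × 3 humidities by default) are binned by reference
concentration into half-open bins with uppers
500/1000/1500/2000/3000/5000 µg/m³ — within a bin, bias and precision are
approximately homogeneous. Per bin with at least `n_min = 30` pairs
(below that the bin reports NA):

* bias `B` = mean of (prediction − reference)/reference;
* observed spread `S_obs` = SD of prediction/reference;
* monitor precision `S = sqrt(max(S_obs^2 - 0.10^2 - u_extra^2, 0))` —
  the reference's own 10% uncertainty is removed in quadrature, floored
  at zero; `u_extra` (default 0) accommodates exposure-instability
  variance if a laboratory quantifies it;
* relative uncertainty `U = (|B| + 1.96 S) * 100%`, the symmetric band
  within which ~95% of readings fall when errors are normal and bias
  constant. The formula is isolated in `relative_uncertainty()` so an
  alternative accuracy criterion can be swapped in; a Monte-Carlo
  coverage oracle in the test suite validates whichever is active.

`compare_corrections()` reports, per bin, the ratio of the reduced
("average", monitor-term-only) model's uncertainty to the full model's —
folds above 1 mean the evaluation variables earned their place — and the
average fold across bins defined for both.

Two properties of this estimator matter when interpreting output. First,
with 10% noise in the log-scale regressor the OLS slope is diluted by
roughly 1%, which tilts predictions upward a few percent at the low end
of the range; together with the Jensen effect of dividing by a noisy
reference this puts a small positive floor under low-bin |bias| even for
a perfect monitor. Second, binning on the noisy reference slightly
reshuffles pairs near bin edges. Both effects are intrinsic to the
procedure (they would be present in a laboratory analysis too); the test
suite therefore checks the *precision band* of a well-behaved monitor
against its generative noise and validates the deconvolution separately
at large n.

## Pipeline, sizes and determinism

`run_pipeline()` chains the stages with plain CSV/JSON stage outputs, MD5
content hashes in `summary.json`, per-stage timing on stderr, and full
determinism given the config seed. All simulated instruments share the
15 s grid, so no block averaging is applied by default; `resample_average()`
exists for aligning real instruments with different native cadences —
note that averaging independent per-sample reference noise also shrinks
it, in which case the `ref_uncertainty` handed to verification should be
scaled accordingly. `check_responsiveness()` reports the
minimum-to-80%-of-maximum first-crossing time against the ~1 min target.

The shipped defaults keep desk-scale problem sizes: screening designs of
15 experiments (one arm per non-default level of the seven variables plus
three shared default arms), 27-experiment factorial verification, 360
samples per experiment, and test-suite simulations of 50–500 replicates
per operating characteristic; these sizes give the test assertions
comfortable Monte-Carlo margins while a full run stays in seconds. Every
default is a config entry, so a laboratory-scale run is a config change,
not a code change.

## Limitations

* The simulator's noise is i.i.d. log-normal; real optical sensors show
  autocorrelation, humidity-dependent heteroscedasticity and quantisation
  that the generator does not emulate. Conclusions about the analysis
  machinery transfer; conclusions about any specific device do not.
* Slope-coded condition effects approximate multiplicative gain shifts;
  if a real device's effects are closer to intercept shifts on the log
  scale, the selected model still corrects them but the coefficients are
  not directly interpretable as gains.
* Rollover data are removed, not unfolded; a reading above the cutoff is
  unusable by design.
* The accuracy band `|B| + 1.96 S` assumes approximately normal relative
  errors and homogeneous bias within a bin; the bin layout is the
  instrument's working approximation to that assumption.
* No field verification: chamber-style evaluation bounds intrinsic device
  behaviour, not workplace performance.
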