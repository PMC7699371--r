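# pmevalkit

Laboratory evaluation and correction of low-cost optical particulate-matter
(PM) monitors for occupational exposure assessment.

Low-cost optical PM2.5 monitors are attractive for workplace monitoring —
cheap, wearable, near real-time — but their raw readings depend strongly on
the aerosol material, the exposure pattern (peaks versus constant
concentration), temperature, humidity, power supply, drift over sessions
and the individual device unit, and many sensors *roll over* at high
concentrations: above a device-specific limit the reported value falls as
the true concentration keeps rising, so the monitor-versus-reference curve
folds back into a "half-circle". pmevalkit implements a complete,
reproducible evaluation-and-correction workflow for such monitors against
an aerodynamic particle sizer (APS) reference:

1. **Chamber simulation** — seeded synthetic exposure-chamber experiments
   with the statistical structure the analysis assumes: plateau exposures
   at ~333/666/1000/2500/5000 µg/m³, transient 0→5000→0 µg/m³ peaks,
   a reference with 10% relative uncertainty, material/temperature/
   humidity/power/pattern/drift/device effects on the monitor response,
   multiplicative log-normal noise, and high-concentration rollover.
2. **Reference processing** — APS size-bin counts to mass concentration
   using the volume-equivalent diameter
   *d*<sub>ve</sub> = *d*<sub>ae</sub>·√(χρ₀/ρ) (density ρ, dynamic shape
   factor χ), ISO 7708 respirable-convention weighting (cumulative
   log-normal, median 4.25 µm, GSD 1.5), and linear calibration of the
   real-time reference against gravimetric samples.
3. **Screening** — loess smoothing of each experiment's
   monitor-versus-reference curve, detection of the negative correlation,
   per-unit maximal reliable concentrations as the 10th percentile (p10)
   of pooled per-experiment limits (a cutoff is only assigned when ≥10% of
   a unit's experiments are flagged), truncation of readings above the
   cutoff, and data-driven selection of the normalization transform
   (identity, log10, √, Box–Cox, Yeo–Johnson, ordered-quantile, scored by
   an out-of-fold Pearson χ²/df normality statistic).
4. **Correction modelling** — linear mixed-effects models (lme4, maximum
   likelihood) regressing the transformed reference on the transformed
   monitor reading. Each evaluation variable enters as a slope modifier of
   the monitor term — fixed slopes for drift, temperature, humidity,
   exposure pattern and power; random slopes (no random intercept) for
   device unit and material — and is admitted only if it passes all three
   criteria: likelihood-ratio *p* < 0.05 (boundary-corrected for variance
   components), a decrease in AIC, and a decrease in mean absolute error
   on the µg/m³ scale. Variables are tested in priority order
   (device → drift → material → rest) with structural terms carried
   forward.
5. **Verification** — predictions on a full-factorial verification set are
   binned by reference concentration (uppers 500/1000/1500/2000/3000/5000
   µg/m³) and each bin's accuracy is summarised as the relative
   uncertainty *U* = (|*B*| + 1.96 *S*)·100%, where *B* is the mean
   relative bias and *S* the relative precision after removing the
   reference's own 10% uncertainty in quadrature
   (*S* = √max(*S*²obs − 0.10², 0)). Bins are judged against a ≤50%
   target, and the fold-improvement of the full correction over an
   "average" correction (monitor term only) is reported per bin.

## Worked example

```r
library(pmevalkit)

## one simulated chamber experiment: quartz dust, transient peaks,
## a monitor that over-responds to SiO2 (gain 1.3) and rolls over at
## 3500 ug/m3 true concentration
mats <- default_materials(monitor_gains = c(ARD = 1, SiO2 = 1.3, Al2O3 = 0.7))
spec <- sensor_response_spec(noise_cv = 0.15, pattern_shift = 0.15,
                             rollover_limit = 3500)
prof <- profile_transient(peak_max = 5000, peak_duration = 1800, n_peaks = 3)
ex <- simulate_experiment(prof, condition_set("SiO2"), spec, mats$SiO2,
                          seed = 42)
ex
#> <experiment_series> 360 samples, 1 unit(s), material SiO2, transient pattern
#>   true range 0-5000 ug/m3; gravimetric 2562.5 ug/m3

## screening: 8 experiments of that unit, pooled p10 cutoff
pairs <- lapply(1:8, function(i) {
  e <- simulate_experiment(prof, condition_set("SiO2"), spec, mats$SiO2,
                           seed = 100 + i)
  data.frame(reference = e$reference, monitor = e$monitor[, 1])
})
screen_unit(pairs, unit_id = "unit1")
#> <cutoff_report> unit unit1: 8/8 experiments flagged; cutoff 5039 ug/m3
#> (monitor output, p10)
```

The cutoff is in *monitor-output* units: with gain ≈1.5 on quartz the
reading at the 3500 µg/m³ rollover point is ≈5300, and the conservative
p10 of the eight per-experiment limits lands at 5039.

The full pipeline — simulate a screening design over all seven evaluation
variables plus a 3×3×3 material–temperature–humidity factorial
verification set, screen, select variables, fit and verify:

```r
res <- run_pipeline(default_run_config(seed = 1), "run1")
res$selection$results[, c("variable", "anova_p", "delta_aic",
                          "mae_fold", "passed")]
#>      variable  anova_p delta_aic mae_fold passed
#> 1        unit 5.00e-01     0.000     1.00  FALSE
#> 2       drift 7.11e-01     1.863     1.00  FALSE
#> 3    material 1.72e-86  -385.156     1.33   TRUE
#> 4 temperature 5.78e-01     1.691     1.00  FALSE
#> 5    humidity 2.33e-02    -3.143     1.01   TRUE
#> 6     pattern 1.69e-10   -38.793     1.03   TRUE
#> 7       power 1.23e-01    -0.375     1.00  FALSE
res$uncertainty
#> <uncertainty_report> full (target <= 50%)
#>   [   0,  500):   43.2% (n=274) *
#>   [ 500, 1000):   37.6% (n=324) *
#>   [1000, 1500):   35.7% (n=331) *
#>   [1500, 2000):   28.2% (n=318) *
#>   [2000, 3000):   29.9% (n=657) *
#>   [3000, 5000):   30.7% (n=1172) *
res$comparison$average_fold
#> [1] 1.85
```

The generator gave this monitor real material and pattern effects (and a
small humidity slope); the three-criterion rule admits exactly those, the
corrected monitor meets the 50% target in every bin (`*`), and correcting
the evaluation variables improves the average bin uncertainty 1.85-fold
over a correction that ignores them — the behaviour expected of a monitor
whose response depends on what it is measuring.

A thin command-line front end is installed at `inst/cli/pmevalkit.R`
(`run`, `simulate`, `screen` subcommands over YAML configs); a bundled
demo configuration sits in `inst/extdata/default_config.yaml`.

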