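# bolusphase

Contrast-bolus phase timing for single-phase CT angiography, with the
perfusion volumetry and stratified agreement statistics used to evaluate
CTA-based ischaemic-lesion estimators against final infarct volume.

## The science

A single-phase CTA of the head is one snapshot of a moving target: the
contrast bolus washes through the arteries, the tissue, and finally the
veins over roughly half a minute. A machine-learning model that estimates
the ischaemic lesion from CTA inherits that timing — an early-arterial
snapshot carries little tissue contrast, a mid-arterial one emphasises the
whole perfusion deficit (infarct core *plus* penumbra), and a delayed one
approaches the steady state better suited to core estimation. Interpreting
such a model's output therefore requires knowing *when* in the bolus
passage each scan was acquired.

bolusphase provides that machinery end to end:

* **Bolus phantom.** The arterial input function (AIF) is a gamma-variate
  enhancement above baseline,

  `C(t) = A * ((t - t0)/(alpha*beta))^alpha * exp(alpha - (t - t0)/beta)`,

  peaking at `A` HU at `t0 + alpha*beta`. The venous output function (VOF)
  is the AIF delayed by the arterio-venous transit and Gaussian-broadened
  with area preserved. A voxelwise CTP series and single-phase CTA
  snapshots are simulated from these curves with known ground truth.
* **Timing estimation.** The CTA's arterial-minus-venous HU difference is
  intersected with the piecewise-linear AIF−VOF difference curve from a
  paired CTP acquisition; ambiguous crossings are disambiguated by the
  absolute mismatch of the raw ROI values plus, when available, the
  whole-field-of-view mean attenuation. The estimate is classified into
  early-arterial / mid-arterial / mid-to-venous / delayed-venous phases
  from the curve landmarks (AIF peak, VOF peak, AIF half-rise).
* **Perfusion volumetry.** Core (rCBF < 30%), penumbra (Tmax > 6 s), the
  hypoperfusion intensity ratio HIR = vol(Tmax > 10 s)/vol(Tmax > 6 s),
  and lesion volume from voxelwise probability maps with the standard
  filters (probability ≥ 0.5, 26-connected components > 0.1 mL,
  ipsilateral by majority vote).
* **Agreement statistics.** Pearson r with Fisher-z CI, ICC(2,1) from
  two-way ANOVA mean squares, ordinary least squares, Bland-Altman with
  empirical 2.5/97.5 percentile limits, Kruskal-Wallis, Shapiro-Wilk
  gating — assembled into a report stratified by time window (< 6 h,
  6-24 h), collateral status (Miteff grade, HIR) and reperfusion (TICI).
* **Cohort simulator.** A generative patient model (log-normal penumbra,
  core as a fraction of it, collateral-dependent infarct growth,
  wake-up strokes with sleep-midpoint last-known-well imputation) that
  reproduces the qualitative signatures a mid-arterial estimator shows
  against final infarct volume.

Everything is tidyverse-native: curves and cohorts are tibbles, reports
have `tidy()`/`glance()` methods and `autoplot()`s; image volumes stay
plain arrays with spacing/time attributes.

## Worked example

Estimate when a CTA was acquired, given the patient's own CTP curves:

```r
library(bolusphase)

bp  <- bolus_params(noise_sd = 0)      # t0 10 s, peak 14 s, venous delay 10 s
geo <- phantom_geometry()
ser <- simulate_ctp_series(bp, geo)
aif <- extract_roi_curve(ser, roi_spec("arterial", geo$arterial))
vof <- extract_roi_curve(ser, roi_spec("venous", geo$venous))
fov <- fov_mean_curve(ser)

# a test-bolus protocol scans 12 s after the aortic test-bolus peak
ta   <- test_bolus_acquisition_time(bp)   # 18.5 s
cta  <- simulate_cta_snapshot(bp, geo, t_acq = ta)
vals <- c(cta_roi_values(cta, geo$arterial, geo$venous), fov = mean(cta$voxels))
estimate_timing(aif, vof, vals, fov = fov)
#> CTA acquisition-time estimate: 18.50 s (mid_arterial)
#>   candidates: 12.01, 18.50
#>   AIF peak 14.00 s, VOF peak 24.00 s, AIF half-rise 12.10 s
#>   flags: multiple_intersections
```

The difference level crossed the curve twice (once on the upslope at
12.01 s, once after the arterial peak); the FOV-mean term picked the true
candidate and the estimate is exact. `plot_timing(aif, vof, vals, est)`
draws the construction.

Run the full cohort pipeline:

```r
cohort <- simulate_cohort(cohort_params(n_patients = 121, seed = 7L))
report <- build_report(cohort)
report
#> Stratified agreement report: 121 patients (4 with unknown LKW)
#>   24 evaluable strata; overall r = 0.95 (n = 121)

glance(report)
#> # A tibble: 1 × 6
#>       n n_unknown_lkw     r   icc cnn_median fiv_median
#>   <int>         <int> <dbl> <dbl>      <dbl>      <dbl>
#> 1   121             4 0.949 0.929       63.3       50.1

dplyr::filter(tidy(report), stratifier == "all")[, c(
  "window", "group", "n", "r", "r_lo", "r_hi", "icc", "slope", "intercept")]
#> # A tibble: 3 × 9
#>   window group     n     r  r_lo  r_hi   icc slope intercept
#>   <chr>  <chr> <int> <dbl> <dbl> <dbl> <dbl> <dbl>     <dbl>
#> 1 all    all     121 0.949 0.928 0.964 0.929 0.856    1.10
#> 2 <6h    all      73 0.965 0.945 0.978 0.948 0.872    0.0306
#> 3 6-24h  all      44 0.881 0.791 0.934 0.853 0.791    4.97
```

The mid-arterial estimator overestimates the final infarct (median 63.3 vs
50.1 mL) because it sees penumbra that successful reperfusion later
salvaged — the central confound the timing analysis exists to expose.
`autoplot(report)` shows the Bland-Altman panels; `write_report(report,
dir)` writes the stratified tables as CSV/JSON.

See `vignettes/methods.Rmd` for the model, the parameter choices and
their rationale, and the numerical conventions.

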