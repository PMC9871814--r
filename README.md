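# rootwave

Quantification of calcium wave kinematics in plant-root fluorescence
time-lapse recordings.

Primary roots of *Arabidopsis* expressing an intensiometric calcium sensor
(e.g. G-CaMP3) respond to osmotic stress — salt (NaCl) or drought-mimicking
PEG — with a cytosolic Ca²⁺ front that initiates at the cells first touched
by the stimulus and then propagates through the root: shoot-ward when the
treatment hits the tip, tip-ward when it hits the differentiation zone,
transversely across the root when only one flank is treated, and in both
directions at once in some conditions. On a dual-flow microfluidic chip
these contact sites can be chosen at will, and the recordings are
time-lapse fluorescence stacks. `rootwave` turns such stacks into numbers:

- **Kymographs** (`build_kymograph()`): position × time matrices built by
  summing pixel intensities transversely (or longitudinally) inside an ROI,
  bin by bin, frame by frame.
- **Front detection** (`detect_front()`): per position, the earliest
  crossing of the half-maximum level
  `baseline + ½ (peak − baseline)` by the lightly smoothed intensity trace,
  located to sub-frame precision.
- **Speed and direction** (`estimate_speed()`, `classify_direction()`,
  `fit_wavefront()`): the signed wave speed *u* (µm/s) is the Theil–Sen
  slope (median of pairwise slopes) of position against front time; a
  V-shaped front-time profile with an interior minimum is split at the
  minimum and fitted per branch, yielding a *bidirectional* classification
  with two signed speeds.
- **Section traces and fold change** (`place_sections()`,
  `extract_traces()`, `fold_change()`): mean-intensity time series at the
  five standard transects along the root axis — Tip (columella), ME1, ME2,
  ED1, ED2, spaced 290/290/290/580 µm — and the background-corrected
  plateau-to-baseline ratio *A*.
- **Condition comparison** (`compare_conditions()`): two-way ANOVA
  (treatment × section) with Tukey HSD pairwise contrasts on per-replicate
  mean intensities.
- **Flow-transit model** (`channel_spec()`, `transit_velocity()`,
  `fill_time()`, `decoupling_ratio()`): the closed form `v = Q / A_free`
  shows the solution front crosses the 12-mm observation channel at
  ~6.8 × 10³ µm/s (filling it in ~1.76 s) — two to three orders of magnitude
  faster than the tissue-borne signal, excluding advection as its carrier.
- **Synthetic recordings with ground truth** (`generate_preset()`,
  `generate_replicates()`): an analytic root phantom (capsule around a
  centerline, arclength/transverse coordinates per pixel) carrying a
  propagating sigmoidal front, rendered with Gaussian optics, Poisson shot
  noise and Gaussian read noise. Nine presets encode the studied treatment
  configurations, so every estimator can be validated by parameter
  recovery without any raw-data download.

All tabular results are tibbles; fitted objects support `tidy()`,
`glance()` and `autoplot()`.

## Worked example

Simulate a full NaCl treatment at the root tip and recover its kinematics:

```r
library(rootwave)

cam <- camera(pixel_size_um = 4, n_frames = 180, frame_interval_s = 1,
              psf_sigma_um = 6)
sim <- generate_preset("nacl_tip_full", seed = 1, cam = cam)
res <- analyze_recording(sim$stack, sim$phantom)

glance(res$fit)
#> # A tibble: 1 × 4
#>   direction  speed_um_s n_branches n_positions
#>   <chr>           <dbl>      <int>       <int>
#> 1 shoot_ward       5.90          1         255

sprintf("Tip-section fold change: %.2f", res$fold_change_tip)
#> "Tip-section fold change: 2.51"

flow_report(channel_spec(), v_signal_um_s = abs(res$fit$speed_um_s))
#> # A tibble: 1 × 5
#>   velocity_um_s fill_time_s signal_um_s ratio decoupled
#>           <dbl>       <dbl>       <dbl> <dbl> <lgl>
#> 1         6817.        1.76        5.90 1155. TRUE
```

The preset injects a shoot-ward wave of 5.9 µm/s with a 2.5-fold intensity
rise as ground truth; the pipeline recovers 5.90 µm/s, a 2.51-fold change
and a flow-to-signal decoupling ratio above 1000 from the rendered noisy
video. `autoplot(res$kymograph)` shows the kymograph heat map and
`autoplot(res$fit)` the detected front times with the fitted slope.

A whole study (several presets × replicates) runs through
`run_pipeline(config, out_dir)`, which writes `summary.csv` (one row per
replicate: direction, signed speed, fold change), the resolved config and a
log, deterministically for a given seed.

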