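---
title: "Wave kinematics from root fluorescence videos: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wave kinematics from root fluorescence videos: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootwave)
```

`rootwave` quantifies treatment-triggered calcium waves in primary roots
imaged on dual-flow microfluidic chips. This vignette documents the models
behind the package: the wave and imaging model of the synthetic-recording
generator, the estimator conventions, the statistical design of replicate
batches, and the numerical choices — together with what each assumes and
where it stops being valid.

## The root phantom and its coordinates

A root is modelled as a capsule: all points within `radius_um` of a
centerline polyline, with a hemispherical cap at the tip apex and a flat cut
at the shoot end (`root_geometry()`, `build_phantom()`). Every pixel of the
rasterised phantom carries the arclength `s` of its nearest centerline point
(µm, `s = 0` at the tip apex, increasing shoot-ward) and a signed transverse
coordinate `r` (µm across the midline). All downstream kinematics are
expressed in these coordinates. Cap pixels project to the apex (`s = 0`),
which is why a tip-initiated wave lights the whole cap essentially at once —
visible as a flat segment at the start of a kymograph.

The default geometry is a straight vertical root of 2400 µm visible
arclength and 60 µm half-width: long enough for the five sampling sections
(span 1450 µm) and a differentiation-zone contact site, placed at
`s = 2000` µm by default. Curved centerlines are supported by the phantom
and by `place_sections()` (spacings are arclength, not chord), but the
kymograph axis is an image axis: speed estimation on strongly curved roots
would mix coordinates. On-chip roots are guided straight, so this is the
intended regime.

## The wave model

A scenario assigns every root point an *activation time*

$$t_a(s, r) = t_0 + \frac{s - s_0}{u} \;\left[+\; \frac{|r - r_\mathrm{treated}|}{v_T}\right]$$

on the propagation side of the initiation locus $s_0$ (both sides at rate
$1/|u|$ for a bidirectional wave; positions on the non-propagating side
never activate). The transverse term applies to one-sided treatments only
and is clamped at the midline when the scenario does not transmit to the
untreated flank. The sign convention is: positive $u$ = shoot-ward
(arclength increasing). The fluorescence multiplier at time $t$ is

$$m(s, r, t) = 1 + (A - 1)\, S\!\left(\frac{t - t_a(s, r)}{\tau}\right)$$

with $A$ the plateau/baseline fold and $S$ a compact-support sigmoid
(smootherstep, $6x^5 - 15x^4 + 10x^3$ on its support) scaled so that the
10–90% rise time equals $\tau$ and the half-rise sits exactly at $t_a$.
The compact support is a deliberate numerical choice: baseline and plateau
are attained *exactly*, so noiseless identities (multiplier 1 before the
rise, spatial maximum equal to $A \cdot$ baseline) hold to machine
precision rather than asymptotically. The price is that the rise begins
$\approx 0.99\,\tau$ before $t_a$; a front anchored at its half-rise cannot
also be identically 1 up to its own onset, and the half-rise anchor wins
because it is what a half-maximum detector estimates. Defaults:
$\tau = 5$ s, $t_0 = 20$ s (so the rise never leaks into the 10-s baseline
window used by the detector). The plateau is sustained — the recordings the
model emulates show no decay within their 180-s window — so there is no
refractory or decay term.

## Scenario presets and replicate variability

`preset_table()` encodes the eight studied treatment configurations plus a
control. Longitudinal speeds (µm/s, signed), amplitude folds, sidedness and
transverse behaviour come from the reported experiments: e.g. full NaCl at
the tip is a shoot-ward 5.9 µm/s wave with a 2.5-fold rise; full treatments
at the differentiation zone travel tip-ward (−6.8 NaCl, −11.6 PEG, fold
1.5); one-sided NaCl at the differentiation zone adds a transverse crossing
at 9.4 µm/s with a secondary tip-ward 5.2 µm/s wave; one-sided PEG there is
bidirectional at ±11 µm/s with a non-crossing transverse component. Two
quantities are not reported anywhere and carry documented placeholders,
never used as recovery targets: the transverse speed of the one-sided PEG
differentiation-zone case (set to 14 µm/s, non-crossing) and the transverse
kinetics of the tip one-sided cases (10 µm/s, non-crossing). The PEG tip
one-sided amplitude is read additively from "0.5-fold higher" than its NaCl
counterpart: $A = 3.0$.

Reported speeds come with root-to-root dispersion (SD over n roots), and
the generator emulates it: each replicate in a batch gets its own true
speed, `mean + z · SD`, with the reported SD (a 10% coefficient of
variation — the typical relative spread of the reported speeds — where no
SD is printed). One `z` is shared by the longitudinal and transverse speeds
of a replicate (a fast root is fast in both). Within a batch the `z` values
are *stratified* normal quantiles `qnorm((i − 0.5)/n)` in a seed-permuted
order: the batch is a representative cohort whose mean equals the reported
mean and whose SD is close to the reported SD. This design makes
recovery-within-2-SE a test of the estimator rather than of sampling luck:
with a fixed shared truth the between-replicate SE collapses to the level
of discretisation noise, while fully random draws would make the batch mean
itself fluctuate by whole standard errors.

## The imaging model

`render_stack()` renders, per frame,

```
pixel = blur( background + mask · baseline · m(s, r, t) ) + noise
```

with a Gaussian point-spread (default σ = 4 µm at the default camera),
Poisson shot noise applied at a gain of 1 ADU per photon-equivalent, and
Gaussian read noise (σ = 20 ADU), digitised to the camera bit depth
(16-bit). Baseline root fluorescence is 2000 ADU over a 200 ADU chamber
background. The default camera is the study acquisition: 568 frames over
180 s (frame interval 180/568 ≈ 0.3169 s — the frame-count/duration pair is
internally consistent, unlike the also-quoted "3.3 fps" — at 2 µm/px,
consistent with a 5×/0.15 objective). Setting both noise terms to zero
returns an unquantised stack on which analytic identities are exact.

What the generator does **not** emulate: root growth during the recording
(the 180-s window justifies a static phantom), 3-D cylindrical optics and
depth attenuation (the root is rendered as a flat 2-D profile), sensor
binding kinetics and saturation (the fold is a free parameter, not derived
from a dissociation constant), photobleaching, stage drift, and
autofluorescence structure. Recovery results therefore demonstrate that the
estimators are unbiased and precise *under this imaging model*; on real
recordings the same estimators face model error that no synthetic test can
rule out.

## Estimator conventions

**Kymographs** sum (not average) pixel intensities inside the ROI within
bins along the chosen axis, by pixel centre, so every ROI pixel lands in
exactly one bin and the per-frame bin total equals the per-frame ROI sum in
exact integer arithmetic. Partial-pixel weighting was rejected to keep this
conservation identity exact. The default bin is one pixel. Section traces,
by contrast, use the *mean* over a transect band (half-width 2 px) —
plot-profile semantics; the two are deliberately different. Display
normalisation is min–max (shared across samples in `global` mode), with an
optional quantile clip.

**Front detection** uses the half-maximum criterion: after a 3-frame moving
mean, the front time is the first crossing of
`baseline + 0.5 · (peak − baseline)`, linearly interpolated between frames.
Half-max was chosen over a fixed `k·σ` threshold as the primary criterion
because it is amplitude-invariant — columns of different brightness (edge
vs. centre of the root) are timed consistently; the fractional level `f`
and the floor multiplier `k_sigma` remain settable. A position is reported
as *no front* when its dynamic range stays below `k_sigma = 4` times the
noise scale, estimated robustly as `mad(diff(trace))/√2` over the whole
trace — stable even for short baseline windows, insensitive to the slow
front rise, and exactly zero for a constant noiseless trace.

**Speed** is the Theil–Sen slope (median of pairwise slopes) of position
against front time; its robustness absorbs positions where detection stalls
or the plateau is clipped by the end of the recording. Sub-frame
interpolation of crossing times makes exact ties rare; pairs with equal
front times are excluded from the slope set. Fit quality is reported as the
median absolute residual and the fraction of positions within three such
scales. Slopes below 1 µm/s are labelled `none` (unresolved — an
"instantaneous" front carries no direction information at this sampling).

**Direction** follows the sign of the slope (positive = shoot-ward). If the
front-time profile, lightly smoothed over positions, has its minimum at an
interior position (more than 10% of the position range from either end),
the profile is split there and both branches fitted; opposite signs with
both magnitudes above threshold classify the wave as *bidirectional* with
two signed speeds.

**Fold change** is the background-corrected ratio
`(max(smoothed) − bg) / (mean(baseline) − bg)`. The correction matters
because a transect band mixes root and chamber pixels; subtracting the
background restores the pure tissue ratio (exactly so in the noiseless
linear model). The background is estimated as the median of the dim
quartile of the per-pixel temporal mean over early frames
(`estimate_background()`).

**Condition comparison** is a fixed-effects two-way ANOVA
(treatment × section, interaction included) on per-replicate mean
intensities over a stated time window, with Tukey HSD pairwise contrasts at
α = 0.05 — the standard design for grouped section intensities. At least
two replicates per cell are required.

## The flow-transit model

`transit_velocity()` computes `v = Q/A_free` with `Q` converted to µm³/s
and `A_free = A_chan (1 − φ)`. The chamber's cross-section is not reported
anywhere in text; the default `A_chan = 97 800 µm²` with φ = 0.5 (the
root occupying half the chamber) is *back-calculated* so that the default
operating point — 20 µL/min through the 12-mm channel — reproduces the
reported ~6.84 × 10³ µm/s front speed, and is flagged as such. φ is an
effective free-cross-section fraction; the "root grown 6 mm (50%) into the
channel" figure is length occupancy and enters only as the motivation for
the 0.5 default. `fill_time()` is `L/v`; the reported 1.76 s and
6.84 × 10³ µm/s differ by printed rounding (12 000/1.76 = 6 818).
`decoupling_ratio()` divides flow speed by signal speed and flags ratios
above 100 as advection-decoupled.

## Problem sizes in the tests and the acceptance script

The test-suite and `scripts/acceptance.R` run the generator at an
analysis-scale acquisition chosen for this package: 180 frames at 1 frame/s
and 4 µm/px with the default optics and noise. At the studied speeds
(4–14 µm/s) the front moves 1–3.5 µm per frame, well below a 4-µm bin, so
the sampling still oversamples the kinematics; recovery accuracy is limited
by the noise model, not the grid. Replicate batches use the reported sample
sizes (n = 10 or 5). The acceptance script re-renders every batch from
scratch from its `--seed` and reports batch means; the testthat suite
asserts recovery within two standard errors of the batch (and, on noiseless
renders, to better than 1%), fold changes within 5% (exact noiseless), the
flow operating point, and the always-on property suite (exact kymograph
conservation, time-reversal antisymmetry of the speed estimator, a silent
control preset, and the ANOVA type-I rate over 20 seeded identical-group
draws).

## Known limitations

- Kymograph positions are image-axis coordinates; speed estimation assumes
  an axis-aligned, near-straight root (the on-chip geometry).
- The five-section layout is anchored at the tip at frame 0 and fixed
  thereafter; growing roots would need tip tracking.
- The transverse estimator reads a ~30-column kymograph at 4 µm/px; PSF
  mixing at the flank edges costs it a percent-level upward bias, an order
  of magnitude inside the dispersion of the quantity it estimates.
- "Analogue-to-digital conversion" of traces is implemented as even-grid
  linear resampling (`resample_trace()`); the original processing step it
  mirrors is not further specified, so this is a documented interpretation.
- AVI/CZI ingestion is out of scope: multi-page TIFF (with a JSON metadata
  sidecar) is the interchange format, and compressed video exports are
  lossy in ways a quantification pipeline should not silently accept.
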