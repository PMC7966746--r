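---
title: "Left atrial 4D-flow quantification: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Left atrial 4D-flow quantification: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(la4dflow)
```

## The problem

Blood that moves slowly through the left atrium (LA) — and especially
through the LA appendage (LAA) — predisposes to thrombus formation, the
proximate cause of cardioembolic stroke in atrial fibrillation (AF).
Time-resolved, three-directionally velocity-encoded phase-contrast MRI
("4D flow" CMR) measures the intra-atrial velocity vector field through the
cardiac cycle, from which three global hemodynamic read-outs are derived:

* **windowed flow velocity** — the spatial mean speed in the region of
  interest, read from the velocity–time curve over the whole available
  cycle, systole, diastole, and at the E- and A-wave peaks;
* **stasis fraction** — the proportion of the region below a 10 cm/s
  speed threshold;
* **kinetic energy (KE)** — `0.5 · rho · m · |v|^2` summed over voxels,
  with blood density `rho = 1.025 g/mL` and voxel mass `rho · V_voxel`,
  reported in mJ and, as an energy *density*, indexed to the maximum LA
  volume in uJ/mL.

Alongside flow, the chamber side is quantified from cine imaging: the LA
volume curve with its three landmarks (maximum, pre-atrial-contraction,
minimum) and the reservoir/conduit/booster decomposition; biplane
area-length LV volumes, mass and ejection fraction; and feature-tracking
global longitudinal strain with its reservoir, conduit and active-emptying
phases. A statistical layer covers the standard small-cohort two-group
workflow (t / Mann–Whitney / Fisher / paired t, Spearman, ICC,
CHA~2~DS~2~-VASc scoring).

This vignette records the package's modelling conventions, the design of
the synthetic validation phantom, the numerical choices, and what the
validation does and does not establish.

## Velocity field conventions

A `velocity_field` stores velocities on a regular voxel grid as a 5-D array
`(i, j, k, component, frame)` in cm/s, with a diagonal affine (voxel
`(i, j, k)` at `((i-1)dx, (j-1)dy, (k-1)dz)` mm) and frame times in ms from
the R-wave. Frames cover only about 90% of the R-R interval: prospective
ECG gating discards late diastole, so "whole cycle (R-R)" statistics are
computed on the available frames without extrapolation. Phase images map to
velocity by the standard linear convention `v = VENC · phase / pi`
(`phase_to_velocity()`), with VENC = 100 cm/s the working sensitivity.

Windows are half-open intervals `[t0, t1)`; E- and A-wave values are the
curve value at the single frame nearest the annotated peak time — an
instantaneous reading, not a window average. "Peak" velocity and KE are
temporal maxima of the *spatially averaged* curve, never the maximum
single-voxel speed; single-voxel maxima are noise-dominated at typical
SNR, and the curve convention is what velocity–time-curve read-outs imply.

## Residual offset correction

Uncompensated eddy currents leave a slowly varying velocity offset after
scanner-side Maxwell-term correction. The package models it, per velocity
component, as a first-order spatial polynomial `a + b·x + c·y + d·z`
(cm/s, world mm), fitted by least squares to the *time-averaged* velocity
of stationary tissue and subtracted from every frame:

* **stationary tissue** is detected as voxels whose temporal standard
  deviation of every component stays below a threshold (default 2 cm/s —
  a configurable convention; at 1 cm/s noise and 10–20 frames the
  chi-distribution tail leaves >95% of true static tissue selected),
  excluding the chamber masks;
* the offset is assumed **time-invariant**, consistent with eddy-current
  physics, so the fit pools all frames (temporal mean);
* a **global volumetric fit** is used rather than per-slice fits, which are
  statistically fragile at this resolution; the model reports the
  stationary-voxel count and per-component residual RMSE for audit.

Correction is exactly idempotent on noiseless data (a refit after
correction returns a null plane) and can only reduce the mean stationary
speed.

Cine-derived masks are aligned to flow frames by nearest-neighbour in time
with wrap-around at the R-R interval (ties resolve to the earlier cine
frame). No contour-morphing interpolation is invented: mask shapes are
taken as-is from the nearest cine frame.

## Stasis semantics

"Volume fraction below 10 cm/s during the entire cardiac cycle, assessed
as a percentage of voxels" admits two readings, and both are implemented:

* `timefrac` (default): the fraction of in-mask voxel–frame *samples*
  below threshold — a duty-cycle of slow flow;
* `strict`: the fraction of voxels (among those inside the mask at every
  frame) that stay below threshold at *all* frames.

`strict` is never larger than `timefrac`. Neither is asserted to be the
convention of any particular prior implementation; the default is
`timefrac` because it is robust to single-frame mask jitter and degrades
continuously with noise.

## Chamber function and strain

From the LA volume curve, landmarks are `v_max` (global maximum, end
ventricular systole), `v_preac` (value at the frame nearest the annotated
pre-atrial-contraction time — supplied by timing annotation, not detected
from the curve) and `v_min` (global minimum). The decomposition is exact
by construction: reservoir = max − min, conduit = max − pre-ac,
active = pre-ac − min, with total/passive function indexed to `v_max` and
booster function to `v_preac`.

Strain is computed from tracked boundary polylines (point correspondence
across frames): per view, strain is the relative arc-length change from
the reference frame, fixed at ventricular end-diastole (the prevailing
feature-tracking convention). The global curve averages the 2- and
4-chamber views *pointwise in time* (not phase-values after the fact).
The strain rate is the centred finite difference of strain/100 (1/s),
one-sided at the ends, with an optional width-3 moving average (off by
default). Phases: reservoir strain is the curve peak; active-emptying
strain is the value at pre-ac; conduit strain is their difference, so
reservoir = conduit + active holds identically. Emptying magnitudes are
reported as positive numbers under the negative-sign convention.
Monotone non-decreasing strain has no emptying phase and raises a timing
error rather than returning a sign-flipped artefact.

LV volumes use the biplane area-length formula `V = 8·A2c·A4c/(3*pi*L)`;
mass is 1.05 g/mL times the epi-endo wall volume. Slice-summation
volumetry multiplies per-slice areas by the full slice increment
(thickness + gap) because gapped stacks tile the chamber only at that
pitch.

## The synthetic dynamic-atrium phantom

No deposited 4D-flow dataset accompanies the study conditions this package
emulates, so validation rests on a generative phantom with analytic ground
truth (`phantom_spec()`, `make_phantom()`).

**Geometry.** The LA is an ellipsoid with semi-axes `(a, a, 1.3a)` whose
`a(t)` tracks an analytic volume curve; the LAA is a static sphere
(radius 8.5 mm) attached at the +x flank, mostly outside the ellipsoid so
that mask carve-out does not bias LA volumetry; each mask excludes the
other region. Default grid: 3.1 × 3.1 × 3 mm voxels (the working 4D-flow
resolution; one voxel is 0.02883 mL), 20 frames over 90% of the R-R
interval.

**Volume curve.** Piecewise half-cosine (C^1, zero slope at landmarks)
through: minimum at the R-wave, maximum at phase 0.40 (end ventricular
systole), pre-ac plateau at phase 0.72, minimum again at 0.93, then flat.
The curve attains `v_max` exactly once.

**Speed model.** Per-voxel speed is `m(t) · s_i`: a temporal envelope
times a static spatial heterogeneity field. The envelope is a diastasis
baseline plus raised-cosine bumps — a systolic hump (centre phase 0.20),
an E peak (0.52) and an A peak (midway between pre-ac and minimum-volume
phases). `s_i` is i.i.d. lognormal with mean 1 and a prescribed
coefficient of variation (the `spatial_heterogeneity` parameter); this
one parameter controls how much of the region sits in the slow-flow tail
and therefore couples mean velocity, stasis and KE realistically.
Directions come from a smooth sinusoidal template under a seeded random
rotation; all reported metrics depend on the magnitude only, so the
direction model is cosmetic and deliberately not validated. Measurement
effects are additive per-component Gaussian noise and a per-component
linear offset plane — exactly the model the preprocessing stage removes.
Identical spec and seed reproduce a dataset bit-exactly.

**Contours.** Tracked-contour sequences are semicircular polylines (48
points, 30 cine frames over the full cycle) whose arc length follows a
prescribed strain curve of the same piecewise-cosine family (zero at the
R-wave, reservoir peak at end systole, active value at pre-ac). Because a
polyline scales linearly with its radius, the discretisation bias cancels
in the strain ratio and phase recovery is exact up to frame timing.

**Ground truth.** Each dataset carries its analytic volume curve,
landmark volumes, prescribed strain phases, and flow metrics computed
directly from the noiseless, offset-free speed array by a separate
vectorized implementation inside the generator. An additional fully
looped brute-force oracle (`oracle_metrics()`) serves as the equivalence
reference for the production metric code on small random fields.

### Cohort presets and calibration

`make_cohort()` draws subjects from two presets emulating a paroxysmal-AF
group and an age-matched control group during sinus rhythm. Subject-level
draws: heart rate (66 ± 7 vs 59 ± 6 bpm), whole-cycle mean-velocity
target (16.7 ± 2.1 vs 13.1 ± 2.4 cm/s), volume landmarks (indexed means
36.6/26.8/15.8 vs 39.6/29.5/19.9 mL/m², de-indexed with a nominal body
surface area of 1.9 m², truncated at ±2 SD with ordering enforced), and
strain phases. The printed group SDs mix biological and measurement
variability with no stated split; the presets treat them as spec-level
(biological) variance and keep measurement noise as the separate 1 cm/s
Gaussian term — one documented choice, not a claim about the source data.

Two constants per preset are calibrated rather than copied from any
table, because no table determines them: the envelope shape ratios
(systolic/E/A/baseline = 1.10/1.70/0.60/0.75 of the subject's target mean
velocity, shared by both groups) and the spatial-heterogeneity CV
(control 0.57, AF 0.61). They were fixed once, via an analytic lognormal
stasis/KE model followed by a full-pipeline check, so that n = 30/group
cohort means of mean velocity, stasis and indexed mean KE land on the
emulated group values; the LAA velocity scales (0.69, 0.633) were solved
the same way from the LAA stasis means. Mean-velocity targets are drawn
*stratified* (group quantiles assigned in random subject order): with
i.i.d. draws the n = 30 cohort mean wanders by a few percent from
sampling luck alone, which is generator variance, not a property of the
analysis under test.

Envelope *peakedness* (hence peak velocity and peak KE) is only loosely
constrained by the emulated summary statistics and is not a calibration
target; cohort-level peak read-outs should not be over-interpreted.

### What the phantom does not emulate

Pulmonary-vein jets, vortical transport, chamber-wall no-slip layers and
any Navier–Stokes realism; velocity aliasing/wrap-around; k-space or MR
signal formation; spatial misregistration between cine and flow stacks;
appendage motion. Passing the recovery and calibration suites therefore
shows that the *quantification* pipeline is correct and well-conditioned
under a known generative model — not that the generative model reproduces
real atrial fluid dynamics.

## Statistical layer

Two-group comparisons auto-select an independent-samples Welch t-test
when both groups pass Shapiro–Wilk at alpha = 0.05 (groups too small to
test, n < 3, are treated as normal), otherwise Mann–Whitney U; Fisher's
exact test uses the two-sided probability-summation rule; Spearman
correlation uses average ranks with asymptotic two-sided p; LA-vs-LAA
contrasts are paired t-tests with degenerate-difference conventions
(all-zero differences give p = 1). Inter-observer agreement is ICC(A,1):
two-way random effects, absolute agreement, single measures, with the
F-based 95% CI — the standard inter-observer convention. No
multiple-testing correction is applied anywhere, matching explorative
small-cohort practice. CHA~2~DS~2~-VASc uses the published point table
(age ≥ 75 and prior stroke/TIA score 2 points each).

## Numerical choices and degenerate inputs

* Nearest-frame lookups (E/A peaks, pre-ac, mask resampling) break exact
  ties toward the earlier frame.
* Readers validate geometry and reject mismatched grids, missing views,
  inconsistent point counts and non-increasing frame times instead of
  coercing.
* Empty masks, empty windows, degenerate (coplanar) stationary-voxel
  configurations, non-positive indexing volumes, and inverted volume
  landmark ordering all raise typed errors (`la_*_error` classes).
* The offset fit requires at least 16 stationary voxels and full column
  rank of the design.
* Zero-variance samples in t-type tests resolve by convention (p = 1 for
  no difference, p -> 0 for a constant shift) rather than erroring.

## Problem sizes used in validation

The shipped test-suite exercises: oracle equivalence on 100 random
6×6×6 voxel, 8-frame fields; offset recovery and parameter recovery on
30³-voxel, 20-frame phantoms (three noiseless, three at 1 cm/s noise);
scaling-law properties on 20 random fields; and one 30 + 30-subject
cohort through the full pipeline (offset detection, fit, correction,
volumetry, metrics). These sizes give stable estimates while keeping the
whole suite in the low minutes on one CPU; all fixtures are generated in
code at run time.

## Known limitations

* The stasis threshold interacts with noise: near-threshold samples make
  the `timefrac` stasis of noisy data differ from the noiseless truth by
  a few percent relative; the recovery suite bounds this at 5% for
  1 cm/s noise.
* Landmark volumes recover to within ~2%: voxelization of a ~3 mm grid
  and frame-quantised timing dominate, improving monotonically with
  resolution.
* `v_preac` depends on the supplied pre-ac annotation; the package does
  not attempt P-wave or inflow-onset detection.
* Whole-cycle statistics are computed over the gated ~90% coverage; they
  are not extrapolated to the missing late-diastolic window.
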