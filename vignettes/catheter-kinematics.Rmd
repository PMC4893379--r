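---
title: "Kinematic assessment of endovascular skill: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinematic assessment of endovascular skill: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cathkin)
```

## Overview

`cathkin` quantifies endovascular catheter-manipulation skill from the 2-D
motion of the catheter/guidewire tip on a fluoroscopy screen during a
two-stage phantom cannulation task (stage 1: navigation over the aortic arch;
stage 2: crossing a stenosed aortic valve into the ventricle). This vignette
explains the measurement model, the tunable parameters and their defaults,
the synthetic-data generator used throughout the tests, and the numerical and
design choices that were genuinely open.

## The measurement model

Per stage, the package reduces a trajectory to seven features. Procedure time
`T_p` and path length `PL` are direct. Average speed is defined as
`v_d = PL / T_p` rather than the mean of instantaneous speeds so that pauses
(the instrument held stationary) lower the score: efficiency, not peak speed,
is the construct. Average acceleration is the mean per-sample magnitude
`sqrt(a_x^2 + a_y^2)` (the alternative — the magnitude of the mean
acceleration vector — is nearly zero for any back-and-forth movement and was
rejected; it can be reconstructed from the per-axis derivatives if needed).

Movement smoothness uses the dimensionless jerk

$$ j_d = \left( \tfrac12 \int_{t_i}^{t_e} \dddot{x}(t)^2 + \dddot{y}(t)^2 \,
   \mathrm{d}t \right) \cdot \frac{T_p^5}{PL^2}, $$

whose $T_p^5 / PL^2$ factor removes all dependence on movement duration and
amplitude: rescaling space by any $c$ and time by any $k$ leaves $j_d$
unchanged (the test suite asserts this to $10^{-6}$ relative). A single ideal
minimum-jerk movement — position profile $10\tau^3 - 15\tau^4 + 6\tau^5$ —
has $j_d = \tfrac12 \int_0^1 (60 - 360\tau + 360\tau^2)^2 d\tau = 360$
exactly, which the implementation reproduces within 1% at 1 kHz sampling.
Lower is smoother; values explode combinatorially with sub-movement count,
pauses and tremor, which is exactly what makes the metric discriminative.

Safety is captured by the mean distance of the tip (and of the annotated
catheter shape) to the vessel wall. The vessel lumen is segmented from the
screen image by threshold binarization (strict `intensity > threshold`;
`"auto"` = maximal between-class variance over the histogram) and each lumen
pixel is assigned its exact Euclidean distance to the nearest background
pixel. The distance transform is computed by the two-pass separable
lower-envelope algorithm on integer squared distances, so its output is
bit-identical to an exhaustive all-pairs search; trajectories are then looked
up with bilinear interpolation.

## The differentiation pipeline

Raw tracks are pixel-quantized and noisy; third derivatives computed on them
directly are meaningless. The pipeline is:

1. **Resample** to a uniform grid spanning exactly the stage interval
   (default step 1/25 s, the PAL video rate implied by the 720 x 576 canvas;
   the step is shrunk, never grown, so both endpoints stay on the grid).
2. **Smooth** with a Savitzky–Golay filter (default window 9 samples, order
   3); polynomials up to the order pass through unchanged, so constant
   velocity and constant acceleration are never distorted.
3. **Differentiate** by central differences (second order for acceleration,
   the 5-point antisymmetric stencil for jerk) using the effective grid step,
   and integrate the squared jerk by the trapezoidal rule. The central
   stencil loses two samples per edge; the integrand is extended to the
   interval boundary with its nearest interior value because a minimum-jerk
   pulse has *maximal* jerk at its endpoints and dropping them biases the
   oracle value visibly (−1% at 1 kHz).

Very short stages are mildly upsampled (step at most `T_p / 8`) so the
stencils fit. Heavy upsampling is deliberately avoided: linear interpolation
between native samples creates curvature kinks which smoothing cannot fully
remove, and the jerk of an interpolated track then reflects the interpolation,
not the movement. Stage intervals are cut at the sample nearest each
annotated boundary; consecutive stages share the boundary sample, so path
segments are never double-counted.

## Screen rectification

The fluoroscopy monitor is filmed by an external camera from an arbitrary
position, so recordings differ by a perspective distortion. Mapping the four
marked screen corners to the canonical 720 x 576 rectangle requires a plane
projective map in general; the implementation solves the standard 8-parameter
linear system and degenerates exactly to the affine case (zero projective
terms) whenever the source quadrilateral is a parallelogram, i.e. when the
camera was fronto-parallel. Coordinates are warped, not pixels: the package
rectifies trajectories and shape annotations, which is lossless and cheaper
than warping video.

## Tip tracking

Tracking is brute-force zero-normalized cross-correlation of a small template
around the previous position, the fully specified half of the semi-automated
protocol used for screen recordings (the interactive half is replaced in
batch mode by flagging frames whose best score falls below a threshold,
default 0.6, plus an optional re-seed map). Matches are refined to sub-pixel
precision by a parabolic fit through the score peak.

Template handling deserves a note. By default the template is refreshed from
every newly matched position, which is the right choice for a real,
deforming catheter. On rigid synthetic targets, however, per-frame refresh
performs a random walk in the rounding errors and can drift onto the static
background, which then matches itself perfectly forever — the failure is
silent because the score stays high. `template_update = "fixed"` keeps the
seed template and is drift-free whenever the target's appearance is constant;
the synthetic round-trip tests use it and recover the rendered tip to
~0.15 px RMS (noise sd 2 greylevels) with no flagged frames. Users tracking
real video should keep the default and expect to re-seed occasionally.

## The synthetic generator

No recordings ship with the package, so all tests run on a synthetic study
designed to emulate the real one's structure:

- **Phantom.** A type-I aortic arch on a 720 x 576 canvas: vertical
  descending limb (length 200 px, lumen radius 18 px), semicircular arch
  (radius 120 px), ascending limb tapering into a 6 px stenotic valve, and a
  rounded ventricle chamber beyond it (rendered by widening the radius
  profile, which keeps the lumen an exact union of discs along the
  centerline — convenient for oracle testing and visually an elliptical
  chamber). Stage 1 ends 40 px proximal to the valve: 2 cm at the assumed
  20 px/cm scale, since no image scale is recorded for the original screens.
- **Trajectories.** Arc-length progress along the centerline is a sum of
  minimum-jerk sub-movements separated by pauses — the standard
  ballistic-sub-movement model of aimed human movement. Skill enters through
  the number of sub-movements, the fraction of time paused, white positional
  tremor, the probability of overshoot-plus-correction, and a smooth lateral
  wander inside the lumen (first-order autoregressive, coefficient 0.95,
  because catheters deflect smoothly rather than jumping between walls).
- **Defaults.** Expert: 6 sub-movements, 5% pauses, 0.5 px tremor, 5%
  corrections. Novice: 18 sub-movements, 35% pauses, 1.5 px tremor, 40%
  corrections. Robotic navigation scales speed by 0.5 (motion scaling for
  fine manipulation makes robotic runs slower). Mean sub-movement duration
  1 s, lateral wander sd 3 px, between-subject lognormal jitter sd 0.15 —
  chosen once as plausible for a tabletop phantom task. These defaults fix
  the *direction* of every group contrast (experts faster and smoother;
  robotic slower); the published medians of the real study are not
  recoverable because the generative parameters of human operators are
  unknown, so no default was tuned toward any printed value.
- **Sampling.** dt = 1/25 s. Frame sequences for tracker tests stamp an
  anti-aliased dark disc at the tip position on the phantom.

What passing tests on this generator do show: the feature definitions,
exact tests and clustering recover a known skill structure of realistic
geometry and sampling rate, end to end. What they cannot show: robustness to
real fluoroscopy artefacts (contrast changes, occlusion by other instruments,
catheter deformation, annotation error), or that the particular default
magnitudes match human novice/expert distributions.

## Exact statistics

With six subjects per group, normal approximations to rank-test null
distributions are poor, and tied feature values are possible; both tests
therefore enumerate their exact permutation null (all `choose(n1+n2, n1)`
group assignments for Mann-Whitney; all `2^n` sign patterns for the Wilcoxon
signed-rank test), with mid-ranks for ties, zero differences dropped, and
two-sided p equal to twice the smaller tail, capped at 1. The attainable
two-sided floor for six same-sign pairs is 2/64 = 0.03125. Note that a
two-sided exact Mann-Whitney p of 0.008 is not attainable for 6 vs 6 under
the doubled-tail convention (the neighbouring attainable values are 2·4/924 ≈
0.0087 and 2·2/924 ≈ 0.0043); the package reports the exact values it
computes.

## Clustering

Feature columns are standardized to zero mean and unit (population) variance
before clustering — procedure times of hundreds of seconds would otherwise
drown dimensionless jerk. k-means runs Lloyd iterations from 100 random
initializations (two distinct data points each), keeps the best
within-cluster SSE, and re-seeds an emptied cluster at the point farthest
from the surviving center; on 12-point data this recovers the exhaustive
global optimum in ≥96% of random instances. The Gaussian mixture uses
two diagonal-covariance components — with a dozen points and 2–4 features a
full covariance is singular — with variances floored at 1e-4 of the column
variance, initialized from the best k-means partition (a deterministic
tightening of plain random initialization), and iterated until the
log-likelihood gain falls below 1e-8; the log-likelihood trace is returned
and is non-decreasing by construction. Accuracy against known labels is the
maximum over the two cluster-to-label bijections, so a perfectly
anti-aligned assignment scores 1 and chance on balanced 12-point data is
at least 0.5.

Heavy-tailed features (dimensionless jerk spans orders of magnitude across
skill levels) can let a single extreme subject dominate the standardized
scale and occasionally cost the partition a subject or two; log-transforming
such features before `run_discrimination()` is a reasonable user-side remedy
that the package leaves to the analyst.

## Degenerate inputs and edge rules

- Binarization is strict (`>`), so a uniform image at the threshold value is
  all background; an all-foreground mask has no wall and the distance
  transform refuses it.
- Zero-variance NCC patches (blank frames, flat templates) score 0 rather
  than NaN; offset ties break toward the smallest displacement, then
  row-major order.
- A trajectory with (numerically) zero path length has no defined jerk
  normalization and errors out; a stage interval must contain at least 5
  (acceleration) or 7 (jerk) uniform samples.
- All-zero paired differences leave the signed-rank test undefined (error),
  matching the zero-drop convention.
- Coordinates are 0-based pixel centers, x = column rightward, y = row
  downward, in every format and function.

## Reproducibility

Every stochastic routine takes a seed and restores the caller's RNG state;
`run_pipeline()` derives all stage seeds from one global seed, and repeated
runs are byte-identical. The test suite sizes its heaviest check (100
simulated 12-subject cohorts through features, exact tests and clustering) to
run in about a minute; `scripts/acceptance.R` recomputes the headline
quantities over 30 cohorts in a few seconds each.

## Known limitations

- The generator draws sub-movement amplitudes and durations independently;
  real aimed movements show speed-accuracy coupling (Fitts-like) that is not
  modelled.
- Tremor is white; physiological tremor is band-limited (~8–12 Hz) and would
  interact differently with the Savitzky–Golay filter at other sampling
  rates.
- `d_shape` uses the vessel centerline as the synthetic catheter body, so
  synthetic shape-vs-tip contrasts are milder than with a real catheter
  hugging the outer wall.
- The tracker is translation-only; rotation or scale changes of the tip
  appearance degrade the match score and surface as flagged frames rather
  than being compensated.
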