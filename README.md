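# cathkin

Objective assessment of endovascular catheter-manipulation skill from
catheter-tip kinematics.

## The problem

In transcatheter procedures such as TAVI (transcatheter aortic valve
implantation), a surgeon steers a catheter/guidewire from the descending
aorta, over the aortic arch, and across a stenosed valve into the left
ventricle, guided only by a fluoroscopy screen. Assessing how *skilfully*
this is done has traditionally relied on expert raters. `cathkin` implements
a fully objective alternative: track the 2-D tip position on the screen,
reduce it to a small set of kinematic features, and test and cluster those
features by experience group (novice vs expert) and by equipment type
(conventional catheters vs a robotic platform).

The package is aimed at researchers in surgical-skill assessment and
image-guided intervention who want a tested, reproducible reference
implementation of this pipeline, together with a synthetic phantom/trajectory
generator for methodological work when recordings are unavailable.

## What it computes

For each task stage (1: arch navigation, 2: valve crossing), from a tip
trajectory (x(t), y(t)) in canonical screen pixels:

- procedure time `T_p` (s) and path length `PL` (px);
- average speed `v_d = PL / T_p` (px/s) — pauses lower it by construction;
- average acceleration magnitude `a_d = mean(sqrt(a_x^2 + a_y^2))` (px/s²);
- dimensionless jerk, the duration- and amplitude-independent smoothness
  measure (lower = smoother):

  `j_d = ( 0.5 ∫ x‴(t)² + y‴(t)² dt ) · T_p⁵ / PL²`

  A single ideal minimum-jerk movement has `j_d = 360` exactly;
- mean distance to the vessel wall of the tip (`d_tip`) and of the annotated
  catheter shape (`d_shape`), in px, from an exact Euclidean distance
  transform of the segmented vessel lumen — a surrogate for safe navigation
  (larger = farther from the wall, less embolisation risk).

Group comparisons use *exact* small-sample tests (full-enumeration
Mann-Whitney U across experience groups, Wilcoxon signed-rank across
equipment within group; two-sided p = doubled smaller tail). Unsupervised
discrimination uses k-means (restarted Lloyd) and a two-component
diagonal-covariance Gaussian mixture fitted by EM, scored against the true
labels by permutation-matched accuracy.

Supporting modules: projective rectification of the recorded fluoroscopy
screen into a canonical 720 x 576 frame; threshold (Otsu) segmentation of the
vessel phantom; brute-force normalized cross-correlation tip tracking with
low-confidence frame flagging; and a synthetic generator producing a type-I
aortic-arch phantom and skill-conditioned tip trajectories built from
minimum-jerk sub-movements with pause, tremor, lateral-drift and
overshoot-correction parameters.

## Worked example

```r
library(cathkin)

cfg <- pipeline_config(n_expert = 6, n_novice = 6, seed = 42)
out <- run_pipeline(cfg)

subset(out$summary, stage == 1 & feature %in% c("T_p", "j_d", "d_tip"),
       c(feature, median_novice_conventional, median_expert_conventional,
         p_mw_conventional))
#>  feature median_novice_conventional median_expert_conventional p_mw_conventional
#>      T_p                   3.01e+01                   5.84e+00           0.00216
#>      j_d                   2.28e+10                   1.89e+06           0.00216
#>    d_tip                   1.59e+01                   1.65e+01           0.13203

out$clustering$n_correct
#> 12   # of 12 subjects correctly grouped by experience (k-means on T_p, v_d, a_d, j_d)
```

Reading the numbers: the six simulated experts complete stage 1 in a median
5.8 s versus 30.1 s for novices, with a far smaller dimensionless jerk
(smoother tracks); both contrasts are significant at the exact Mann-Whitney
floor-adjacent p = 0.0022 for 6 vs 6. Tip distance-to-wall differs little
between groups, as expected when both stay near the lumen centerline.
Unsupervised k-means on the four stage-1 motion features recovers the
experience groups perfectly in this cohort.

The same functions work on real data: read a tracked trajectory with
`read_trajectory_csv()`, rectify it with `fit_screen_transform()` /
`apply_transform()`, segment a phantom frame with `binarize()` +
`distance_image()`, and feed everything to `extract_features()`,
`summarize_cohort()` and `run_discrimination()`.

## Documentation

The methods vignette (`vignettes/catheter-kinematics.Rmd`) describes the
model, the synthetic generator and its defaults, numerical choices in the
differentiation pipeline, and known limitations.
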