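---
title: "Models and methods behind vswim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vswim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vswim)
```

## The behavior being measured

Larval zebrafish swim in discrete propulsive events ("bouts") separated by
quiescent inter-bout intervals (IBIs). Because larvae are front-heavy, they
are unstable in the pitch axis (nose-up/nose-down) and must use swimming
itself to stay balanced and to climb or dive. Four scalar parameters
summarize how a cohort does this:

* **Bout-timing sensitivity.** Bout frequency (the reciprocal of the IBI
  duration) grows with postural eccentricity. On raw (IBI pitch, bout
  frequency) points we fit the vertex-form parabola
  \(y = a (x - b)^2 + c\): `a` is the sensitivity (reported in mHz/deg²),
  `b` the posture of minimal movement rate, `c` the baseline bout rate (Hz).
* **Steering gain.** The slope of the OLS line of pitch at peak speed on
  bout trajectory (the elevation angle of the displacement at the time of
  peak speed). A gain of 1 means larvae point exactly where they go.
* **Fin–body ratio.** Attack angle (trajectory minus pitch at peak speed;
  the lift contributed by the pectoral fins) as a logistic function
  \(y = a + h/(1 + e^{-k(x+b)})\) of the steering-related rotation (pitch
  change from bout start to the time of peak angular velocity). The maximal
  slope \(kh/4\) measures the division of labor between trunk and fins.
* **Righting gain and set point.** Righting rotation (pitch change from the
  peak to +100 ms) regressed on initial pitch; the negated slope is the
  righting gain and the x-intercept the preferred posture ("set point").

All fits are least squares on raw per-bout / per-IBI points;
`binned_average()` exists for display only.

## Bout segmentation

A *bout* is a maximal span with instantaneous speed strictly above 5 mm/s;
within an epoch (a contiguous run of frames with exactly one tracked
animal), each such span contributes one bout aligned at its speed maximum
(first frame on ties; t = 0 at the peak). A bout is kept only if the full
window from 500 ms before to 300 ms after the peak lies inside its epoch,
so every aligned window has exactly `round(0.5 fps) + round(0.3 fps) + 1`
samples. Only epochs longer than 2.5 s that reach a super-threshold speed
are analyzed. IBIs are the sub-threshold spans between consecutive bouts,
shortened by a 100 ms buffer at each end to absorb detection error;
non-positive durations are discarded, and the IBI pitch is the mean pitch
over the buffered interval.

Quality control discards epochs with (i) a frame-to-frame displacement
above `qc_max_jump` — by default a 150 mm/s pace equivalent, an order of
magnitude above typical swim speed, so tracking teleports are caught while
genuinely fast bouts (the speed SD is ~5 mm/s around a 13 mm/s mean, so a
25 mm/s bout is ordinary) are kept; (ii) a recorded fish length deviating
more than 40% from the session median; (iii) missing frames. Every
exclusion is logged with its reason.

Speed may be smoothed with a 3-frame centered moving average
(`speed_smoothing = 3`), a robustness default for noisy tracking. On clean
simulated traces the smoother systematically attenuates raised-cosine speed
peaks by roughly 1%, so exactness and recovery analyses (including the
acceptance script) run with smoothing off. The 5 mm/s comparison is
strictly greater-than; at the printed precision of the threshold the choice
is immaterial, and we state it for reproducibility.

## The synthetic swimmer

No generative model of this behavior is published, so the package defines
one explicitly, with two modes.

**Targeted mode** (`generate_relationship_samples()`) draws (x, y) pairs
directly from one relationship with Gaussian predictors and residuals, so a
fit recovers the generating coefficients exactly in expectation; residual
SDs default to values consistent with the published goodness-of-fit
(steering 6°, righting 3°, fin–body 5°, timing 0.6 Hz). This is the mode
for coefficient-recovery and resolution analyses: the four relationships
cannot in general hold simultaneously and exactly in one dataset.

**Session mode** (`sample_bout_latents()` + `simulate_session()`) realizes
a causal chain per bout — IBI pitch → IBI duration (inverse-rate with
lognormal mean-1 noise, so expected bout frequency is proportional to the
timing parabola \(\lambda(p)\) — with proportionality constant
\(e^{\sigma^2}\) from the reciprocal of the lognormal, so session-mode
parabola fits recover the *shape* (vertex) exactly but scale `a` and `c`
by that constant; targeted mode recovers all coefficients — unlike an
exponential model whose reciprocal has no mean) → initial pitch →
steering-related rotation → attack angle (logistic) → pitch at peak →
trajectory (= pitch at peak + attack angle, exact) → righting rotation →
peak speed — and lays it onto a continuous 166 Hz trace: raised-cosine
speed bumps whose width sets the net displacement to the profile's mean
bout displacement, a pre-peak steering ramp, a post-peak righting ramp
completing by +100 ms, and linear-drift-plus-jitter pitch between bouts
(the between-bout drift law is unpublished; the piecewise-linear
relax–hold–approach profile is a stand-in, flagged as such).

Choices that deserve justification:

* **Peak speed.** Printed speed statistics describe *detected* bouts,
  which are conditioned on exceeding the 5 mm/s threshold. The generator
  therefore solves for the parent normal whose truncated-at-5 distribution
  has exactly the quoted mean/SD (`match_truncated_normal()`), rather than
  truncating a normal with the quoted parameters (which would inflate the
  mean by ~0.6 mm/s).
* **Pitch chain.** Reference tables mix means and medians, so the IBI
  pitch mean, steering-related rotation mean and pitch-at-peak centre
  cannot all be honored through rotation alone. The reconciliation is a
  small deterministic nose-down drift between the IBI and the bout's start
  — consistent with front-heavy larvae falling nose-down between bouts —
  leaving the pre-peak residual rotation with its table-implied mean
  (steering rotation minus steering-related rotation).
* **Angular velocity.** The pre-peak ramp is a constant base rotation rate
  plus a *symmetric* squared-cosine angular-velocity bump centered at the
  angular-velocity lead time (default from the age's reference value,
  39.16 ms at 7 dpf), with base and bump areas solved so the pitch at the
  bump centre and at the peak equal the latents exactly. Symmetry matters:
  the measured peak time is read off an 11-frame-smoothed median trace, and
  a boxcar smoother preserves the location of a symmetric peak while
  shifting an asymmetric one by tens of ms. Under full per-bout noise the
  median-trace peak still wanders by a few frames between repeats — more
  than the ~5 ms repeat-to-repeat SD of real data — which is a known
  limitation of the generator, so timing-recovery tests use low-noise
  profiles where recovery is deterministic.
* **Bout spacing.** Consecutive speed peaks are kept at least 420 ms apart
  (pre-ramp + post-ramp + a short drift): a larva cannot complete a full
  steering maneuver mid-way through a shorter pause. When the clamp binds,
  the realized IBI replaces the drawn one in the ground truth.
* **Sigmoid placement.** Reference tables publish the sigmoid height and
  maximal slope but not its horizontal position or lower asymptote; the
  profiles center the sigmoid at zero rotation and set the asymptote so the
  curve's midpoint reproduces the age's central attack angle.
* **Timing-parabola vertex.** Not published either; profiles place it at
  the age's mean IBI pitch (movement rate minimal at the typical posture).

What session mode does *not* emulate: turning and azimuthal kinematics
(heading is fixed), multi-animal interactions, slow drift of the tracker,
skewed/heavy-tailed posture distributions (all marginals are normal or
truncated-normal), and any dependence of bout timing on angular velocity.
Passing recovery tests on this generator therefore shows the pipeline's
numerics are correct under the stated model, not that the model captures
every feature of real data.

## Rendering and tracking

`render_frames()` paints a body ellipse plus a brighter head disc (head
centered inside the front of the ellipse so the blob is connected) on a
static noisy background, and records the painted body- and head-pixel
centroids as per-frame ground truth — the body-band centroid is the honest
reference for the tracker, since the head disc removes pixels from the
ellipse and shifts the body centroid along the axis. The tracker mirrors
the acquisition algorithm: absolute background difference, an initial-cut
intensity band, 8-connected components with a 5-px noise floor, rejection
of frames with zero or multiple animal-scale blobs or out-of-range pixel
counts, and an intensity-band split of the blob into head (head band) and
body (remainder). Head/body bands are applied to the *raw* frame within
the foreground mask (the alternative — banding the subtracted image — is a
one-line change and matters only if the background is bright). Pitch is
the elevation of the head-minus-body centroid vector, nose-up positive and
invariant to heading; image rows grow downward, so z is negated before
records are written. Published per-organism thresholds are available
verbatim via `tracker_preset()`.

## Resolution analysis

`ci_width_vs_n()` resamples N points with replacement (20 resamples per N),
refits, and converts each fit's standard error into a normal-approximation
CI width \(2 z_{0.975} \cdot SE\); the fin–body ratio's SE comes from the
propagation formula
\(V = (E_k^2 V_h + E_h^2 V_k + V_k V_h)/16\)
(`finbody_slope_variance()`). `impose_effect()` scales one target
coefficient by \(1 + f\) (for the fin–body ratio, k, so the maximal slope
scales exactly by \(1+f\)) while keeping all other coefficients and the y
residuals at the given x values. `effect_size_curve()` draws N points
independently from the original and altered datasets (paired index draws
are a documented alternative, not the default), fits each, repeats 200
times (`inner_reps`), and reports Cohen's d with \(\sigma\) taken over all
400 pooled values, averaged over 20 outer repetitions; resampling units
are bouts/IBIs, not fish or repeats. Failed fits are redrawn and the
redraw count reported, so silent bias toward convergent subsets is
visible. Fin–body fits inside the simulation use a fixed 40 ms
angular-velocity lead to bound runtime.

## Numerical choices

* OLS and the quadratic fit use `stats::lm`; vertex-form coefficients and
  SEs follow by the delta method from the polynomial covariance. The
  parabola is fit unconstrained; a negative baseline rate is flagged with a
  warning rather than forced positive.
* The logistic fit is multi-start Levenberg–Marquardt
  (`minpack.lm::nlsLM`, 5 data-driven starts, bounds \(k \in [0, 10]\),
  \(h \in [0, 90]\), tolerances 1e-10), because sigmoid least squares is
  multimodal; the best converged start by SSE wins, and total
  non-convergence is an error carrying diagnostics.
* The 50th-percentile exclusion for the fin–body fit (steering rotation
  above the median of the speed-filtered set *and* negative attack angle)
  is computed on the set being fit, pooled or per repeat.
* Trajectory uses the two frames flanking t = 0 (`atan2(dz, |dx|)`, range
  (−90°, 90°]); a wider displacement window is a documented alternative.
* Righting gain is −slope. Published phrasings ("absolute value",
  "inverse", "numeric inversion") coincide for corrective (negative-slope)
  behavior; for non-corrective data the signed convention is reported with
  a warning.
* Ties at the bout peak go to the earliest frame; multi-peak
  super-threshold spans yield one bout at the global maximum.

## Problem sizes

Recovery tests use 10,000 targeted-mode pairs per relationship; the
end-to-end check simulates a 9,000 s session (≈ 5,300 extractable bouts);
the resolution grid is N ∈ {500, 2000, 8000} with inner_reps 50 and 40
outer repetitions; tracker accuracy uses ~260 rendered 400×400 frames.
These sizes give standard errors comfortably below the tolerances being
asserted while keeping the whole suite around a minute of compute.

## Known limitations

Azimuthal behavior, bout-type classification, angular-velocity-dependent
timing models, and between-condition hypothesis testing are out of scope.
The generator's normal marginals understate the skew of real posture
distributions, and its angular-velocity peak time is noisier across
repeats than real data. Coordinates are standardized to mm (with
`mm_per_pixel` in metadata); the record dialect fixes what the acquisition
software leaves open (tab separator, no header, 6-decimal floats).
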