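---
title: "Methods: reliability-weighted cue integration in smooth pursuit, from eye traces to a time-shifted linear model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pursuit dissimilarity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pursuitmvpa)
```

## The scientific question

When a motion cue precedes a pursuit target, the oculomotor system combines
the two direction estimates. Under reliability weighting (Bayesian cue
integration), the weight of each source is proportional to its precision:
a low-contrast target is less reliable, so the cue attracts the executed
pursuit direction more. This package implements the full analysis chain used
to study that integration behaviorally (rotated-trace distance statistics),
neurally (cross-validated Mahalanobis dissimilarity of multichannel epochs),
and mechanistically (a time-shifted linear model relating neural
dissimilarity to sensory and motor dissimilarity), together with a synthetic
generator that emulates the statistical structure of such an experiment so
that every stage is testable against known ground truth.

## The synthetic generator

`sim_config()` + `simulate_eye_traces()` produce per-trial eye position and
velocity (1 kHz, −100..500 ms around target motion onset). The executed
direction is the reliability-weighted circular mean of target and cue
directions, computed on unit vectors (`atan2` of weighted component sums) —
correct for angles, and indistinguishable from the linear mean over the
±60° span used. Key parameters, all overridable:

* `directions = c(0, -30, -60)` deg and `contrasts = c(1, 0.12)` — the
  three-direction, two-contrast design; `target_speed = 16` deg/s.
* `target_reliability_by_contrast = c("1" = 9, "0.12" = 3)` and
  `cue_reliability = 1`. With these defaults the cue pulls an invalid-block
  trial by about 6° at high contrast and about 15° at low contrast — a
  moderate, behaviorally plausible attraction that makes the low-contrast
  cue effect clearly larger, which is the regime of interest.
* `latency_mean_by_contrast = c("1" = 105, "0.12" = 124)` ms with
  `latency_jitter_sd = 10` ms. Only the low-contrast value is anchored in
  measurement (~124 ms); high-contrast pursuit latency is shorter, and
  105 ms is a placeholder typical of high-contrast pursuit.
* The speed ramp is a single-rate exponential
  (`pursuit_gain = 0.02` /ms, time constant 50 ms) toward
  `steady_state_gain = 0.9` of target speed. Open-loop pursuit undershoots
  the target; a steady-state gain below 1 is the standard description and
  leaves a persistent retinal velocity error inside the trial, which is
  what makes the integrated error keep growing after the velocity
  difference between directions has plateaued.
* `saccade_rate` injects brief (24 ms) 50-deg/s half-sine transients inside
  −100..250 ms, for exercising the screening rules.

`generate_epochs()` is a forward mixture model: channel `c` on a trial with
direction `d` is

    x_c(t) = w_s P_s(c, d) |IRVE|(t + t_s) + w_m P_m(c, d) speed(t + t_m) + noise

with direction-specific random spatial patterns drawn once from
`spatial_pattern_seed`, true mixture defaults `(w_s, w_m) = (1, 0.5)` and
`(t_s, t_m) = (-35, 27)` ms, and Gaussian noise with a low-rank shared
spatial component plus independent channel noise (`noise_spatial_rank = 5`),
giving realistic channel correlations with a full-rank covariance.

What the generator does *not* emulate: volume conduction or any biophysical
head model, oscillatory structure, eye blinks, drifts or non-stationarities
across a session. Passing tests therefore demonstrate the correctness and
calibration of the estimators under the assumed statistical structure, not
robustness to every artifact of real recordings.

## Behavioral statistics

`screen_saccades()` rejects a trial if eye speed exceeds 5 deg/s during
fixation (−100..100 ms) or 20 deg/s during early pursuit (100..250 ms).
`estimate_latency()` marks pursuit onset as the first time in 50..300 ms at
which speed exceeds baseline mean + 3 SD for at least 20 consecutive ms;
this estimator is a documented stand-in chosen from standard oculomotor
practice (the underlying published procedure is not specified in detail),
with all parameters exposed. A zero-variance baseline falls back to an
absolute 2 deg/s threshold.

`rotate_and_distance()` rotates every velocity trace by −30°, mapping the
midline between the outer target directions onto the horizontal axis, and
takes the *absolute* vertical separation of the two direction-group means
(Δy). Whether the separation should be signed is ambiguous; the absolute
value matches the geometry in which rotation symmetrizes the two directions
about the horizontal (`distance = "euclidean"` gives the full 2-D distance
between the rotated mean velocity vectors instead). With valid and invalid blocks present it reports
Δy(valid) − Δy(invalid) and its value 100 ms after pursuit latency (the end
of the open-loop period). Alignment defaults to the per-block mean estimated
latency, rounded to the 1-ms grid.

## Cross-validated Mahalanobis dissimilarity

`preprocess_epochs()` applies a ±10 ms rectangular moving average (output
axis trimmed so every point has a full window), per-day division by the
day's maximum absolute value (placing recording days on a common scale),
then per-channel z-scoring over times and trials.

`crossval_dissimilarity()` computes, per time point, leave-one-trial-out
distances of each held-out pattern to its own-condition mean (D11) and the
other-condition mean (D12) under the pseudo-inverse of the pooled
covariance, and reports D12 − D11, which is ≈ 0 under exchangeability and
positive when patterns differ. Numerical and design choices:

* *Covariance pooling*: per-condition covariances about each condition's
  own mean, pooled with degrees-of-freedom weights. The exact
  "variance-stabilized" pooling used historically is underspecified; this
  df-weighted pooling plus shrinkage is the standard remedy and is
  pluggable (`shrinkage = "auto"` uses a Ledoit–Wolf analytic coefficient
  toward a scaled identity, a fixed λ or `"none"` are available).
* *Per-time-point covariance* (not pooled over time), matching the
  "at each time point" definition; `time_pooled_cov = TRUE` averages the
  covariance over the evaluated time points when channel noise can be
  assumed stationary.
* *Symmetrization*: the defining equations are written from condition 1's
  perspective; by default both role assignments are averaged
  (`symmetrize = FALSE` reproduces the one-sided form exactly, and the
  test suite checks both against an independent loop-based oracle).
* *Trial-count matching*: unequal counts are handled by 10 seeded random
  subsamples of the larger condition, averaged; with equal counts the
  subsampling is a no-op and the result is seed-independent.
* Degenerate inputs: all-zero patterns give a zero pseudo-inverse and a
  zero dissimilarity rather than an error; constant channels z-score to 0
  with a message.

`feature_dissimilarity()` runs the same machinery with the horizontal and
vertical components of an eye-movement feature (velocity, position, retinal
velocity error, or its integral) playing the role of channels.
`select_channels()` implements the 47-channel analysis montage (64 minus 17
artifact-prone electrodes) and the frontal-central (13) and central-parietal
(14) regional groups.

## Sensory and motor features

The retinal velocity error (RVE) is target velocity minus eye velocity;
before motion onset the target is static. Its cumulative trapezoidal
integral (IRVE, in deg) starts at stimulus onset (t = 0): the dots already
move during the initial local-motion phase, so integrating from 0 is the
natural choice; the start is a parameter because integrating from global
motion onset (100 ms) is also defensible. Trapezoidal integration at 1 ms
steps keeps the linearity identities exact to numerical precision.

## The time-shifted linear model

`fit_dissim_model()` fits

    E(t) = w_s S_IRVE(t + t_s) + w_m M_vel(t + t_m)

jointly to four condition traces (valid/invalid × high/low contrast) over
30..330 ms with one shared parameter set; the full variant adds retinal
velocity error (sharing t_s) and eye position (sharing t_m), six free
parameters in total. Regressors are max–min normalized jointly across
conditions and time so the weights are relative contributions; the neural
trace is left unnormalized (normalizing it too would only rescale the
weights, and leaving it raw keeps residuals in the units of the observed
dissimilarity). The four conditions enter the residual sum of squares with
equal weight.

Because the weights enter linearly, they are profiled out: for every
candidate integer-ms shift pair the weights have a closed-form least-squares
solution, and an exhaustive grid over `shift_bounds = c(-100, 100)` ms
(covering the plausible −35/+27 ms regime with wide margin) finds the
*global* optimum deterministically — replacing a derivative-free multistart
search whose optimizer choice is incidental to the science. RSS ties are
broken toward the smallest |t_s| + |t_m|; collinear candidates are solved by
the least-norm solution. A seeded multistart local search is provided as an
option and agrees with the grid in testing. There is no intercept by
default (the model has none); `intercept = TRUE` is available and makes
residuals mean-zero.

`residual_differences()` subtracts the model prediction per condition and
forms the valid-minus-invalid residual difference per contrast — the trace
on which any cue-integration component not explained by sensory input or
motor output should survive, ready for `cluster_test()`.

### Design of the parameter-recovery study

The recovery study (acceptance tests and `scripts/acceptance.R`) generates
four-condition data from known `(w_s, w_m, t_s, t_m) = (0.8, 0.6, -35, 27)`
with smooth condition-specific sigmoid templates and white noise at 25% of
the signal SD. The true weights are chosen to give both components
comparable energy: when the motor component is much weaker than the sensory
one, its time shift is intrinsically poorly identified (the same reason the
motor shift carries a much larger uncertainty than the sensory shift in
fitted real data), and the study would then measure identifiability rather
than estimator quality. The sensory-dominant regime is exercised separately
through the forward-model defaults (mixture 1 : 0.5) in the generator and
pipeline tests. Noiseless data are recovered exactly (RSS = 0, R² = 1).

## Cluster-based permutation inference

`cluster_test()` thresholds per-time one-sample t values across participants
at a two-sided cluster-defining p (0.05 or 0.01 are the conventional
choices), sums t within contiguous same-sign suprathreshold runs, and
compares each cluster mass against the permutation distribution of the
maximum absolute mass under participant-level sign flips — the exact
implementation of "shuffling the data with zeros" for a test against zero.
Both signs enter one null distribution (two-sided familywise control), and
the +1/(n+1) convention keeps p values strictly positive. Paired
comparisons test the difference of two condition matrices. 50,000
permutations are appropriate for final inference; the package's tests use
300–1,000 permutations, which is ample for calibration checks.

## Problem sizes used by the tests and acceptance script

These are desk-scale choices that keep the whole suite fast while leaving
each check statistically meaningful: oracle equivalence on 20 random
instances (≤4 channels, ≤10 trials); null calibration over 200 simulated
datasets (24 trials/condition, 3 channels, 10 time points); parameter
recovery over 100 seeded replicates of the 4 × 301-sample design;
familywise error over 500 null replicates (14 participants × 60 time
points, 1,000 permutations) and power over 200 replicates with a 50-ms,
1-SD injected effect; the behavioral contrast on 200 trials per design cell.
The end-to-end pipeline demo runs 2–3 simulated participants with 6–10
trials per cell and 6–16 channels.

## Known limitations

* The latency estimator and the covariance-pooling rule are principled
  stand-ins for underspecified procedures; both are parameterized so that
  alternatives can be swapped in.
* D12 − D11 with square-root distances is only approximately unbiased under
  the null (the leave-one-out mean uses n−1 trials while the other
  condition supplies n); the bias is far below Monte-Carlo resolution at
  the trial counts used, and the calibration test verifies this.
* The generator's epochs are stationary mixtures; conclusions about
  robustness to drifts, blinks or oscillatory confounds are out of scope.
* Epoch serialization uses wide CSV plus a JSON sidecar; large recordings
  would warrant a binary container instead.
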