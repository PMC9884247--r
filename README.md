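# pursuitmvpa

Analysis tools for studying **reliability-weighted (Bayesian) integration of
a motion cue and a pursuit target** in smooth pursuit eye movements and in
simultaneously recorded multichannel neural epochs — for oculomotor and
cognitive neuroscientists who want the full chain from raw traces to
inference in one tested, seedable package.

When a moving cue precedes a pursuit target, the brain combines the two
direction estimates with weights proportional to their reliability: a
low-contrast (unreliable) target lets the cue attract the eyes more. The
package quantifies this at three levels:

1. **Behavior** — trials are screened for saccades (speed > 5°/s during
   fixation, > 20°/s during early pursuit), pursuit latency is estimated,
   every velocity trace is rotated by −30° so the two outer target
   directions straddle the horizontal, and the vertical separation of the
   direction-group means, Δy(t), is compared between cue-valid and
   cue-invalid blocks (Δy₂ − Δy₁ at +100 ms after latency).

2. **Multivariate dissimilarity** — per time point, leave-one-trial-out
   cross-validated Mahalanobis distances

   D₁₁ = (1/n) Σᵢ √[(TD₁ − td₁ⁱ)ᵀ pC⁺ (TD₁ − td₁ⁱ)],
   D₁₂ = (1/n) Σᵢ √[(TD₂ − td₁ⁱ)ᵀ pC⁺ (TD₂ − td₁ⁱ)]

   where TD₁/TD₂ are condition means (own mean excluding the held-out
   trial), and pC⁺ is the pseudo-inverse of the pooled (optionally shrunk)
   channel covariance. D₁₂ − D₁₁ ≈ 0 under exchangeability and grows with
   pattern separation. The same machinery runs on 2-D eye-movement features
   (velocity, position, retinal velocity error and its integral, IRVE).

3. **A time-shifted linear model** — the neural dissimilarity trace is
   modeled jointly over four conditions (cue validity × contrast) as

   E(t) = w_s · S_IRVE(t + t_s) + w_m · M_vel(t + t_m)

   with weights profiled out in closed form and the shifts found by an
   exhaustive integer-ms grid (deterministic global optimum). Residual
   valid-minus-invalid differences isolate any cue-integration component
   not explained by sensory input or motor output, and a sign-flip
   cluster-based permutation test provides familywise-corrected inference.

A synthetic generator (`sim_config()`, `simulate_eye_traces()`,
`generate_epochs()`) emulates the whole experiment — cue-attracted pursuit
ramps, contrast-dependent latency, forward-mixed multichannel epochs with
spatially correlated noise, saccade artifacts — so every stage is testable
against known ground truth without any data download.

## Worked example

```r
library(pursuitmvpa)

cfg  <- sim_config(n_trials_per_cell = 60, n_channels = 4, seed = 7)
tr   <- simulate_eye_traces(cfg)
rep_ <- screen_saccades(tr)
rep_
#> screening_report: 674 kept, 46 rejected (fixation_speed:31, pursuit_speed:15)

kept <- apply_screening(tr, rep_)
low  <- which(abs(kept$meta$contrast - 0.12) < 1e-9)
rotate_and_distance(subset_traces(kept, low))
#> trace_distance: rotation -30 deg, align latency, blocks: valid, invalid
#>   delta_y(valid) - delta_y(invalid) at +100 ms: 1.465 deg/s
```

The 1.465 deg/s is the cue effect at low contrast: in invalid blocks the cue
pulls the two direction groups together, so their separation is smaller than
in valid blocks. At high contrast the same statistic is roughly a third of
that — the behavioral signature of reliability weighting.

Fitting the time-shifted model to synthetic four-condition dissimilarity
traces generated with true parameters (w_s, w_m, t_s, t_m) =
(0.8, 0.6, −35 ms, +27 ms) and 5% noise:

```r
fit <- fit_dissim_model(des)   # des: build_design(neural, sensory, motor)
fit
#> Time-shifted linear dissimilarity model (reduced)
#>   window 30..330 ms, 4 conditions
#>   weights:
#>         irve eye_velocity
#>       0.7879       0.6116
#>   t_s = -36 ms, t_m = 27 ms
#>   R^2 = 0.989 (RSS = 3.216)
```

The sensory (IRVE) signal leads the neural trace by ~35 ms and the motor
signal lags it by ~27 ms, recovered to within 1 ms here. `summary()`,
`coef()`, `predict()`, `residuals()`, `plot()` and `simulate()` methods are
available; `residual_differences(fit)` prepares the valid-minus-invalid
residual traces for `cluster_test()`.

`run_pipeline(pipeline_config(...), out_dir)` chains every stage
(simulate → screen → behavior → features → dissimilarity → fit →
residuals → cluster test) across simulated participants and writes a
manifest with md5 hashes; identical configs reproduce identical hashes.

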