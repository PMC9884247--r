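# Build an eye_trace_set directly from velocity matrices (trials x time),
# for hand-constructed behavioral cases.
make_traces <- function(vel_h, vel_v, time = -100:500,
                        target_dir = rep(0, nrow(vel_h)),
                        block = rep("valid", nrow(vel_h)),
                        contrast = rep(1, nrow(vel_h))) {
  n <- nrow(vel_h)
  structure(list(
    time = as.integer(time),
    vel_h = vel_h, vel_v = vel_v,
    pos_h = t(apply(vel_h, 1, pursuitmvpa:::cumtrapz1, dt = 1e-3)),
    pos_v = t(apply(vel_v, 1, pursuitmvpa:::cumtrapz1, dt = 1e-3)),
    meta = data.frame(trial_id = sprintf("t%03d", seq_len(n)),
                      target_dir = target_dir, cue_dir = target_dir,
                      exec_dir = target_dir, contrast = contrast,
                      block = block, day = "day1",
                      latency_true = NA_real_, saccade = FALSE,
                      stringsAsFactors = FALSE)),
    class = "eye_trace_set")
}

subset_features_idx <- function(f, idx) pursuitmvpa:::subset_features(f, idx)

# Small deterministic config used across tests.
quick_config <- function(n_trials_per_cell = 6, n_channels = 6, ...) {
  sim_config(n_trials_per_cell = n_trials_per_cell, n_channels = n_channels,
             seed = 42, spatial_pattern_seed = 7, ...)
}
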