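#' Simulation configuration
#'
#' Builds the parameter set for the synthetic pursuit experiment. The design
#' mirrors a cue-then-target smooth pursuit task: on each trial a motion cue
#' precedes a pursuit target moving at `target_speed` deg/s in one of
#' `directions`; target contrast is drawn from `contrasts`; in valid blocks
#' the cue direction equals the target direction, in invalid blocks it is
#' drawn at random from `directions`. The executed pursuit direction is the
#' reliability-weighted circular mean of cue and target directions, so the
#' cue attracts the eye more when target contrast (hence target reliability)
#' is low.
#'
#' @param n_trials_per_cell trials per direction x contrast x block cell.
#' @param directions target directions in degrees (0 = rightward, negative =
#'   clockwise/downward).
#' @param contrasts target contrasts as fractions in (0, 1].
#' @param target_speed target speed, deg/s.
#' @param cue_reliability precision weight of the cue direction estimate.
#' @param target_reliability_by_contrast named numeric vector mapping each
#'   contrast to the precision weight of the target direction estimate.
#' @param latency_mean_by_contrast named numeric vector of mean pursuit
#'   latencies (ms) per contrast.
#' @param latency_jitter_sd trial-to-trial latency SD, ms.
#' @param pursuit_gain exponential rise rate of the speed ramp, 1/ms.
#' @param steady_state_gain asymptotic eye speed as a fraction of target
#'   speed; open-loop pursuit undershoots the target, so the default is 0.9,
#'   leaving a persistent retinal velocity error within the trial.
#' @param vel_noise_sd white velocity noise SD on each component, deg/s.
#' @param n_channels number of recording channels in synthetic epochs.
#' @param channel_names channel labels; defaults to the 47-channel analysis
#'   set (or generic labels if `n_channels` differs from 47).
#' @param n_days number of recording days trials are split over.
#' @param spatial_pattern_seed seed for the fixed direction-specific spatial
#'   patterns and the noise mixing matrix.
#' @param mix_weights length-2 numeric `c(w_s, w_m)`: true sensory (IRVE
#'   magnitude) and motor (eye speed) mixture weights of the forward model.
#' @param mix_shifts length-2 numeric `c(t_s, t_m)` in ms: true time shifts;
#'   negative `t_s` means the sensory signal leads the channel data.
#' @param noise_sd channel noise scale (same units as the mixed signal).
#' @param noise_spatial_rank rank of the shared spatial noise component.
#' @param saccade_rate per-trial probability of an injected saccadic transient.
#' @param seed master seed for trial-level randomness.
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_trials_per_cell = 4)
#' tr <- simulate_eye_traces(cfg)
#' nrow(tr$meta)
#' @export
sim_config <- function(n_trials_per_cell = 20,
                       directions = c(0, -30, -60),
                       contrasts = c(1.00, 0.12),
                       target_speed = 16,
                       cue_reliability = 1,
                       target_reliability_by_contrast = c("1" = 9, "0.12" = 3),
                       latency_mean_by_contrast = c("1" = 105, "0.12" = 124),
                       latency_jitter_sd = 10,
                       pursuit_gain = 0.02,
                       steady_state_gain = 0.9,
                       vel_noise_sd = 0.3,
                       n_channels = 47,
                       channel_names = NULL,
                       n_days = 2,
                       spatial_pattern_seed = 99,
                       mix_weights = c(w_s = 1, w_m = 0.5),
                       mix_shifts = c(t_s = -35, t_m = 27),
                       noise_sd = 1,
                       noise_spatial_rank = 5,
                       saccade_rate = 0.05,
                       seed = 1) {
  cfg <- list(
    n_trials_per_cell = as.integer(n_trials_per_cell),
    directions = as.numeric(directions),
    contrasts = as.numeric(contrasts),
    target_speed = target_speed,
    cue_reliability = cue_reliability,
    target_reliability_by_contrast = target_reliability_by_contrast,
    latency_mean_by_contrast = latency_mean_by_contrast,
    latency_jitter_sd = latency_jitter_sd,
    pursuit_gain = pursuit_gain,
    steady_state_gain = steady_state_gain,
    vel_noise_sd = vel_noise_sd,
    n_channels = as.integer(n_channels),
    channel_names = channel_names,
    n_days = as.integer(n_days),
    spatial_pattern_seed = as.integer(spatial_pattern_seed),
    mix_weights = mix_weights,
    mix_shifts = mix_shifts,
    noise_sd = noise_sd,
    noise_spatial_rank = as.integer(noise_spatial_rank),
    saccade_rate = saccade_rate,
    seed = as.integer(seed))
  if (is.null(cfg$channel_names)) {
    cfg$channel_names <- if (cfg$n_channels == 47L) channel_group("default47")
                         else sprintf("ch%02d", seq_len(cfg$n_channels))
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg(cfg$n_trials_per_cell >= 1, "n_trials_per_cell must be >= 1")
  stopifnot_msg(all(cfg$contrasts > 0 & cfg$contrasts <= 1),
                "contrasts must lie in (0, 1]")
  stopifnot_msg(cfg$cue_reliability > 0, "cue_reliability must be > 0")
  stopifnot_msg(all(cfg$target_reliability_by_contrast > 0),
                "target reliabilities must be > 0")
  stopifnot_msg(all(cfg$latency_mean_by_contrast > 0),
                "latency means must be > 0")
  stopifnot_msg(cfg$latency_jitter_sd >= 0, "latency_jitter_sd must be >= 0")
  stopifnot_msg(cfg$steady_state_gain > 0 && cfg$steady_state_gain <= 1.5,
                "steady_state_gain must be in (0, 1.5]")
  stopifnot_msg(cfg$n_channels >= 2, "n_channels must be >= 2")
  stopifnot_msg(length(cfg$channel_names) == cfg$n_channels &&
                  !anyDuplicated(cfg$channel_names),
                "channel_names must be unique and match n_channels")
  stopifnot_msg(cfg$noise_spatial_rank >= 1, "noise_spatial_rank must be >= 1")
  stopifnot_msg(cfg$saccade_rate >= 0 && cfg$saccade_rate <= 1,
                "saccade_rate must be a probability")
  for (ct in cfg$contrasts) {
    lookup_by_contrast(cfg$target_reliability_by_contrast, ct)
    lookup_by_contrast(cfg$latency_mean_by_contrast, ct)
  }
  invisible(cfg)
}

lookup_by_contrast <- function(map, contrast) {
  keys <- as.numeric(names(map))
  i <- which(abs(keys - contrast) < 1e-9)
  if (length(i) != 1L)
    stop(sprintf("no entry for contrast %s in map (%s)",
                 format(contrast), paste(names(map), collapse = ", ")),
         call. = FALSE)
  unname(map[i])
}

eye_time_axis <- function() -100:500

#' Simulate cue-attracted pursuit eye traces
#'
#' Generates one trial per row of the full design (direction x contrast x
#' block x `n_trials_per_cell`). Each trial's executed direction is the
#' reliability-weighted circular mean of target and cue directions; eye speed
#' is zero until a Gaussian-jittered latency, then rises exponentially toward
#' `target_speed`. With probability `saccade_rate` a brief high-speed
#' transient (a saccade) is injected inside the -100..250 ms screening
#' window. Position is the cumulative trapezoidal integral of velocity.
#'
#' @param config a [sim_config()].
#' @return an `eye_trace_set`: list with integer-ms `time` axis (-100..500),
#'   trials x time matrices `vel_h`, `vel_v`, `pos_h`, `pos_v`, and a `meta`
#'   data frame (trial_id, target_dir, cue_dir, exec_dir, contrast, block,
#'   day, latency_true, saccade).
#' @export
simulate_eye_traces <- function(config) {
  validate_sim_config(config)
  time <- eye_time_axis()
  nt <- length(time)
  design <- expand.grid(rep = seq_len(config$n_trials_per_cell),
                        block = c("valid", "invalid"),
                        contrast = config$contrasts,
                        target_dir = config$directions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(design)
  with_seed(config$seed, {
    cue <- ifelse(design$block == "valid", design$target_dir,
                  sample(config$directions, n, replace = TRUE))
    r_t <- vapply(design$contrast, function(ct)
      lookup_by_contrast(config$target_reliability_by_contrast, ct), 0)
    exec_dir <- vapply(seq_len(n), function(k)
      circ_weighted_mean(c(design$target_dir[k], cue[k]),
                         c(r_t[k], config$cue_reliability)), 0)
    lat_mu <- vapply(design$contrast, function(ct)
      lookup_by_contrast(config$latency_mean_by_contrast, ct), 0)
    latency <- rnorm(n, lat_mu, config$latency_jitter_sd)
    latency <- pmax(latency, 20)
    has_sacc <- runif(n) < config$saccade_rate

    vel_h <- matrix(0, n, nt)
    vel_v <- matrix(0, n, nt)
    for (k in seq_len(n)) {
      speed <- ifelse(time >= latency[k],
                      config$steady_state_gain * config$target_speed *
                        (1 - exp(-config$pursuit_gain * (time - latency[k]))),
                      0)
      th <- exec_dir[k] * pi / 180
      vh <- speed * cos(th)
      vv <- speed * sin(th)
      if (has_sacc[k]) {
        t0 <- runif(1, -90, 226)          # bump fits inside -100..250 ms
        dur <- 24
        idx <- which(time >= t0 & time < t0 + dur)
        bump <- 50 * sin(pi * (time[idx] - t0) / dur)
        dir_s <- runif(1, 0, 2 * pi)
        vh[idx] <- vh[idx] + bump * cos(dir_s)
        vv[idx] <- vv[idx] + bump * sin(dir_s)
      }
      if (config$vel_noise_sd > 0) {
        vh <- vh + rnorm(nt, 0, config$vel_noise_sd)
        vv <- vv + rnorm(nt, 0, config$vel_noise_sd)
      }
      vel_h[k, ] <- vh
      vel_v[k, ] <- vv
    }
    pos_h <- t(apply(vel_h, 1, cumtrapz1, dt = 1e-3))
    pos_v <- t(apply(vel_v, 1, cumtrapz1, dt = 1e-3))
    meta <- data.frame(
      trial_id = sprintf("t%04d", seq_len(n)),
      target_dir = design$target_dir,
      cue_dir = cue,
      exec_dir = exec_dir,
      contrast = design$contrast,
      block = design$block,
      day = sprintf("day%d", 1 + (seq_len(n) - 1L) %% config$n_days),
      latency_true = latency,
      saccade = has_sacc,
      stringsAsFactors = FALSE)
    structure(list(time = time, vel_h = vel_h, vel_v = vel_v,
                   pos_h = pos_h, pos_v = pos_v, meta = meta),
              class = "eye_trace_set")
  })
}

#' @export
print.eye_trace_set <- function(x, ...) {
  cat(sprintf("eye_trace_set: %d trials, %d samples (%d..%d ms)\n",
              nrow(x$meta), length(x$time), min(x$time), max(x$time)))
  cat(sprintf("  directions: %s; contrasts: %s; blocks: %s\n",
              paste(sort(unique(x$meta$target_dir)), collapse = ", "),
              paste(sort(unique(x$meta$contrast)), collapse = ", "),
              paste(sort(unique(x$meta$block)), collapse = ", ")))
  invisible(x)
}

#' Subset trials of an eye trace set, epoch set, or feature set
#'
#' @param traces an `eye_trace_set`.
#' @param idx logical or integer trial index.
#' @return the container restricted to the selected trials.
#' @export
subset_traces <- function(traces, idx) {
  structure(list(time = traces$time,
                 vel_h = traces$vel_h[idx, , drop = FALSE],
                 vel_v = traces$vel_v[idx, , drop = FALSE],
                 pos_h = traces$pos_h[idx, , drop = FALSE],
                 pos_v = traces$pos_v[idx, , drop = FALSE],
                 meta = traces$meta[idx, , drop = FALSE]),
            class = "eye_trace_set")
}

#' Generate multichannel epochs from eye traces by a forward mixture model
#'
#' Each channel is a weighted, time-shifted linear mixture of the trial's
#' sensory drive (magnitude of the integrated retinal velocity error, IRVE)
#' and motor drive (eye speed), with direction-specific spatial patterns,
#' plus spatially correlated Gaussian noise:
#' \deqn{x_c(t) = w_s P_s(c, d) \, |IRVE|(t + t_s) +
#'               w_m P_m(c, d) \, s(t + t_m) + \epsilon_c(t)}
#' Patterns and the noise mixing matrix are drawn once from
#' `spatial_pattern_seed`, so different trial-level seeds share identical
#' spatial structure.
#'
#' @param traces an `eye_trace_set` on the -100..500 ms axis.
#' @param config the [sim_config()] supplying mixture parameters.
#' @return an `epoch_set`: list with `data` (trials x channels x time),
#'   `channel_names`, `time`, `meta` (the trace meta table).
#' @export
generate_epochs <- function(traces, config) {
  validate_sim_config(config)
  stopifnot_msg(identical(as.integer(traces$time), eye_time_axis()),
                "traces must be on the -100..500 ms, 1 ms axis")
  time <- traces$time
  nt <- length(time)
  n <- nrow(traces$meta)
  nc <- config$n_channels
  ndir <- length(config$directions)

  pat <- with_seed(config$spatial_pattern_seed, {
    list(P_s = matrix(rnorm(nc * ndir), nc, ndir),
         P_m = matrix(rnorm(nc * ndir), nc, ndir),
         A = matrix(rnorm(nc * config$noise_spatial_rank), nc,
                    config$noise_spatial_rank))
  })

  rve <- retinal_velocity_error(traces, target_speed = config$target_speed)
  irve <- integrate_rve(rve)
  irve_mag <- sqrt(irve$h^2 + irve$v^2)
  speed <- sqrt(traces$vel_h^2 + traces$vel_v^2)

  w_s <- unname(config$mix_weights[1]); w_m <- unname(config$mix_weights[2])
  t_s <- unname(config$mix_shifts[1]);  t_m <- unname(config$mix_shifts[2])

  dir_idx <- match(traces$meta$target_dir, config$directions)
  stopifnot_msg(!anyNA(dir_idx), "trial target_dir not in config directions")

  data <- array(0, dim = c(n, nc, nt))
  with_seed(config$seed + 1L, {
    rk <- config$noise_spatial_rank
    scale_mix <- 1 / sqrt(2)
    for (k in seq_len(n)) {
      s_k <- shift_series(irve_mag[k, ], t_s)
      m_k <- shift_series(speed[k, ], t_m)
      sig <- w_s * outer(pat$P_s[, dir_idx[k]], s_k) +
             w_m * outer(pat$P_m[, dir_idx[k]], m_k)
      if (config$noise_sd > 0) {
        z <- matrix(rnorm(rk * nt), rk, nt)
        w <- matrix(rnorm(nc * nt), nc, nt)
        sig <- sig + config$noise_sd * scale_mix *
          (pat$A %*% z / sqrt(rk) + w)
      }
      data[k, , ] <- sig
    }
  })
  new_epoch_set(data, config$channel_names, time, traces$meta)
}

new_epoch_set <- function(data, channel_names, time, meta) {
  stopifnot_msg(length(dim(data)) == 3, "data must be trials x channels x time")
  stopifnot_msg(dim(data)[1] == nrow(meta), "trial count must match meta rows")
  stopifnot_msg(dim(data)[2] == length(channel_names) &&
                  !anyDuplicated(channel_names),
                "channel_names must be unique and match data")
  stopifnot_msg(dim(data)[3] == length(time), "time axis must match data")
  dimnames(data) <- list(NULL, channel_names, NULL)
  structure(list(data = data, channel_names = channel_names,
                 time = as.integer(time), meta = meta),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d trials x %d channels x %d samples (%d..%d ms)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$time), max(x$time)))
  invisible(x)
}

#' @rdname subset_traces
#' @param epochs an `epoch_set`.
#' @export
subset_epochs <- function(epochs, idx) {
  new_epoch_set(epochs$data[idx, , , drop = FALSE], epochs$channel_names,
                epochs$time, epochs$meta[idx, , drop = FALSE])
}
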