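new_feature_set <- function(kind, time, h, v, meta) {
  structure(list(kind = kind, time = as.integer(time), h = h, v = v,
                 meta = meta), class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("feature_set[%s]: %d trials x %d samples (%d..%d ms)\n",
              x$kind, nrow(x$h), length(x$time), min(x$time), max(x$time)))
  invisible(x)
}

#' Retinal velocity error
#'
#' The retinal velocity error (RVE) is the target velocity vector minus the
#' eye velocity vector — the residual motion of the target image on the
#' retina. Before `motion_onset` the target is static, so RVE is minus the
#' eye velocity; from onset the target moves at `target_speed` along each
#' trial's target direction.
#'
#' @param traces an `eye_trace_set`.
#' @param target_speed target speed, deg/s.
#' @param motion_onset time of target motion onset, ms (default 0).
#' @return a `feature_set` of kind `"retinal_velocity_error"` (deg/s).
#' @examples
#' tr <- simulate_eye_traces(sim_config(n_trials_per_cell = 2))
#' rve <- retinal_velocity_error(tr)
#' @export
retinal_velocity_error <- function(traces, target_speed = 16,
                                   motion_onset = 0) {
  time <- traces$time
  time_index(time, motion_onset, "motion_onset")
  moving <- as.numeric(time >= motion_onset)
  th <- traces$meta$target_dir * pi / 180
  tgt_h <- outer(target_speed * cos(th), moving)
  tgt_v <- outer(target_speed * sin(th), moving)
  new_feature_set("retinal_velocity_error", time,
                  tgt_h - traces$vel_h, tgt_v - traces$vel_v, traces$meta)
}

#' Integrated retinal velocity error (IRVE)
#'
#' Cumulative trapezoidal time integral of the RVE from `start` onward,
#' giving a position-dimensioned accumulation (deg) of uncorrected motion
#' error; IRVE is defined as 0 at and before `start`.
#'
#' @param rve a `feature_set` of kind `"retinal_velocity_error"`.
#' @param start integration start, ms (default 0, stimulus onset).
#' @return a `feature_set` of kind `"irve"` (deg).
#' @examples
#' tr <- simulate_eye_traces(sim_config(n_trials_per_cell = 2))
#' irve <- integrate_rve(retinal_velocity_error(tr))
#' @export
integrate_rve <- function(rve, start = 0) {
  stopifnot_msg(inherits(rve, "feature_set") &&
                  rve$kind == "retinal_velocity_error",
                "rve must be a retinal_velocity_error feature_set")
  i0 <- time_index(rve$time, start, "start")
  integ <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    seg <- seq(i0, ncol(m))
    out[, seg] <- t(apply(m[, seg, drop = FALSE], 1, cumtrapz1, dt = 1e-3))
    out
  }
  new_feature_set("irve", rve$time, integ(rve$h), integ(rve$v), rve$meta)
}

#' Motor feature traces
#'
#' Extracts the two motor features of pursuit — eye velocity (deg/s) and eye
#' position (deg) — as horizontal/vertical feature sets on the trace axis.
#'
#' @param traces an `eye_trace_set`.
#' @return list with elements `velocity` and `position`, each a `feature_set`.
#' @export
motor_features <- function(traces) {
  list(velocity = new_feature_set("eye_velocity", traces$time,
                                  traces$vel_h, traces$vel_v, traces$meta),
       position = new_feature_set("eye_position", traces$time,
                                  traces$pos_h, traces$pos_v, traces$meta))
}

# trials x time matrix of feature magnitude sqrt(h^2 + v^2)
feature_magnitude <- function(fs) sqrt(fs$h^2 + fs$v^2)

#' @rdname subset_traces
#' @param fs a `feature_set`.
#' @export
subset_features <- function(fs, idx) {
  new_feature_set(fs$kind, fs$time, fs$h[idx, , drop = FALSE],
                  fs$v[idx, , drop = FALSE], fs$meta[idx, , drop = FALSE])
}
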