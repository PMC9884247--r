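#' Screen trials for saccadic eye movements
#'
#' A trial is rejected if eye speed exceeds `fixation_thresh` anywhere in the
#' fixation window, or `pursuit_thresh` anywhere in the pursuit window.
#' Defaults follow common pursuit practice: 5 deg/s during fixation
#' (-100..100 ms) and 20 deg/s during early pursuit (100..250 ms).
#'
#' @param traces an `eye_trace_set`.
#' @param fixation_window,pursuit_window length-2 ms windows (inclusive).
#' @param fixation_thresh,pursuit_thresh speed thresholds, deg/s.
#' @return a `screening_report`: list with `kept_trial_ids`, `rejected`
#'   (data frame of trial_id and reason, `fixation_speed` or
#'   `pursuit_speed`), and the thresholds/windows used.
#' @examples
#' tr <- simulate_eye_traces(sim_config(n_trials_per_cell = 5, saccade_rate = 0.5))
#' screen_saccades(tr)$rejected
#' @export
screen_saccades <- function(traces,
                            fixation_window = c(-100, 100),
                            pursuit_window = c(100, 250),
                            fixation_thresh = 5,
                            pursuit_thresh = 20) {
  time <- traces$time
  for (w in list(fixation_window, pursuit_window)) {
    time_index(time, w[1], "window start")
    time_index(time, w[2], "window end")
  }
  speed <- sqrt(traces$vel_h^2 + traces$vel_v^2)
  fix_idx <- time >= fixation_window[1] & time <= fixation_window[2]
  pur_idx <- time >= pursuit_window[1] & time <= pursuit_window[2]
  fix_bad <- apply(speed[, fix_idx, drop = FALSE] > fixation_thresh, 1, any)
  pur_bad <- apply(speed[, pur_idx, drop = FALSE] > pursuit_thresh, 1, any)
  reason <- ifelse(fix_bad, "fixation_speed",
                   ifelse(pur_bad, "pursuit_speed", NA_character_))
  ids <- traces$meta$trial_id
  structure(list(
    kept_trial_ids = ids[is.na(reason)],
    rejected = data.frame(trial_id = ids[!is.na(reason)],
                          reason = reason[!is.na(reason)],
                          stringsAsFactors = FALSE),
    fixation_window = fixation_window, pursuit_window = pursuit_window,
    fixation_thresh = fixation_thresh, pursuit_thresh = pursuit_thresh),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf("screening_report: %d kept, %d rejected (%s)\n",
              length(x$kept_trial_ids), nrow(x$rejected),
              if (nrow(x$rejected)) paste(names(table(x$rejected$reason)),
                                          table(x$rejected$reason),
                                          sep = ":", collapse = ", ")
              else "none"))
  invisible(x)
}

#' Keep only screened trials
#'
#' @param traces an `eye_trace_set`.
#' @param report a `screening_report` from [screen_saccades()].
#' @return the `eye_trace_set` restricted to kept trials.
#' @export
apply_screening <- function(traces, report) {
  subset_traces(traces, traces$meta$trial_id %in% report$kept_trial_ids)
}

#' Estimate pursuit latency of a single trial
#'
#' Latency is the first time in `search_window` at which eye speed exceeds
#' the baseline mean + 3 SD and stays above it for at least `sustain_ms`
#' consecutive milliseconds. A zero-variance baseline falls back to an
#' absolute 2 deg/s threshold (with a message). Returns `NA` if speed never
#' crosses.
#'
#' @param speed numeric eye-speed vector (deg/s) on `time`.
#' @param time integer ms axis.
#' @param baseline_window,search_window length-2 ms windows.
#' @param sustain_ms required supra-threshold run length, ms.
#' @return latency in ms, or `NA_real_`.
#' @export
estimate_latency <- function(speed, time,
                             baseline_window = c(-100, 0),
                             search_window = c(50, 300),
                             sustain_ms = 20) {
  stopifnot_msg(baseline_window[2] <= search_window[1],
                "baseline window must precede search window")
  b <- time >= baseline_window[1] & time <= baseline_window[2]
  stopifnot_msg(any(b), "baseline window outside time axis")
  mu <- mean(speed[b]); s <- sd(speed[b])
  thr <- if (is.na(s) || s == 0) {
    message("degenerate baseline (zero variance): using 2 deg/s threshold")
    2
  } else mu + 3 * s
  # search may run past search_window to verify the sustain criterion
  cand <- which(time >= search_window[1] & time <= search_window[2] &
                  speed > thr)
  above <- speed > thr
  for (i in cand) {
    j <- i + seq_len(sustain_ms) - 1L
    if (max(j) <= length(speed) && all(above[j])) return(time[i])
  }
  NA_real_
}

#' Per-trial pursuit latencies for a whole trace set
#'
#' @param traces an `eye_trace_set`.
#' @param ... passed to [estimate_latency()].
#' @return numeric vector of latencies (ms), `NA` where speed never crosses.
#' @export
estimate_latencies <- function(traces, ...) {
  speed <- sqrt(traces$vel_h^2 + traces$vel_v^2)
  vapply(seq_len(nrow(speed)), function(k)
    estimate_latency(speed[k, ], traces$time, ...), 0)
}

#' Rotated-trace distance between direction groups
#'
#' Rotates every trial's velocity vector by `rotation` degrees (so the
#' midline between `upper_dir` and `lower_dir` maps onto the horizontal
#' axis), averages the rotated vertical component within each direction
#' group, and takes the absolute vertical separation of the two group means:
#' \eqn{\Delta y(t)}. When both `valid` and `invalid` blocks are present the
#' valid-minus-invalid difference \eqn{\Delta y_2 - \Delta y_1} and its value
#' 100 ms after pursuit latency are also returned.
#'
#' @param traces an `eye_trace_set` (typically one contrast cell, screened).
#' @param rotation rotation angle, deg.
#' @param upper_dir,lower_dir target directions defining the two groups, deg.
#' @param align `"latency"` re-expresses time relative to the per-block mean
#'   estimated pursuit latency; `"stimulus"` keeps stimulus-onset time.
#' @param distance `"vertical"` (default) uses the rotated vertical
#'   separation of the group means; `"euclidean"` uses the full 2-D distance
#'   between the rotated mean velocity vectors.
#' @param out_window ms output window on the aligned axis.
#' @return a `trace_distance` object: `time` (aligned axis), `delta_y`
#'   (matrix, one column per block), `delta_delta_y` and `value_at_100ms`
#'   (valid minus invalid; `NULL` if a single block was supplied), and the
#'   per-block mean latencies used for alignment.
#' @export
rotate_and_distance <- function(traces, rotation = -30,
                                upper_dir = 0, lower_dir = -60,
                                align = c("latency", "stimulus"),
                                distance = c("vertical", "euclidean"),
                                out_window = c(-100, 100)) {
  align <- match.arg(align)
  distance <- match.arg(distance)
  blocks <- intersect(c("valid", "invalid"), unique(traces$meta$block))
  stopifnot_msg(length(blocks) >= 1, "no trials given")
  t_rel <- seq(out_window[1], out_window[2])
  delta <- matrix(NA_real_, length(t_rel), length(blocks),
                  dimnames = list(NULL, blocks))
  latencies <- setNames(numeric(length(blocks)), blocks)

  rot <- rotate_hv(traces$vel_h, traces$vel_v, rotation)
  for (b in blocks) {
    in_b <- traces$meta$block == b
    up <- in_b & abs(traces$meta$target_dir - upper_dir) < 1e-9
    lo <- in_b & abs(traces$meta$target_dir - lower_dir) < 1e-9
    if (!any(up)) stop(sprintf("empty group: direction %g, block %s",
                               upper_dir, b), call. = FALSE)
    if (!any(lo)) stop(sprintf("empty group: direction %g, block %s",
                               lower_dir, b), call. = FALSE)
    mu_up <- colMeans(rot$v[up, , drop = FALSE])
    mu_lo <- colMeans(rot$v[lo, , drop = FALSE])
    if (distance == "euclidean") {
      mu_up_h <- colMeans(rot$h[up, , drop = FALSE])
      mu_lo_h <- colMeans(rot$h[lo, , drop = FALSE])
    }
    if (align == "latency") {
      lat <- estimate_latencies(subset_traces(traces, up | lo))
      L <- round(mean(lat, na.rm = TRUE))
      if (is.na(L)) stop("no measurable latency in block ", b, call. = FALSE)
    } else L <- 0
    latencies[b] <- L
    idx <- match(t_rel + L, traces$time)
    stopifnot_msg(!anyNA(idx), "aligned window falls outside the time axis")
    delta[, b] <- if (distance == "euclidean")
      sqrt((mu_up[idx] - mu_lo[idx])^2 + (mu_up_h[idx] - mu_lo_h[idx])^2)
    else abs(mu_up[idx] - mu_lo[idx])
  }
  ddy <- NULL; v100 <- NULL
  if (all(c("valid", "invalid") %in% blocks)) {
    ddy <- delta[, "valid"] - delta[, "invalid"]
    v100 <- ddy[match(100, t_rel)]
  }
  structure(list(time = t_rel, delta_y = delta, delta_delta_y = ddy,
                 value_at_100ms = v100, align = align,
                 mean_latency = latencies, rotation = rotation),
            class = "trace_distance")
}

#' @export
print.trace_distance <- function(x, ...) {
  cat(sprintf("trace_distance: rotation %g deg, align %s, blocks: %s\n",
              x$rotation, x$align, paste(colnames(x$delta_y), collapse = ", ")))
  if (!is.null(x$value_at_100ms))
    cat(sprintf("  delta_y(valid) - delta_y(invalid) at +100 ms: %.3f deg/s\n",
                x$value_at_100ms))
  invisible(x)
}
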