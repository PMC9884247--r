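#' Read and write pipeline artifacts
#'
#' Eye traces and all one-dimensional results are stored as tidy CSV; epoch
#' sets as a wide CSV (one row per trial x channel) with a JSON sidecar for
#' the channel names, time axis and trial metadata; fits and cluster results
#' as JSON. All formats round-trip losslessly up to numeric printing
#' precision (15 significant digits).
#'
#' @param traces an `eye_trace_set`.
#' @param dir output directory (created if needed).
#' @return `write_*` return the written paths invisibly; `read_*` return the
#'   reconstructed object.
#' @name pursuit_io
NULL

fmt_num <- function(x) formatC(x, digits = 15, format = "g")

#' @rdname pursuit_io
#' @export
write_eye_traces <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- data.frame(
    trial_id = rep(traces$meta$trial_id, each = length(traces$time)),
    time = rep(traces$time, nrow(traces$meta)),
    vel_h = as.vector(t(traces$vel_h)), vel_v = as.vector(t(traces$vel_v)),
    pos_h = as.vector(t(traces$pos_h)), pos_v = as.vector(t(traces$pos_v)))
  utils::write.csv(long, file.path(dir, "traces.csv"), row.names = FALSE)
  utils::write.csv(traces$meta, file.path(dir, "trials.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, c("traces.csv", "trials.csv")))
}

#' @rdname pursuit_io
#' @export
read_eye_traces <- function(dir) {
  long <- utils::read.csv(file.path(dir, "traces.csv"),
                          stringsAsFactors = FALSE)
  meta <- utils::read.csv(file.path(dir, "trials.csv"),
                          stringsAsFactors = FALSE)
  time <- sort(unique(long$time))
  nt <- length(time)
  ord <- order(match(long$trial_id, meta$trial_id), long$time)
  long <- long[ord, ]
  as_m <- function(col) matrix(long[[col]], nrow(meta), nt, byrow = TRUE)
  structure(list(time = as.integer(time),
                 vel_h = as_m("vel_h"), vel_v = as_m("vel_v"),
                 pos_h = as_m("pos_h"), pos_v = as_m("pos_v"), meta = meta),
            class = "eye_trace_set")
}

#' @rdname pursuit_io
#' @param epochs an `epoch_set`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(epochs$data)[1]; nc <- dim(epochs$data)[2]
  flat <- matrix(aperm(epochs$data, c(3, 2, 1)),
                 nrow = n * nc, byrow = TRUE)   # rows: trial-major, channel
  df <- data.frame(trial_id = rep(epochs$meta$trial_id, each = nc),
                   channel = rep(epochs$channel_names, n))
  df <- cbind(df, as.data.frame(flat))
  names(df)[-(1:2)] <- paste0("t", epochs$time)
  utils::write.csv(df, file.path(dir, "epochs.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(channel_names = epochs$channel_names, time = epochs$time,
         meta = epochs$meta),
    file.path(dir, "epochs_meta.json"), digits = NA, auto_unbox = FALSE)
  invisible(file.path(dir, c("epochs.csv", "epochs_meta.json")))
}

#' @rdname pursuit_io
#' @export
read_epochs <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "epochs_meta.json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(file.path(dir, "epochs.csv"),
                        stringsAsFactors = FALSE, check.names = FALSE)
  meta <- as.data.frame(side$meta, stringsAsFactors = FALSE)
  time <- as.integer(side$time)
  nc <- length(side$channel_names)
  n <- nrow(meta)
  vals <- as.matrix(df[, -(1:2)])
  data <- array(0, dim = c(n, nc, length(time)))
  for (k in seq_len(n)) {
    rows <- which(df$trial_id == meta$trial_id[k])
    data[k, match(df$channel[rows], side$channel_names), ] <- vals[rows, ]
  }
  new_epoch_set(data, side$channel_names, time, meta)
}

#' @rdname pursuit_io
#' @param x a `dissim_trace` (for `write_dissim`) or path.
#' @param path file path.
#' @export
write_dissim <- function(x, path) {
  utils::write.csv(data.frame(time = x$time, value = x$value,
                              n_used = x$n_trials_used[1]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname pursuit_io
#' @export
read_dissim <- function(path) {
  df <- utils::read.csv(path)
  new_dissim_trace(list(time = as.integer(df$time), value = df$value,
                        n_trials_used = rep(df$n_used[1], 2),
                        subsample_iterations = NA_integer_, seed = NA_integer_),
                   pair = c("condition_1", "condition_2"))
}

#' @rdname pursuit_io
#' @param fit a `dissim_lm`.
#' @export
write_fit_json <- function(fit, path) {
  jsonlite::write_json(
    list(variant = fit$variant, weights = as.list(fit$weights),
         intercept = fit$intercept, t_s = fit$t_s, t_m = fit$t_m,
         r_squared = fit$r_squared, rss = fit$rss,
         window = fit$window, conditions = fit$conditions,
         search = fit$search[!vapply(fit$search, is.null, TRUE)]),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname pursuit_io
#' @param result a `cluster_result`.
#' @export
write_cluster_json <- function(result, path) {
  jsonlite::write_json(
    list(clusters = result$clusters, threshold_p = result$threshold_p,
         n_permutations = result$n_permutations, seed = result$seed,
         tail = result$tail, n_participants = result$n_participants),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
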