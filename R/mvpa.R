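#' Preprocess multichannel epochs
#'
#' Applies, in order: (1) rectangular moving-average smoothing of each
#' channel and trial with a +/- `smooth_halfwidth` ms window (the output time
#' axis is trimmed so every evaluated point has a full window); (2) per-day
#' normalization by the day's maximum absolute value across channels, times
#' and trials, so multiple recording days are on a common scale; (3)
#' per-channel z-scoring over times and trials. Constant (zero-SD) channels
#' are set to zero with a message.
#'
#' @param epochs an `epoch_set`.
#' @param smooth_halfwidth half width of the rectangular window, ms
#'   (default 10, i.e. a 20-ms window).
#' @param analysis_window optional length-2 ms window to crop to after
#'   smoothing.
#' @param day_max_normalize,channel_zscore logical switches for steps 2-3.
#' @return a preprocessed `epoch_set`.
#' @export
preprocess_epochs <- function(epochs, smooth_halfwidth = 10,
                              analysis_window = NULL,
                              day_max_normalize = TRUE,
                              channel_zscore = TRUE) {
  h <- as.integer(smooth_halfwidth)
  d <- epochs$data
  n <- dim(d)[1]; nc <- dim(d)[2]; nt <- dim(d)[3]
  time <- epochs$time
  if (h > 0) {
    stopifnot_msg(nt > 2 * h, "smoothing window wider than the data")
    kern <- rep(1 / (2 * h + 1), 2 * h + 1)
    keep <- (h + 1):(nt - h)
    out <- array(0, dim = c(n, nc, length(keep)))
    for (k in seq_len(n)) {
      sm <- stats::filter(t(d[k, , , drop = TRUE]), kern, sides = 2)
      out[k, , ] <- t(sm[keep, , drop = FALSE])
    }
    d <- out
    time <- time[keep]
  }
  if (!is.null(analysis_window)) {
    keep <- which(time >= analysis_window[1] & time <= analysis_window[2])
    stopifnot_msg(length(keep) > 0, "analysis_window outside smoothed axis")
    d <- d[, , keep, drop = FALSE]
    time <- time[keep]
  }
  if (day_max_normalize) {
    stopifnot_msg(!is.null(epochs$meta$day), "day labels required")
    for (dy in unique(epochs$meta$day)) {
      idx <- epochs$meta$day == dy
      mx <- max(abs(d[idx, , , drop = FALSE]))
      if (mx == 0) stop("day ", dy, " has all-zero data; maximum undefined",
                        call. = FALSE)
      d[idx, , ] <- d[idx, , , drop = FALSE] / mx
    }
  }
  if (channel_zscore) {
    nz <- 0L
    for (c_i in seq_len(nc)) {
      x <- d[, c_i, , drop = TRUE]
      s <- sd(as.vector(x))
      if (is.na(s) || s == 0) { d[, c_i, ] <- 0; nz <- nz + 1L }
      else d[, c_i, ] <- (x - mean(x)) / s
    }
    if (nz > 0) message(nz, " zero-SD channel(s) set to 0")
  }
  new_epoch_set(d, epochs$channel_names, time, epochs$meta)
}

#' Pooled precision matrix of two condition samples
#'
#' Per-condition covariances of the channel patterns at one time point are
#' computed about each condition's own mean, pooled with trial-count
#' (degrees-of-freedom) weights, regularized by shrinkage toward a scaled
#' identity, and pseudo-inverted. Shrinkage `"auto"` uses a Ledoit-Wolf
#' style analytic coefficient; a numeric value in `[0, 1]` fixes the
#' coefficient (`1` gives a scaled identity); `"none"` disables shrinkage
#' (a rank-deficient pooled covariance is still pseudo-inverted, with a
#' warning).
#'
#' @param x_a,x_b trials x channels matrices (patterns at one time point).
#' @param shrinkage `"auto"`, `"none"`, or a number in `[0, 1]`.
#' @return channels x channels precision (pseudo-inverse) matrix.
#' @export
pooled_precision <- function(x_a, x_b, shrinkage = "auto") {
  x_a <- as.matrix(x_a); x_b <- as.matrix(x_b)
  stopifnot_msg(ncol(x_a) == ncol(x_b), "channel counts differ")
  n1 <- nrow(x_a); n2 <- nrow(x_b)
  stopifnot_msg(n1 >= 2 && n2 >= 2, "need >= 2 trials per condition")
  d_a <- sweep(x_a, 2, colMeans(x_a))
  d_b <- sweep(x_b, 2, colMeans(x_b))
  cpool <- (crossprod(d_a) + crossprod(d_b)) / (n1 + n2 - 2)
  regularized_inverse(cpool, d_a, d_b, shrinkage)
}

# Shrink a pooled covariance toward a scaled identity and pseudo-invert it.
# d_a/d_b are the demeaned samples used for the data-driven coefficient.
regularized_inverse <- function(cpool, d_a, d_b, shrinkage) {
  p <- ncol(cpool)
  nu <- mean(diag(cpool))
  lam <- if (identical(shrinkage, "none")) 0
    else if (identical(shrinkage, "auto")) {
      x <- rbind(d_a, d_b); n <- nrow(x)
      s <- crossprod(x) / n
      # Ledoit-Wolf (2004) shrinkage toward mean-variance * identity
      mu <- mean(diag(s))
      d2 <- sum((s - diag(mu, p))^2)
      b2 <- sum(vapply(seq_len(n), function(i)
        sum((tcrossprod(x[i, ]) - s)^2), 0)) / n^2
      if (d2 <= 0) 0 else min(1, max(0, b2 / d2))
    } else {
      stopifnot_msg(is.numeric(shrinkage) && shrinkage >= 0 && shrinkage <= 1,
                    "numeric shrinkage must be in [0, 1]")
      shrinkage
    }
  creg <- (1 - lam) * cpool + lam * diag(nu, p)
  if (identical(shrinkage, "none") && qr(creg)$rank < p)
    warning("pooled covariance is rank deficient; using pseudo-inverse")
  MASS::ginv(creg)
}

# Mahalanobis quadratic form rows: sqrt(diag(D %*% P %*% t(D))) for row
# deviations D.
maha_rows <- function(dev, prec) sqrt(pmax(rowSums((dev %*% prec) * dev), 0))

# One-perspective cross-validated distance difference at a single time point.
# x1 trials are held out one at a time; x2 supplies the other-condition mean.
d12_minus_d11 <- function(x1, x2, prec, cross_validate = TRUE) {
  n1 <- nrow(x1)
  m2 <- colMeans(x2)
  if (cross_validate) {
    cs <- colSums(x1)
    m1_loo <- (matrix(cs, n1, ncol(x1), byrow = TRUE) - x1) / (n1 - 1)
    d11 <- mean(maha_rows(m1_loo - x1, prec))
  } else {
    m1 <- colMeans(x1)
    d11 <- mean(maha_rows(sweep(x1, 2, m1), prec))
  }
  d12 <- mean(maha_rows(sweep(x1, 2, m2, FUN = function(a, b) b - a), prec))
  d12 - d11
}

# Core machinery shared by epoch and feature dissimilarity. arr_* are
# trials x channels x time arrays on a common axis.
crossval_core <- function(arr_a, arr_b, time, n_subsample_iters, seed,
                          shrinkage, symmetrize, cross_validate,
                          time_points = NULL, time_pooled_cov = FALSE) {
  na <- dim(arr_a)[1]; nb <- dim(arr_b)[1]
  stopifnot_msg(dim(arr_a)[2] == dim(arr_b)[2], "channel counts differ")
  stopifnot_msg(dim(arr_a)[3] == length(time) && dim(arr_b)[3] == length(time),
                "time axes differ")
  stopifnot_msg(na >= 3 && nb >= 3,
                "need >= 3 trials per condition for leave-one-out")
  tp <- if (is.null(time_points)) seq_along(time)
        else match(as.integer(round(time_points)), time)
  stopifnot_msg(!anyNA(tp), "requested time points not on the axis")
  n <- min(na, nb)
  iters <- if (na == nb) 1L else as.integer(n_subsample_iters)
  acc <- matrix(0, length(tp), iters)
  with_seed(seed, {
    for (it in seq_len(iters)) {
      ia <- if (na > n) sample(na, n) else seq_len(na)
      ib <- if (nb > n) sample(nb, n) else seq_len(nb)
      prec_pooled <- NULL
      if (time_pooled_cov) {
        # covariance averaged over all evaluated time points, one precision
        nc <- dim(arr_a)[2]
        acc_c <- matrix(0, nc, nc)
        da_all <- NULL; db_all <- NULL
        for (t_i in tp) {
          xa <- arr_a[ia, , t_i, drop = FALSE]; dim(xa) <- dim(xa)[1:2]
          xb <- arr_b[ib, , t_i, drop = FALSE]; dim(xb) <- dim(xb)[1:2]
          d_a <- sweep(xa, 2, colMeans(xa)); d_b <- sweep(xb, 2, colMeans(xb))
          acc_c <- acc_c + (crossprod(d_a) + crossprod(d_b)) / (2 * n - 2)
          da_all <- rbind(da_all, d_a); db_all <- rbind(db_all, d_b)
        }
        prec_pooled <- regularized_inverse(acc_c / length(tp),
                                           da_all, db_all, shrinkage)
      }
      for (j in seq_along(tp)) {
        t_i <- tp[j]
        xa <- arr_a[ia, , t_i, drop = FALSE]; dim(xa) <- dim(xa)[1:2]
        xb <- arr_b[ib, , t_i, drop = FALSE]; dim(xb) <- dim(xb)[1:2]
        prec <- if (time_pooled_cov) prec_pooled
                else pooled_precision(xa, xb, shrinkage)
        v <- d12_minus_d11(xa, xb, prec, cross_validate)
        if (symmetrize)
          v <- (v + d12_minus_d11(xb, xa, prec, cross_validate)) / 2
        acc[j, it] <- v
      }
    }
  })
  list(time = time[tp], value = rowMeans(acc),
       n_trials_used = c(n, n), subsample_iterations = iters, seed = seed)
}

#' Cross-validated Mahalanobis dissimilarity time course
#'
#' For each time point the channel patterns of two conditions are compared
#' by leave-one-trial-out cross-validated Mahalanobis distances:
#' \deqn{D_{11} = \frac1n \sum_i \sqrt{(TD_1 - td_1^i)^\top pC^{+} (TD_1 - td_1^i)}}
#' \deqn{D_{12} = \frac1n \sum_i \sqrt{(TD_2 - td_1^i)^\top pC^{+} (TD_2 - td_1^i)}}
#' where \eqn{TD_1} is the mean of the remaining own-condition trials,
#' \eqn{TD_2} the mean of the other condition, and \eqn{pC^{+}} the
#' pseudo-inverse of the pooled covariance. The reported value is
#' \eqn{D_{12} - D_{11}}, which is approximately 0 under exchangeability and
#' positive when the patterns differ. By default the roles of the two
#' conditions are swapped and the two estimates averaged. Unequal trial
#' counts are handled by `n_subsample_iters` seeded random subsamples of the
#' larger condition (a no-op, independent of the seed, when counts match).
#'
#' @param epochs_a,epochs_b `epoch_set`s on identical channel/time axes
#'   (typically from [preprocess_epochs()]).
#' @param n_subsample_iters subsample repetitions when trial counts differ.
#' @param seed seed for the subsampling.
#' @param shrinkage covariance shrinkage policy, see [pooled_precision()].
#' @param symmetrize average over both condition-role assignments?
#' @param cross_validate set `FALSE` for the naive (positively biased,
#'   non-cross-validated) variant; for diagnostics only.
#' @param time_points optional subset of ms time points to evaluate.
#' @param time_pooled_cov estimate one covariance pooled over all evaluated
#'   time points instead of one per time point (per-time-point is the
#'   default, matching the definition of the distance at each time).
#' @return a `dissim_trace`: list with `time`, `value` (D12 - D11),
#'   `condition_pair`, `n_trials_used`, `subsample_iterations`, `seed`.
#' @export
crossval_dissimilarity <- function(epochs_a, epochs_b,
                                   n_subsample_iters = 10, seed = 1,
                                   shrinkage = "auto", symmetrize = TRUE,
                                   cross_validate = TRUE,
                                   time_points = NULL,
                                   time_pooled_cov = FALSE) {
  stopifnot_msg(identical(epochs_a$channel_names, epochs_b$channel_names),
                "channel sets differ")
  stopifnot_msg(identical(epochs_a$time, epochs_b$time), "time axes differ")
  res <- crossval_core(epochs_a$data, epochs_b$data, epochs_a$time,
                       n_subsample_iters, seed, shrinkage, symmetrize,
                       cross_validate, time_points, time_pooled_cov)
  new_dissim_trace(res, pair = c("condition_1", "condition_2"))
}

#' Dissimilarity time course of 2-D eye-movement features
#'
#' Applies the machinery of [crossval_dissimilarity()] to per-trial feature
#' traces, with the horizontal and vertical components playing the role of
#' channels.
#'
#' @param features_a,features_b `feature_set`s of the same kind on the same
#'   time axis.
#' @inheritParams crossval_dissimilarity
#' @return a `dissim_trace`.
#' @export
feature_dissimilarity <- function(features_a, features_b,
                                  n_subsample_iters = 10, seed = 1,
                                  shrinkage = "auto", symmetrize = TRUE,
                                  cross_validate = TRUE,
                                  time_points = NULL,
                                  time_pooled_cov = FALSE) {
  stopifnot_msg(features_a$kind == features_b$kind,
                "feature kinds differ")
  stopifnot_msg(identical(features_a$time, features_b$time),
                "time axes differ")
  to_arr <- function(f) {
    a <- array(0, dim = c(nrow(f$h), 2L, ncol(f$h)))
    a[, 1L, ] <- f$h; a[, 2L, ] <- f$v
    a
  }
  res <- crossval_core(to_arr(features_a), to_arr(features_b),
                       features_a$time, n_subsample_iters, seed, shrinkage,
                       symmetrize, cross_validate, time_points,
                       time_pooled_cov)
  new_dissim_trace(res, pair = c("features_1", "features_2"),
                   kind = features_a$kind)
}

new_dissim_trace <- function(res, pair, kind = NULL) {
  structure(c(res, list(condition_pair = pair, kind = kind)),
            class = "dissim_trace")
}

#' @export
print.dissim_trace <- function(x, ...) {
  cat(sprintf(
    "dissim_trace%s: %d time points (%d..%d ms), n = %d/%d, %d iteration(s)\n",
    if (is.null(x$kind)) "" else sprintf(" [%s]", x$kind),
    length(x$time), min(x$time), max(x$time),
    x$n_trials_used[1], x$n_trials_used[2], x$subsample_iterations))
  cat(sprintf("  mean D12 - D11 = %.4f, max = %.4f at %d ms\n",
              mean(x$value), max(x$value), x$time[which.max(x$value)]))
  invisible(x)
}

#' Subset an epoch set to a named channel group
#'
#' @param epochs an `epoch_set`.
#' @param group either a group name understood by [channel_group()]
#'   (`"default47"`, `"frontal_central"`, `"central_parietal"`, `"all"`) or a
#'   character vector of channel names.
#' @return an `epoch_set` with the channel subset, in group order.
#' @export
select_channels <- function(epochs, group) {
  names_wanted <- if (length(group) == 1L &&
                      group %in% c("default47", "frontal_central",
                                   "central_parietal", "all", "excluded17"))
    channel_group(group) else as.character(group)
  if (identical(group, "all")) names_wanted <- epochs$channel_names
  missing <- setdiff(names_wanted, epochs$channel_names)
  if (length(missing))
    stop("unknown channel name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(names_wanted, epochs$channel_names)
  new_epoch_set(epochs$data[, idx, , drop = FALSE], names_wanted,
                epochs$time, epochs$meta)
}
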