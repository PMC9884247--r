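#' Assemble the design for the time-shifted dissimilarity model
#'
#' Collects, for each experimental condition, the neural dissimilarity trace
#' (the response) and the sensory/motor feature dissimilarity traces (the
#' regressors). Each regressor kind is max-min normalized jointly across
#' conditions and time points, so fitted weights express relative
#' contributions; the neural traces are left on their own scale. All four
#' conditions are fit simultaneously with one shared parameter set.
#'
#' @param neural named list of `dissim_trace` objects, one per condition.
#'   Condition names of the form `valid_100`, `invalid_12`, ... enable
#'   [residual_differences()].
#' @param sensory named list of regressor kinds; the reduced model uses
#'   `irve`, the full model adds `retinal_velocity_error`. Each element is a
#'   list of `dissim_trace`s with the same condition names as `neural`.
#' @param motor named list of motor regressor kinds; the reduced model uses
#'   `eye_velocity`, the full model adds `eye_position`.
#' @param window length-2 ms fit window (default 30..330, the open-loop
#'   period plus a ~30 ms neural response latency).
#' @return a `dissim_design` object.
#' @export
build_design <- function(neural, sensory, motor, window = c(30, 330)) {
  conds <- names(neural)
  stopifnot_msg(!is.null(conds) && all(nzchar(conds)),
                "neural must be a named list of conditions")
  tw <- seq(as.integer(window[1]), as.integer(window[2]))
  ntime <- neural[[1]]$time
  for (tr in neural) stopifnot_msg(identical(tr$time, ntime),
                                   "neural traces must share one axis")
  stopifnot_msg(all(tw %in% ntime), "fit window not covered by neural traces")
  y <- unlist(lapply(neural, function(tr) tr$value[match(tw, tr$time)]),
              use.names = FALSE)

  norm_kind <- function(lst, kind) {
    stopifnot_msg(identical(sort(names(lst)), sort(conds)),
                  paste0("regressor '", kind,
                         "' must cover the same conditions as neural"))
    rt <- lst[[1]]$time
    for (tr in lst) stopifnot_msg(identical(tr$time, rt),
                                  "regressor traces must share one axis")
    m <- do.call(rbind, lapply(lst[conds], function(tr) tr$value))
    rng <- range(m)
    if (diff(rng) == 0) {
      message("regressor '", kind, "' has zero range; set to 0")
      m[] <- 0
    } else m <- (m - rng[1]) / (rng[2] - rng[1])
    list(time = rt, values = m)
  }
  regs <- c(
    lapply(seq_along(sensory), function(i)
      c(norm_kind(sensory[[i]], names(sensory)[i]), role = "sensory")),
    lapply(seq_along(motor), function(i)
      c(norm_kind(motor[[i]], names(motor)[i]), role = "motor")))
  names(regs) <- c(names(sensory), names(motor))
  structure(list(conditions = conds, window = window, window_time = tw,
                 y = y, y_matrix = matrix(y, nrow = length(conds),
                                          byrow = TRUE,
                                          dimnames = list(conds, NULL)),
                 regressors = regs),
            class = "dissim_design")
}

#' @export
print.dissim_design <- function(x, ...) {
  cat(sprintf("dissim_design: %d conditions x %d time points (%d..%d ms)\n",
              length(x$conditions), length(x$window_time),
              x$window[1], x$window[2]))
  cat("  regressors:",
      paste(sprintf("%s (%s)", names(x$regressors),
                    vapply(x$regressors, `[[`, "", "role")), collapse = ", "),
      "\n")
  invisible(x)
}

# Shifted, concatenated regressor columns: n_rows x n_shifts matrix for one
# regressor kind; rows are condition-major over the fit window.
shifted_columns <- function(reg, tw, shifts) {
  idx <- lapply(shifts, function(s) match(tw + s, reg$time))
  bad <- vapply(idx, anyNA, TRUE)
  if (any(bad))
    stop(sprintf(
      "regressor axis [%d, %d] does not cover the shifted window; need [%d, %d]",
      min(reg$time), max(reg$time),
      min(tw) + min(shifts), max(tw) + max(shifts)), call. = FALSE)
  vapply(idx, function(ii) as.vector(t(reg$values[, ii, drop = FALSE])),
         numeric(length(tw) * nrow(reg$values)))
}

#' Fit the time-shifted linear model of neural dissimilarity
#'
#' Models the neural dissimilarity trace as a weighted sum of time-shifted
#' sensory and motor dissimilarities,
#' \deqn{E(t) = w_s S_{IRVE}(t + t_s) + w_m M_{vel}(t + t_m)}
#' (reduced variant; the full variant adds retinal velocity error with the
#' same sensory shift and eye position with the same motor shift, six free
#' parameters in total). Because the weights enter linearly, they are solved
#' in closed form by least squares at every candidate shift pair, and the
#' shifts are found by exhaustive search on an integer-ms grid — a
#' deterministic search that attains the global optimum within the bounds.
#' A seeded multistart local search is available as an alternative. RSS ties
#' are broken toward the smallest `|t_s| + |t_m|`.
#'
#' @param design a `dissim_design` from [build_design()].
#' @param variant `"reduced"` (IRVE + eye velocity) or `"full"` (adds
#'   retinal velocity error and eye position).
#' @param shift_bounds length-2 ms bounds for both shifts (default +/-100).
#' @param shift_step grid step in ms.
#' @param search `"grid"` (exhaustive) or `"multistart"` (seeded local
#'   search from `n_starts` random starts).
#' @param n_starts,seed multistart controls.
#' @param intercept include an intercept term (the model has none by
#'   default).
#' @return an object of class `dissim_lm` with components `weights` (named),
#'   `t_s`, `t_m`, `r_squared`, `rss`, per-condition `fitted`, `residuals`
#'   and `observed` matrices, `window`, `variant` and a `search` record.
#' @examples
#' \donttest{
#' # see the package vignette for an end-to-end example
#' }
#' @export
fit_dissim_model <- function(design, variant = c("reduced", "full"),
                             shift_bounds = c(-100, 100), shift_step = 1,
                             search = c("grid", "multistart"),
                             n_starts = 50, seed = 1, intercept = FALSE) {
  variant <- match.arg(variant)
  search <- match.arg(search)
  stopifnot_msg(inherits(design, "dissim_design"), "design must be a dissim_design")
  roles <- vapply(design$regressors, `[[`, "", "role")
  s_kinds <- if (variant == "reduced") "irve"
             else c("irve", "retinal_velocity_error")
  m_kinds <- if (variant == "reduced") "eye_velocity"
             else c("eye_velocity", "eye_position")
  missing <- setdiff(c(s_kinds, m_kinds), names(design$regressors))
  if (length(missing))
    stop("design lacks regressor kind(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  stopifnot_msg(all(roles[s_kinds] == "sensory") && all(roles[m_kinds] == "motor"),
                "regressor roles do not match the variant")

  tw <- design$window_time
  shifts <- seq(as.integer(shift_bounds[1]), as.integer(shift_bounds[2]),
                by = as.integer(shift_step))
  ns <- length(shifts)
  y <- design$y
  smats <- lapply(design$regressors[s_kinds], shifted_columns, tw = tw,
                  shifts = shifts)
  mmats <- lapply(design$regressors[m_kinds], shifted_columns, tw = tw,
                  shifts = shifts)
  y0 <- y
  if (intercept) {
    center <- function(m) sweep(m, 2, colMeans(m))
    smats <- lapply(smats, center); mmats <- lapply(mmats, center)
    y <- y - mean(y0)
  }
  yy <- sum(y^2)
  p_s <- length(smats); p_m <- length(mmats); p <- p_s + p_m

  # Pre-computed normal-equation blocks indexed by shift:
  # within-block Grams, cross Gram for every shift pair, and X'y.
  sall <- do.call(cbind, smats)              # n x (p_s * ns)
  mall <- do.call(cbind, mmats)
  g_sm <- crossprod(sall, mall)              # (p_s*ns) x (p_m*ns)
  sy <- drop(crossprod(sall, y))
  my <- drop(crossprod(mall, y))
  gram_within <- function(mats) {
    k <- length(mats)
    out <- array(0, dim = c(k, k, ns))
    for (a in seq_len(k)) for (b in a:k) {
      v <- colSums(mats[[a]] * mats[[b]])
      out[a, b, ] <- v; out[b, a, ] <- v
    }
    out
  }
  g_ss <- gram_within(smats)
  g_mm <- gram_within(mmats)
  blk <- function(i, j) {                    # cross Gram at shift pair (i, j)
    g_sm[(seq_len(p_s) - 1L) * ns + i, (seq_len(p_m) - 1L) * ns + j,
         drop = FALSE]
  }
  rss_at <- function(i, j) {
    xtx <- matrix(0, p, p)
    xtx[seq_len(p_s), seq_len(p_s)] <- g_ss[, , i]
    xtx[p_s + seq_len(p_m), p_s + seq_len(p_m)] <- g_mm[, , j]
    xtx[seq_len(p_s), p_s + seq_len(p_m)] <- blk(i, j)
    xtx[p_s + seq_len(p_m), seq_len(p_s)] <- t(blk(i, j))
    xty <- c(sy[(seq_len(p_s) - 1L) * ns + i], my[(seq_len(p_m) - 1L) * ns + j])
    w <- tryCatch(solve(xtx, xty), error = function(e) {
      drop(MASS::ginv(xtx) %*% xty)          # collinear: least-norm solution
    })
    list(rss = yy - sum(w * xty), w = w)
  }

  evals <- 0L
  if (search == "grid") {
    if (p == 2L) {
      # fully vectorized 2-parameter grid
      ss <- g_ss[1, 1, ]; mm <- g_mm[1, 1, ]
      sm <- g_sm
      det <- outer(ss, mm) - sm^2
      ws <- (outer(sy, mm) - sm * matrix(my, ns, ns, byrow = TRUE)) / det
      wm <- (outer(ss, my) - sm * matrix(sy, ns, ns)) / det
      rss_mat <- yy - (ws * matrix(sy, ns, ns) +
                         wm * matrix(my, ns, ns, byrow = TRUE))
      rss_mat[!is.finite(rss_mat)] <- Inf
      evals <- ns * ns
      best_rss <- min(rss_mat)
      tie <- which(rss_mat <= best_rss + 1e-9 * max(1, abs(best_rss)),
                   arr.ind = TRUE)
      cost <- abs(shifts[tie[, 1]]) + abs(shifts[tie[, 2]])
      pick <- tie[which.min(cost), ]
      i <- pick[1]; j <- pick[2]
      sol <- rss_at(i, j)
    } else {
      best <- NULL
      for (i in seq_len(ns)) for (j in seq_len(ns)) {
        r <- rss_at(i, j); evals <- evals + 1L
        better <- is.null(best) || r$rss < best$rss - 1e-9 * max(1, abs(best$rss))
        tied <- !is.null(best) &&
          abs(r$rss - best$rss) <= 1e-9 * max(1, abs(best$rss)) &&
          (abs(shifts[i]) + abs(shifts[j])) < (abs(shifts[best$i]) + abs(shifts[best$j]))
        if (better || tied) best <- c(r, list(i = i, j = j))
      }
      i <- best$i; j <- best$j; sol <- best
    }
  } else {
    rss_only <- function(i, j) rss_at(i, j)$rss
    best <- NULL
    with_seed(seed, {
      for (st in seq_len(n_starts)) {
        ci <- sample(ns, 1); cj <- sample(ns, 1)
        cur <- rss_only(ci, cj); evals <- evals + 1L
        repeat {
          nb <- rbind(c(ci - 1, cj), c(ci + 1, cj), c(ci, cj - 1), c(ci, cj + 1))
          nb <- nb[nb[, 1] >= 1 & nb[, 1] <= ns & nb[, 2] >= 1 & nb[, 2] <= ns, ,
                   drop = FALSE]
          vals <- apply(nb, 1, function(z) rss_only(z[1], z[2]))
          evals <- evals + nrow(nb)
          if (min(vals) < cur - 1e-12) {
            k <- which.min(vals); ci <- nb[k, 1]; cj <- nb[k, 2]; cur <- min(vals)
          } else break
        }
        if (is.null(best) || cur < best$rss)
          best <- list(rss = cur, i = ci, j = cj)
      }
    })
    i <- best$i; j <- best$j; sol <- rss_at(i, j)
  }

  w <- sol$w
  names(w) <- c(s_kinds, m_kinds)
  t_s <- shifts[i]; t_m <- shifts[j]
  xcols <- cbind(
    do.call(cbind, lapply(smats, function(m) m[, i])),
    do.call(cbind, lapply(mmats, function(m) m[, j])))
  yhat <- drop(xcols %*% w)
  b0 <- 0
  if (intercept) {
    # columns and y were centered for the search; recover the intercept on
    # the original scale
    raw <- cbind(
      do.call(cbind, lapply(design$regressors[s_kinds], function(r)
        shifted_columns(r, tw, shifts[i])[, 1])),
      do.call(cbind, lapply(design$regressors[m_kinds], function(r)
        shifted_columns(r, tw, shifts[j])[, 1])))
    b0 <- mean(y0) - sum(colMeans(raw) * w)
    yhat <- drop(raw %*% w) + b0
  }
  res <- y0 - yhat
  rss <- sum(res^2)
  tss <- sum((y0 - mean(y0))^2)
  nc <- length(design$conditions)
  to_mat <- function(v) matrix(v, nrow = nc, byrow = TRUE,
                               dimnames = list(design$conditions, NULL))
  structure(list(
    weights = w, intercept = if (intercept) b0 else NULL,
    t_s = t_s, t_m = t_m,
    rss = rss, r_squared = 1 - rss / tss,
    observed = design$y_matrix, fitted = to_mat(yhat),
    residuals = to_mat(res),
    window = design$window, window_time = tw,
    conditions = design$conditions, variant = variant,
    search = list(method = search, bounds = shift_bounds,
                  step = shift_step, evaluations = evals,
                  n_starts = if (search == "multistart") n_starts else NULL,
                  seed = if (search == "multistart") seed else NULL),
    call = match.call()),
    class = "dissim_lm")
}

#' @export
print.dissim_lm <- function(x, digits = 4, ...) {
  cat(sprintf("Time-shifted linear dissimilarity model (%s)\n", x$variant))
  cat(sprintf("  window %d..%d ms, %d conditions\n",
              x$window[1], x$window[2], length(x$conditions)))
  cat("  weights:\n")
  print(round(x$weights, digits))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept: %.4g\n", x$intercept))
  cat(sprintf("  t_s = %g ms, t_m = %g ms\n", x$t_s, x$t_m))
  cat(sprintf("  R^2 = %.3f (RSS = %.4g)\n", x$r_squared, x$rss))
  invisible(x)
}

#' @export
summary.dissim_lm <- function(object, ...) {
  per_cond <- vapply(seq_along(object$conditions), function(k) {
    o <- object$observed[k, ]; r <- object$residuals[k, ]
    1 - sum(r^2) / sum((o - mean(o))^2)
  }, 0)
  names(per_cond) <- object$conditions
  out <- list(fit = object, r_squared_by_condition = per_cond)
  class(out) <- "summary.dissim_lm"
  out
}

#' @export
print.summary.dissim_lm <- function(x, ...) {
  print(x$fit)
  cat("  per-condition R^2:\n")
  print(round(x$r_squared_by_condition, 3))
  invisible(x)
}

#' @export
coef.dissim_lm <- function(object, ...) {
  c(object$weights, t_s = object$t_s, t_m = object$t_m,
    if (!is.null(object$intercept)) c(intercept = object$intercept))
}

#' @export
fitted.dissim_lm <- function(object, ...) object$fitted

#' @export
residuals.dissim_lm <- function(object, ...) object$residuals

#' Predict neural dissimilarity from a design at the fitted parameters
#'
#' @param object a `dissim_lm`.
#' @param design optional new `dissim_design` on the same regressor kinds;
#'   defaults to re-predicting the training fit.
#' @param ... unused.
#' @return conditions x time matrix of predictions over the design window.
#' @export
predict.dissim_lm <- function(object, design = NULL, ...) {
  if (is.null(design)) return(object$fitted)
  stopifnot_msg(inherits(design, "dissim_design"), "design must be a dissim_design")
  tw <- design$window_time
  kinds <- names(object$weights)
  cols <- vapply(kinds, function(k) {
    sh <- if (design$regressors[[k]]$role == "sensory") object$t_s else object$t_m
    shifted_columns(design$regressors[[k]], tw, sh)[, 1]
  }, numeric(length(tw) * length(design$conditions)))
  yhat <- drop(cols %*% object$weights) +
    if (is.null(object$intercept)) 0 else object$intercept
  matrix(yhat, nrow = length(design$conditions), byrow = TRUE,
         dimnames = list(design$conditions, NULL))
}

#' @export
simulate.dissim_lm <- function(object, nsim = 1, seed = NULL, ...) {
  s <- sd(as.vector(object$residuals))
  f <- as.vector(t(object$fitted))
  sim_one <- function() f + rnorm(length(f), 0, s)
  if (!is.null(seed)) with_seed(seed, replicate(nsim, sim_one()))
  else replicate(nsim, sim_one())
}

#' @export
plot.dissim_lm <- function(x, ...) {
  nc <- length(x$conditions)
  op <- graphics::par(mfrow = c(ceiling(nc / 2), min(nc, 2)),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (k in seq_len(nc)) {
    graphics::plot(x$window_time, x$observed[k, ], type = "l",
                   xlab = "time (ms)", ylab = "dissimilarity",
                   main = x$conditions[k], ...)
    graphics::lines(x$window_time, x$fitted[k, ], col = 2, lty = 2)
  }
  invisible(x)
}

#' Residual traces and valid-minus-invalid residual differences
#'
#' Subtracting the model prediction from the observed neural dissimilarity
#' leaves the component not accounted for by sensory input or motor output.
#' When condition names follow the `<block>_<contrast>` convention
#' (e.g. `valid_12`, `invalid_12`), the valid-minus-invalid residual
#' difference is computed per contrast, ready for [cluster_test()].
#'
#' @param fit a `dissim_lm`.
#' @return list with `time`, `residuals` (conditions x time matrix) and
#'   `valid_minus_invalid` (named list per contrast, or `NULL` if condition
#'   names do not encode block/contrast).
#' @export
residual_differences <- function(fit) {
  res <- fit$residuals
  parts <- strsplit(fit$conditions, "_", fixed = TRUE)
  ok <- all(lengths(parts) == 2L) &&
    all(vapply(parts, `[[`, "", 1) %in% c("valid", "invalid"))
  diffs <- NULL
  if (ok) {
    contrast <- vapply(parts, `[[`, "", 2)
    block <- vapply(parts, `[[`, "", 1)
    diffs <- lapply(unique(contrast), function(ct) {
      v <- which(block == "valid" & contrast == ct)
      iv <- which(block == "invalid" & contrast == ct)
      if (length(v) == 1L && length(iv) == 1L) res[v, ] - res[iv, ] else NULL
    })
    names(diffs) <- unique(contrast)
    diffs <- Filter(Negate(is.null), diffs)
    if (!length(diffs)) diffs <- NULL
  }
  list(time = fit$window_time, residuals = res, valid_minus_invalid = diffs)
}
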