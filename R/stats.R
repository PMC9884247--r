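# Suprathreshold cluster masses of a t-value trace: contiguous runs of
# same-sign samples with |t| > tcrit. Returns start/end indices, sign, mass.
cluster_masses <- function(tvec, tcrit) {
  lab <- ifelse(tvec > tcrit, 1L, ifelse(tvec < -tcrit, -1L, 0L))
  r <- rle(lab)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep))
    return(data.frame(start = integer(), end = integer(),
                      sign = integer(), mass = numeric()))
  data.frame(start = starts[keep], end = ends[keep], sign = r$values[keep],
             mass = vapply(which(keep), function(k)
               sum(tvec[starts[k]:ends[k]]), 0))
}

# One-sample t values per column with sign-flip weights applied; X is
# participants x time, signs a vector of +/-1 per participant.
flip_tvals <- function(x, signs) {
  n <- nrow(x)
  m <- colMeans(x * signs)
  ssq <- colSums(x^2)                    # invariant under sign flips
  s2 <- (ssq - n * m^2) / (n - 1)
  tv <- m / sqrt(s2 / n)
  tv[!is.finite(tv)] <- 0                # zero-variance columns carry no evidence
  tv
}

#' Cluster-based permutation test for time series
#'
#' Tests a participants x time matrix against zero (or a paired condition)
#' with multiple-comparison control over time. Per-time one-sample t values
#' are thresholded at the two-sided cluster-defining p; contiguous
#' same-sign suprathreshold runs form clusters whose mass is the sum of
#' t values; the null distribution of the maximum absolute cluster mass is
#' built by sign-flipping whole participant traces (equivalent to shuffling
#' the data with zeros), jointly over both signs for two-sided control.
#' Corrected p uses the +1 convention so p is never exactly 0.
#'
#' @param traces participants x time matrix.
#' @param threshold_p two-sided cluster-defining p value (default 0.05).
#' @param n_perm number of sign-flip permutations (use 50000 for final
#'   inference; smaller values are fine for exploration).
#' @param seed permutation seed.
#' @param paired_with optional matrix of the same shape; the test is then
#'   applied to `traces - paired_with` (a paired comparison).
#' @param time optional ms axis used to label cluster extents.
#' @return a `cluster_result`: data frame `clusters` (start/end ms, sign,
#'   mass, corrected p) plus the test settings.
#' @examples
#' x <- matrix(rnorm(14 * 50), 14)
#' x[, 20:30] <- x[, 20:30] + 1
#' cluster_test(x, n_perm = 500, seed = 1)
#' @export
cluster_test <- function(traces, threshold_p = 0.05, n_perm = 1000,
                         seed = 1, paired_with = NULL, time = NULL) {
  x <- as.matrix(traces)
  if (!is.null(paired_with)) {
    stopifnot_msg(identical(dim(x), dim(as.matrix(paired_with))),
                  "paired_with must match traces in shape")
    x <- x - as.matrix(paired_with)
  }
  n <- nrow(x)
  if (n < 2) stop("need at least 2 participants", call. = FALSE)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p value")
  tcrit <- qt(1 - threshold_p / 2, df = n - 1)
  tobs <- flip_tvals(x, rep(1, n))
  obs <- cluster_masses(tobs, tcrit)
  null_max <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      cm <- cluster_masses(flip_tvals(x, signs), tcrit)
      if (nrow(cm)) max(abs(cm$mass)) else 0
    }, 0)
  })
  obs$p <- vapply(obs$mass, function(m)
    (1 + sum(null_max >= abs(m))) / (n_perm + 1), 0)
  if (!is.null(time)) {
    obs$start_ms <- time[obs$start]
    obs$end_ms <- time[obs$end]
  }
  structure(list(clusters = obs, threshold_p = threshold_p,
                 n_permutations = n_perm, seed = seed, tail = "two-sided",
                 n_participants = n, time = time),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "cluster_result: %d cluster(s), defining p = %g, %d permutations, n = %d\n",
    nrow(x$clusters), x$threshold_p, x$n_permutations, x$n_participants))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  invisible(x)
}

#' Significant clusters of a cluster test
#'
#' @param result a `cluster_result`.
#' @param alpha corrected significance level.
#' @return the rows of `result$clusters` with corrected p below `alpha`.
#' @export
significant_clusters <- function(result, alpha = 0.05) {
  result$clusters[result$clusters$p < alpha, , drop = FALSE]
}

#' Scalar t tests for participant summaries
#'
#' One-sample, two-sample (Welch) or paired t statistics with two-sided p,
#' used for scalar condition comparisons (e.g. the rotated-trace distance
#' difference at +100 ms) and for weight/shift significance summaries. A
#' zero-variance sample errors unless the one-sample mean equals `mu`
#' exactly, in which case t = 0 and p = 1.
#'
#' @param a numeric vector of participant values.
#' @param b optional second vector (required for two-sample/paired kinds).
#' @param kind test type.
#' @param mu null value for the one-sample test.
#' @return list with `statistic`, `p_value`, `df`, `kind`.
#' @export
scalar_test <- function(a, b = NULL,
                        kind = c("one_sample", "two_sample", "paired"),
                        mu = 0) {
  kind <- match.arg(kind)
  if (kind == "one_sample") {
    stopifnot_msg(length(a) >= 2, "need n >= 2")
    s <- sd(a)
    if (s == 0) {
      if (isTRUE(all.equal(mean(a), mu)))
        return(list(statistic = 0, p_value = 1, df = length(a) - 1,
                    kind = kind))
      stop("zero variance with mean different from mu", call. = FALSE)
    }
    tt <- stats::t.test(a, mu = mu)
  } else {
    stopifnot_msg(!is.null(b), "b required for two-sample/paired tests")
    stopifnot_msg(length(a) >= 2 && length(b) >= 2, "need n >= 2 per group")
    if (kind == "paired" && sd(a - b) == 0) {
      if (isTRUE(all.equal(mean(a - b), 0)))
        return(list(statistic = 0, p_value = 1, df = length(a) - 1,
                    kind = kind))
      stop("zero variance of paired differences", call. = FALSE)
    }
    if (kind == "two_sample" && sd(a) == 0 && sd(b) == 0) {
      if (isTRUE(all.equal(mean(a), mean(b))))
        return(list(statistic = 0, p_value = 1, df = 2 * (length(a) - 1),
                    kind = kind))
      stop("zero variance in both samples", call. = FALSE)
    }
    tt <- stats::t.test(a, b, paired = (kind == "paired"))
  }
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), kind = kind)
}
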