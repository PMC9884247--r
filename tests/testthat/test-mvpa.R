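test_that("rectangular smoothing spreads an impulse to 1/21 over +/-10 ms", {
  arr <- array(0, dim = c(1, 2, 101))
  arr[1, 1, 51] <- 1
  ep <- as_epochs(arr, time = 0:100)
  pp <- preprocess_epochs(ep, smooth_halfwidth = 10,
                          day_max_normalize = FALSE, channel_zscore = FALSE)
  expect_identical(pp$time, 10:90)
  v <- pp$data[1, 1, ]
  on <- pp$time >= 40 & pp$time <= 60   # impulse sat at t = 50
  expect_equal(unname(v[on]), rep(1 / 21, sum(on)), tolerance = 1e-12)
  expect_true(all(v[!on] == 0))
})

test_that("constant channels z-score to zero and identical days normalize identically", {
  set.seed(5)
  arr <- array(rnorm(8 * 3 * 50), dim = c(8, 3, 50))
  arr[, 2, ] <- 4  # constant channel
  ep <- as_epochs(arr, time = 0:49, day = rep(c("day1", "day2"), each = 4))
  # make day2 an exact copy of day1
  ep$data[5:8, , ] <- ep$data[1:4, , ]
  expect_message(pp <- preprocess_epochs(ep, smooth_halfwidth = 0),
                 "zero-SD")
  expect_true(all(pp$data[, 2, ] == 0))
  expect_equal(pp$data[1:4, , ], pp$data[5:8, , ], tolerance = 1e-12)
  # z-scored channels have unit SD over trials x times
  expect_equal(sd(as.vector(pp$data[, 1, ])), 1, tolerance = 1e-12)
})

test_that("an all-zero day is rejected", {
  arr <- array(0, dim = c(4, 2, 10))
  arr[1:2, , ] <- 1
  ep <- as_epochs(arr, time = 0:9, day = rep(c("a", "b"), each = 2))
  expect_error(preprocess_epochs(ep, smooth_halfwidth = 0,
                                 channel_zscore = FALSE), "all-zero")
})

test_that("pooled precision behaves in closed-form limits", {
  set.seed(7)
  # scalar case: precision is 1 / pooled variance
  a <- matrix(rnorm(20), 20, 1); b <- matrix(rnorm(30), 30, 1)
  pv <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (20 + 30 - 2)
  expect_equal(pooled_precision(a, b, shrinkage = "none")[1, 1], 1 / pv,
               tolerance = 1e-10)
  # full shrinkage: scaled identity
  a4 <- matrix(rnorm(40), 10, 4); b4 <- matrix(rnorm(40), 10, 4)
  p1 <- pooled_precision(a4, b4, shrinkage = 1)
  expect_equal(p1, diag(p1[1, 1], 4), tolerance = 1e-10)
  # large-sample identity recovery for iid unit-variance channels
  a_big <- matrix(rnorm(2000 * 4), 2000, 4)
  b_big <- matrix(rnorm(2000 * 4), 2000, 4)
  expect_lt(max(abs(pooled_precision(a_big, b_big, "none") - diag(4))), 0.1)
  # rank-deficient unshrunk covariance warns but returns
  a2 <- matrix(rnorm(3 * 5), 3, 5); b2 <- matrix(rnorm(3 * 5), 3, 5)
  expect_warning(pooled_precision(a2, b2, shrinkage = "none"),
                 "rank deficient")
})

test_that("dissimilarity is near zero under exchangeability", {
  set.seed(11)
  arr_a <- array(rnorm(100 * 3 * 10), dim = c(100, 3, 10))
  arr_b <- array(rnorm(100 * 3 * 10), dim = c(100, 3, 10))
  dt <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b))
  # time-averaged value within 2 MC SEs of zero
  se <- sd(dt$value) / sqrt(length(dt$value))
  expect_lt(abs(mean(dt$value)), 2 * se + 0.02)
})

test_that("cross-validation removes the positive bias of the naive distance", {
  set.seed(13)
  reps <- 40
  cv <- naive <- numeric(reps)
  for (r in seq_len(reps)) {
    arr_a <- array(rnorm(10 * 3 * 2), dim = c(10, 3, 2))
    arr_b <- array(rnorm(10 * 3 * 2), dim = c(10, 3, 2))
    cv[r] <- mean(crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b),
                                         shrinkage = "none")$value)
    naive[r] <- mean(crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b),
                                            shrinkage = "none",
                                            cross_validate = FALSE)$value)
  }
  expect_gt(mean(naive), mean(cv) + 2 * sd(naive) / sqrt(reps))
  expect_lt(abs(mean(cv)), 3 * sd(cv) / sqrt(reps))
})

test_that("dissimilarity is invariant to channel order and common linear maps", {
  set.seed(17)
  arr_a <- array(rnorm(8 * 4 * 3), dim = c(8, 4, 3)) + 0.5
  arr_b <- array(rnorm(8 * 4 * 3), dim = c(8, 4, 3))
  base <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b),
                                 shrinkage = "none")$value
  perm <- c(3, 1, 4, 2)
  v_perm <- crossval_dissimilarity(as_epochs(arr_a[, perm, , drop = FALSE]),
                                   as_epochs(arr_b[, perm, , drop = FALSE]),
                                   shrinkage = "none")$value
  expect_equal(v_perm, base, tolerance = 1e-8)
  m <- matrix(rnorm(16), 4, 4) + diag(4)
  lin <- function(arr) {
    out <- arr
    for (t in 1:3) out[, , t] <- arr[, , t] %*% m
    out
  }
  v_lin <- crossval_dissimilarity(as_epochs(lin(arr_a)), as_epochs(lin(arr_b)),
                                  shrinkage = "none")$value
  expect_equal(v_lin, base, tolerance = 1e-8)
})

test_that("equal trial counts make subsampling a seed-independent no-op", {
  set.seed(19)
  arr_a <- array(rnorm(6 * 3 * 4), dim = c(6, 3, 4))
  arr_b <- array(rnorm(6 * 3 * 4), dim = c(6, 3, 4))
  d1 <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b), seed = 1)
  d2 <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b), seed = 999)
  expect_identical(d1$value, d2$value)
  expect_identical(d1$subsample_iterations, 1L)
  # unequal counts: seeded subsampling is reproducible
  arr_c <- array(rnorm(12 * 3 * 4), dim = c(12, 3, 4))
  d3 <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_c), seed = 5)
  d4 <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_c), seed = 5)
  expect_identical(d3$value, d4$value)
  expect_identical(d3$subsample_iterations, 10L)
})

test_that("time-pooled covariance matches per-time at a single time point", {
  set.seed(29)
  arr_a <- array(rnorm(8 * 3 * 1), dim = c(8, 3, 1))
  arr_b <- array(rnorm(8 * 3 * 1), dim = c(8, 3, 1))
  per_t <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b),
                                  shrinkage = "none")$value
  pooled <- crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b),
                                   shrinkage = "none",
                                   time_pooled_cov = TRUE)$value
  expect_equal(pooled, per_t, tolerance = 1e-10)
  # multi-time: runs and stays finite
  arr_a2 <- array(rnorm(8 * 3 * 5), dim = c(8, 3, 5))
  arr_b2 <- array(rnorm(8 * 3 * 5), dim = c(8, 3, 5))
  v <- crossval_dissimilarity(as_epochs(arr_a2), as_epochs(arr_b2),
                              time_pooled_cov = TRUE)$value
  expect_true(all(is.finite(v)))
})

test_that("too few trials raise an error", {
  arr_a <- array(rnorm(2 * 3 * 2), dim = c(2, 3, 2))
  arr_b <- array(rnorm(5 * 3 * 2), dim = c(5, 3, 2))
  expect_error(crossval_dissimilarity(as_epochs(arr_a), as_epochs(arr_b)),
               ">= 3 trials")
})

test_that("channel groups select the documented subsets", {
  cfg <- sim_config(n_trials_per_cell = 1, n_channels = 64,
                    channel_names = montage_64(), seed = 2)
  tr <- simulate_eye_traces(cfg)
  ep <- generate_epochs(tr, cfg)
  expect_identical(dim(select_channels(ep, "default47")$data)[2], 47L)
  expect_identical(dim(select_channels(ep, "frontal_central")$data)[2], 13L)
  expect_identical(dim(select_channels(ep, "central_parietal")$data)[2], 14L)
  expect_identical(select_channels(ep, "all")$data, ep$data)
  expect_error(select_channels(ep, c("Cz", "NOPE", "ALSO_NOPE")),
               "NOPE, ALSO_NOPE")
})

test_that("feature dissimilarity of identical direction groups is near zero", {
  set.seed(23)
  nt <- length(-100:500)
  vh <- matrix(rnorm(8 * nt, sd = 0.1), 8)
  tr <- make_traces(vh, matrix(rnorm(8 * nt, sd = 0.1), 8))
  f <- motor_features(tr)$velocity
  d <- feature_dissimilarity(subset_features_idx(f, 1:4),
                             subset_features_idx(f, 5:8),
                             time_points = seq(-100, 500, by = 50))
  expect_lt(mean(abs(d$value)), 0.5)
})
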