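zero_traces <- function(n = 3) {
  nt <- length(-100:500)
  make_traces(matrix(0, n, nt), matrix(0, n, nt))
}

test_that("saccade screening applies the speed thresholds in their windows", {
  tr <- zero_traces(3)
  time <- tr$time
  # trial 2: 35 deg/s transient at 150 ms -> pursuit window violation
  tr$vel_h[2, time >= 150 & time <= 160] <- 35
  # trial 3: 6 deg/s drift at -50 ms -> fixation window violation (6 > 5)
  tr$vel_v[3, time >= -55 & time <= -45] <- 6
  rep_ <- screen_saccades(tr)
  expect_identical(rep_$kept_trial_ids, "t001")
  expect_identical(rep_$rejected$reason[rep_$rejected$trial_id == "t002"],
                   "pursuit_speed")
  expect_identical(rep_$rejected$reason[rep_$rejected$trial_id == "t003"],
                   "fixation_speed")
  # kept + rejected partition the input
  expect_setequal(c(rep_$kept_trial_ids, rep_$rejected$trial_id),
                  tr$meta$trial_id)
})

test_that("screening is idempotent on the kept set", {
  tr <- simulate_eye_traces(quick_config(saccade_rate = 0.5))
  rep1 <- screen_saccades(tr)
  kept <- apply_screening(tr, rep1)
  rep2 <- screen_saccades(kept)
  expect_identical(nrow(rep2$rejected), 0L)
})

test_that("screening rejects windows outside the time axis", {
  expect_error(screen_saccades(zero_traces(1),
                               pursuit_window = c(100, 900)), "outside")
})

test_that("latency estimation finds a sustained ramp onset", {
  time <- -100:500
  mk_speed <- function(onset) {
    s <- ifelse(time >= onset, 14 * (1 - exp(-0.02 * (time - onset))), 0)
    s + rep(c(0.05, -0.05), length.out = length(time))  # tiny baseline noise
  }
  est <- estimate_latency(mk_speed(120), time)
  expect_lt(abs(est - 120), 2.5)
  est2 <- estimate_latency(mk_speed(150), time)
  expect_lt(abs((est2 - est) - 30), 2.5)
  # flat trace: no crossing
  expect_message(
    flat <- estimate_latency(rep(0, length(time)), time),
    "degenerate baseline")
  expect_true(is.na(flat))
})

test_that("rotation maps the -30 degree direction onto the horizontal axis", {
  r <- pursuitmvpa:::rotate_hv(cos(-30 * pi / 180), sin(-30 * pi / 180), 30)
  expect_equal(r$v, 0, tolerance = 1e-12)
  # speed is preserved under rotation for every sample
  h <- rnorm(50); v <- rnorm(50)
  rr <- pursuitmvpa:::rotate_hv(h, v, -30)
  expect_equal(sqrt(rr$h^2 + rr$v^2), sqrt(h^2 + v^2), tolerance = 1e-12)
})

test_that("identical direction groups give zero trace distance", {
  nt <- length(-100:500)
  vh <- matrix(rep(c(1, 1, 2, 2), nt), 4, nt)
  vv <- matrix(rep(c(3, 3, 1, 1), nt), 4, nt)
  tr <- make_traces(vh, vv, target_dir = c(0, 0, -60, -60))
  td <- rotate_and_distance(tr, align = "stimulus")
  rot_v <- function(h, v) h * sin(-30 * pi / 180) + v * cos(-30 * pi / 180)
  expected <- abs(rot_v(1, 3) - rot_v(2, 1))
  expect_equal(unname(td$delta_y[, "valid"]),
               rep(expected, length(td$time)), tolerance = 1e-12)
  # full 2-D distance dominates the vertical separation and matches the
  # closed form on constant traces
  tde <- rotate_and_distance(tr, align = "stimulus", distance = "euclidean")
  rot_h <- function(h, v) h * cos(-30 * pi / 180) - v * sin(-30 * pi / 180)
  expected_e <- sqrt((rot_v(1, 3) - rot_v(2, 1))^2 +
                       (rot_h(1, 3) - rot_h(2, 1))^2)
  expect_equal(unname(tde$delta_y[, "valid"]),
               rep(expected_e, length(tde$time)), tolerance = 1e-12)
  expect_true(all(tde$delta_y >= td$delta_y - 1e-12))
  # truly identical groups
  tr2 <- make_traces(vh[c(1, 1, 1, 1), ], vv[c(1, 1, 1, 1), ],
                     target_dir = c(0, 0, -60, -60))
  td2 <- rotate_and_distance(tr2, align = "stimulus")
  expect_true(all(td2$delta_y == 0))
})

test_that("trace distance is invariant to a common velocity offset", {
  cfg <- quick_config(saccade_rate = 0)
  tr <- simulate_eye_traces(cfg)
  td1 <- rotate_and_distance(subset_traces(tr, tr$meta$contrast == 1),
                             align = "stimulus")
  tr$vel_h <- tr$vel_h + 0.7
  tr$vel_v <- tr$vel_v - 1.1
  td2 <- rotate_and_distance(subset_traces(tr, tr$meta$contrast == 1),
                             align = "stimulus")
  expect_equal(td1$delta_y, td2$delta_y, tolerance = 1e-6)
})

test_that("empty direction groups raise an informative error", {
  tr <- zero_traces(2)
  tr$meta$target_dir <- c(0, 0)
  expect_error(rotate_and_distance(tr, align = "stimulus"),
               "empty group.*-60")
})
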