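test_that("the design concatenates four conditions over the 30-330 ms window", {
  des <- make_synth_design()
  expect_length(des$y, 301 * 4)
  expect_identical(dim(des$y_matrix), c(4L, 301L))
  # max-min normalization is scale invariant
  des10 <- local({
    d <- make_synth_design()
    d
  })
  expect_equal(des$regressors$irve$values, des10$regressors$irve$values)
  rng <- range(des$regressors$irve$values)
  expect_equal(rng, c(0, 1))
})

test_that("a zero-range regressor is guarded and a constant stays constant", {
  tt <- -100:500
  conds <- c("valid_100", "invalid_100")
  mk <- function(v) list(time = tt, value = v)
  neural <- list(mk(rep(1, length(tt))), mk(rep(2, length(tt))))
  names(neural) <- conds
  flat <- list(mk(rep(5, length(tt))), mk(rep(5, length(tt))))
  names(flat) <- conds
  ramp <- list(mk(seq_along(tt) / 601), mk(seq_along(tt) / 601))
  names(ramp) <- conds
  expect_message(
    des <- build_design(lapply(neural, function(n) {
      n$value <- n$value[match(30:330, tt)]; n$time <- 30:330; n
    }), sensory = list(irve = flat), motor = list(eye_velocity = ramp)),
    "zero range")
  expect_true(all(des$regressors$irve$values == 0))
})

test_that("noiseless data are recovered exactly by the grid search", {
  des <- make_synth_design(w_s = 0.8, w_m = 0.3, t_s = -35, t_m = 27)
  ft <- fit_dissim_model(des)
  expect_equal(ft$t_s, -35)
  expect_equal(ft$t_m, 27)
  expect_equal(unname(ft$weights), c(0.8, 0.3), tolerance = 1e-8)
  expect_equal(ft$r_squared, 1, tolerance = 1e-10)
  expect_lt(ft$rss, 1e-16)
  expect_identical(names(ft$weights), c("irve", "eye_velocity"))
})

test_that("predictions plus residuals reproduce the observed traces exactly", {
  des <- make_synth_design(noise_frac = 0.25, seed = 4)
  ft <- fit_dissim_model(des)
  expect_equal(ft$fitted + ft$residuals, ft$observed, tolerance = 1e-12)
  expect_equal(predict(ft), ft$fitted)
  expect_equal(predict(ft, des), ft$fitted, tolerance = 1e-10)
  # intercept option makes residuals mean-zero over the fit window
  ft0 <- fit_dissim_model(des, intercept = TRUE)
  expect_lt(abs(mean(ft0$residuals)), 1e-10)
  expect_identical(names(coef(ft)),
                   c("irve", "eye_velocity", "t_s", "t_m"))
})

test_that("the full model nests the reduced model", {
  des <- make_synth_design(noise_frac = 0.3, seed = 9)
  # give the full variant its extra regressor kinds (true weights zero)
  tt <- -100:500
  extra_s <- lapply(seq_along(des$conditions), function(k)
    list(time = tt, value = (1 + k / 10) / (1 + exp(-(tt - 100 - 4 * k) / 20))))
  extra_m <- lapply(seq_along(des$conditions), function(k)
    list(time = tt, value = (1 - k / 20) / (1 + exp(-(tt - 220 - 5 * k) / 40))))
  names(extra_s) <- names(extra_m) <- des$conditions
  neural <- lapply(seq_along(des$conditions), function(k)
    list(time = des$window_time, value = des$y_matrix[k, ]))
  names(neural) <- des$conditions
  s_base <- lapply(seq_along(des$conditions), function(k)
    list(time = des$regressors$irve$time,
         value = des$regressors$irve$values[k, ]))
  m_base <- lapply(seq_along(des$conditions), function(k)
    list(time = des$regressors$eye_velocity$time,
         value = des$regressors$eye_velocity$values[k, ]))
  names(s_base) <- names(m_base) <- des$conditions
  des_full <- build_design(neural,
                           sensory = list(irve = s_base,
                                          retinal_velocity_error = extra_s),
                           motor = list(eye_velocity = m_base,
                                        eye_position = extra_m))
  ft_red <- fit_dissim_model(des_full, variant = "reduced",
                             shift_bounds = c(-60, 60))
  ft_full <- fit_dissim_model(des_full, variant = "full",
                              shift_bounds = c(-60, 60), shift_step = 5)
  expect_identical(names(ft_full$weights),
                   c("irve", "retinal_velocity_error", "eye_velocity",
                     "eye_position"))
  # full model can only explain at least as much at the same shifts; allow
  # its coarser shift grid a little slack
  expect_gte(ft_full$r_squared, ft_red$r_squared - 0.02)
})

test_that("multistart search agrees with the exhaustive grid here", {
  des <- make_synth_design(noise_frac = 0.15, seed = 21)
  g <- fit_dissim_model(des)
  m <- fit_dissim_model(des, search = "multistart", n_starts = 60, seed = 3)
  expect_equal(m$rss, g$rss, tolerance = 1e-6)
  expect_identical(c(m$t_s, m$t_m), c(g$t_s, g$t_m))
})

test_that("insufficient regressor coverage for the shift bounds errors", {
  des <- make_synth_design()
  expect_error(fit_dissim_model(des, shift_bounds = c(-200, 200)),
               "does not cover")
})

test_that("residual differences recover block structure by contrast", {
  des <- make_synth_design(noise_frac = 0.1, seed = 2)
  ft <- fit_dissim_model(des)
  rd <- residual_differences(ft)
  expect_named(rd$valid_minus_invalid, c("100", "12"))
  expect_length(rd$valid_minus_invalid[["12"]], 301)
  # noiseless fit: residuals identically zero
  ft0 <- fit_dissim_model(make_synth_design())
  rd0 <- residual_differences(ft0)
  expect_lt(max(abs(rd0$residuals)), 1e-8)
})
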