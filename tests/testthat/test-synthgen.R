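test_that("generation is bit-identical under a fixed seed and config", {
  cfg <- quick_config()
  a <- simulate_eye_traces(cfg)
  b <- simulate_eye_traces(cfg)
  expect_identical(a, b)
  expect_identical(generate_epochs(a, cfg), generate_epochs(b, cfg))
})

test_that("executed direction follows reliability weighting", {
  # negligible cue weight: executed direction equals the target direction
  cfg0 <- quick_config(cue_reliability = 1e-9, vel_noise_sd = 0)
  tr0 <- simulate_eye_traces(cfg0)
  expect_equal(tr0$meta$exec_dir, tr0$meta$target_dir, tolerance = 1e-6)

  # valid block: cue coincides with target, so weighting is exact
  cfg <- quick_config()
  tr <- simulate_eye_traces(cfg)
  v <- tr$meta$block == "valid"
  expect_equal(tr$meta$exec_dir[v], tr$meta$target_dir[v])

  # equal weights, target 0 vs cue -60: circular midpoint -30
  cfgm <- sim_config(n_trials_per_cell = 40, directions = c(0, -60),
                     cue_reliability = 5,
                     target_reliability_by_contrast = c("1" = 5, "0.12" = 5),
                     n_channels = 4, seed = 11)
  trm <- simulate_eye_traces(cfgm)
  sel <- trm$meta$block == "invalid" & trm$meta$target_dir == 0 &
    trm$meta$cue_dir == -60
  expect_gt(sum(sel), 0)
  expect_equal(trm$meta$exec_dir[sel], rep(-30, sum(sel)))
})

test_that("cue attraction grows monotonically with relative cue reliability", {
  att <- vapply(c(0.5, 2, 8), function(rc) {
    cfg <- quick_config(cue_reliability = rc, saccade_rate = 0)
    tr <- simulate_eye_traces(cfg)
    inv <- tr$meta$block == "invalid" & tr$meta$cue_dir != tr$meta$target_dir
    mean(abs(tr$meta$exec_dir[inv] - tr$meta$target_dir[inv]))
  }, 0)
  expect_true(all(diff(att) > 0))
})

test_that("position traces are the cumulative integral of velocity", {
  tr <- simulate_eye_traces(quick_config())
  pos <- t(apply(tr$vel_h, 1, pursuitmvpa:::cumtrapz1, dt = 1e-3))
  expect_equal(tr$pos_h, pos, tolerance = 1e-12)
  expect_true(all(diff(tr$time) == 1L))
})

test_that("saccade injection creates high-speed transients in the screening window", {
  cfg <- quick_config(saccade_rate = 1, vel_noise_sd = 0)
  tr <- simulate_eye_traces(cfg)
  speed <- sqrt(tr$vel_h^2 + tr$vel_v^2)
  win <- tr$time >= -100 & tr$time <= 250
  expect_true(all(apply(speed[, win] > 30, 1, any)))
  cfg0 <- quick_config(saccade_rate = 0, vel_noise_sd = 0,
                       latency_jitter_sd = 0)
  tr0 <- simulate_eye_traces(cfg0)
  sp0 <- sqrt(tr0$vel_h^2 + tr0$vel_v^2)
  expect_false(any(sp0[, tr0$time <= 100] > 5))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(cue_reliability = 0), "cue_reliability")
  expect_error(sim_config(contrasts = c(1, 1.3)), "contrasts")
  expect_error(sim_config(latency_mean_by_contrast = c("1" = -5, "0.12" = 124)),
               "latency")
  expect_error(sim_config(n_channels = 1), "n_channels")
})

test_that("degenerate forward model reproduces scaled shifted IRVE exactly", {
  cfg <- quick_config(noise_sd = 0, mix_weights = c(w_s = 2, w_m = 0),
                      mix_shifts = c(t_s = -35, t_m = 27),
                      vel_noise_sd = 0, saccade_rate = 0, n_channels = 4)
  tr <- simulate_eye_traces(cfg)
  ep <- generate_epochs(tr, cfg)
  irve <- integrate_rve(retinal_velocity_error(tr, cfg$target_speed))
  mag <- sqrt(irve$h^2 + irve$v^2)
  pat <- pursuitmvpa:::with_seed(cfg$spatial_pattern_seed, {
    list(P_s = matrix(rnorm(4 * 3), 4, 3))
  })
  k <- 1L
  d <- match(tr$meta$target_dir[k], cfg$directions)
  expected <- 2 * pat$P_s[2, d] *
    pursuitmvpa:::shift_series(mag[k, ], -35)
  expect_equal(ep$data[k, 2, ], expected, tolerance = 1e-12)
})

test_that("identical trials give identical epochs at zero noise", {
  cfg <- quick_config(noise_sd = 0, vel_noise_sd = 0, latency_jitter_sd = 0,
                      saccade_rate = 0)
  tr <- simulate_eye_traces(cfg)
  ep <- generate_epochs(tr, cfg)
  same_cell <- which(tr$meta$target_dir == 0 & tr$meta$contrast == 1 &
                       tr$meta$block == "valid")
  expect_gt(length(same_cell), 1)
  expect_equal(ep$data[same_cell[1], , ], ep$data[same_cell[2], , ],
               tolerance = 1e-12)
})
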