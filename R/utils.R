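#' @importFrom stats rnorm runif sd qt filter setNames simulate
NULL

# Run code with a temporary RNG state seeded by `seed`, restoring the caller's
# stream afterwards. All internal randomness goes through this so that results
# are reproducible per-call without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sample x(t + shift_ms) on the same uniform 1-ms grid, holding edge values.
# shift_ms > 0 looks ahead (pulls later samples earlier).
shift_series <- function(x, shift_ms) {
  n <- length(x)
  s <- as.integer(round(shift_ms))
  idx <- pmin(pmax(seq_len(n) + s, 1L), n)
  x[idx]
}

# Cumulative trapezoidal integral of y sampled at uniform spacing dt,
# anchored so the integral is 0 at the first sample.
cumtrapz1 <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1L] + y[-n]) / 2)) * dt
}

# Rotate 2-D rows (h, v) by angle degrees (counter-clockwise positive).
rotate_hv <- function(h, v, angle_deg) {
  th <- angle_deg * pi / 180
  list(h = h * cos(th) - v * sin(th),
       v = h * sin(th) + v * cos(th))
}

# Weighted circular mean of angles (degrees) on unit vectors.
circ_weighted_mean <- function(angles_deg, weights) {
  th <- angles_deg * pi / 180
  atan2(sum(weights * sin(th)), sum(weights * cos(th))) * 180 / pi
}

stopifnot_msg <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# Index of a time value on an integer-ms axis, with range check.
time_index <- function(time_axis, t, what = "time") {
  i <- match(as.integer(round(t)), time_axis)
  if (is.na(i))
    stop(sprintf("%s %s ms is outside the axis [%d, %d]",
                 what, format(t), min(time_axis), max(time_axis)), call. = FALSE)
  i
}
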