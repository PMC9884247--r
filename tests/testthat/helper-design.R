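# Synthetic 4-condition design with known ground truth for the time-shifted
# linear model. Sensory and motor templates are smooth condition-dependent
# sigmoids; the neural trace is constructed from the *normalized* regressors
# (as build_design produces them) so the true weights are exact.
make_synth_design <- function(w_s = 0.8, w_m = 0.3, t_s = -35, t_m = 27,
                              noise_frac = 0, seed = 1,
                              window = c(30, 330), bump = NULL) {
  tt <- -100:500
  conds <- c("valid_100", "invalid_100", "valid_12", "invalid_12")
  sig <- function(on, amp, tau) amp / (1 + exp(-(tt - on) / tau))
  s_raw <- list(sig(120, 1.0, 25), sig(135, 0.9, 25),
                sig(150, 1.2, 30), sig(170, 1.1, 30))
  m_raw <- list(sig(165, 1.0, 30), sig(175, 0.95, 30),
                sig(190, 0.9, 35), sig(205, 0.85, 35))
  norm <- function(lst) {
    m <- do.call(rbind, lst)
    (m - min(m)) / (max(m) - min(m))
  }
  s_n <- norm(s_raw); m_n <- norm(m_raw)
  tw <- seq(window[1], window[2])
  sh <- function(x, s) x[pmin(pmax(seq_along(x) + s, 1), length(x))]
  neural <- lapply(1:4, function(k) {
    y_full <- w_s * sh(s_n[k, ], t_s) + w_m * sh(m_n[k, ], t_m)
    y <- y_full[match(tw, tt)]
    if (!is.null(bump) && grepl("^valid", conds[k]) && grepl("12$", conds[k]))
      y <- y + bump$height * exp(-((tw - bump$center) / bump$width)^2)
    list(time = tw, value = y)
  })
  names(neural) <- conds
  if (noise_frac > 0) {
    sig_sd <- sd(unlist(lapply(neural, `[[`, "value")))
    neural <- pursuitmvpa:::with_seed(seed, lapply(neural, function(n) {
      n$value <- n$value + rnorm(length(n$value), 0, noise_frac * sig_sd)
      n
    }))
  }
  s_lst <- lapply(1:4, function(k) list(time = tt, value = s_raw[[k]]))
  m_lst <- lapply(1:4, function(k) list(time = tt, value = m_raw[[k]]))
  names(s_lst) <- names(m_lst) <- conds
  build_design(neural, sensory = list(irve = s_lst),
               motor = list(eye_velocity = m_lst), window = window)
}
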