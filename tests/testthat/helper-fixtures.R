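# Shared fixture builders. Everything is generated in code; seeds are fixed
# by the calling tests.

# 1-min CPP series with slow-wave structure (5-30 min periods) plus mild
# sampling noise, the input regime the inversion operates on.
make_cpp <- function(seed, n = 240, mean_cpp = 80, slow_sd = 7,
                     noise_sd = 1) {
  set.seed(seed)
  tt <- (seq_len(n) - 1) * 60
  periods <- 1 / stats::runif(3, 1 / 1800, 1 / 300)
  s <- rowSums(sapply(1:3, function(k) {
    stats::runif(1, 0.5, 1) * sin(2 * pi * tt / periods[k] + stats::runif(1, 0, 2 * pi))
  }))
  v <- mean_cpp + slow_sd * s / stats::sd(s) + stats::rnorm(n, 0, noise_sd)
  channel_series(tt, v, "CPP", rate = 1 / 60)
}

# Forward-inverse fixture: flow generated by the compartmental model under a
# piecewise-constant parameter schedule, optionally observed with additive
# noise. Returns truth and the noisy reference.
make_forward_inverse <- function(seed, n = 240, jumps = c(0.02, 0.06),
                                 noise_frac = 0) {
  cpp <- make_cpp(seed, n)
  set.seed(seed + 10000L)
  steps <- stats::runif(2, jumps[1], jumps[2]) * sample(c(-1, 1), 2, TRUE)
  a1 <- 0.012 * (1 + c(rep(0, n %/% 3), rep(steps[1], n %/% 3),
                       rep(steps[2], n - 2 * (n %/% 3))))
  alphas <- data.frame(alpha1 = a1, alpha2 = rep(0.5, n))
  q_true <- forward_flow(cpp, alphas)
  q_obs <- q_true$v
  if (noise_frac > 0) {
    q_obs <- q_obs + stats::rnorm(n, 0, noise_frac * stats::sd(q_true$v))
  }
  list(cpp = cpp,
       q_true = q_true,
       flow = channel_series(q_true$t, q_obs, "CBF", rate = 1 / 60),
       alphas = alphas)
}

# A clean epoch with all three required channels at low cost (short
# duration, low rate ABP/ICP unless waveform realism is required).
make_small_epoch <- function(seed = 1, duration_min = 100, regime = "pPFR",
                             ...) {
  generate_regime_epoch(synth_spec(regime, duration_min = duration_min,
                                   seed = seed, ...))
}

expect_no_na <- function(x) testthat::expect_false(anyNA(x))
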