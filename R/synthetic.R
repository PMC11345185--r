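#' Specification for a synthetic monitoring epoch
#'
#' Defines the generating conditions for a labelled synthetic epoch: the
#' pressure-flow regime, signal morphology, coordination gain between
#' perfusion pressure and tissue perfusion, per-channel noise, and any gaps
#' or artifacts to plant. The same spec (including `seed`) always produces
#' identical output.
#'
#' The coupling gain is the signed slope, in (mL/hg/min) per mmHg, linking
#' slow cerebral perfusion pressure (CPP) excursions to perfusion. Its sign
#' must match the regime: positive for `pPFR`, negative for `nPFR`; for
#' `zPFR` the magnitude is used in an alternating, zero-mean block schedule.
#' The effective signal-to-noise ratio of the coordination is
#' `|gain| * sd(slow CPP) / noise_sd["perf"]`; at the defaults it is 2.
#'
#' @param regime One of `"pPFR"`, `"zPFR"`, `"nPFR"`.
#' @param duration_min Epoch duration in minutes.
#' @param heart_rate Beats per minute, in `[30, 200]`.
#' @param abp_mean,pulse_pressure Mean arterial pressure and systolic-diastolic
#'   swing, mmHg.
#' @param icp_mean Mean intracranial pressure, mmHg.
#' @param slow_fluctuation_scale Standard deviation (mmHg) of the slow
#'   (1-10 min timescale) ABP fluctuations that drive CPP variability.
#' @param coupling_gain Signed CPP-to-perfusion gain; default set by regime
#'   (`+1`, `-1`, or magnitude 1 for the alternating zPFR schedule).
#' @param noise_sd Named vector of per-channel observation noise standard
#'   deviations (`abp`, `icp`, `perf`).
#' @param gap_spec Tibble with columns `channel`, `start`, `length` (seconds)
#'   describing runs to blank with `NA`.
#' @param defect_spec Tibble of artifact descriptors passed to
#'   [inject_defects()].
#' @param seed Integer RNG seed; same seed, same epoch.
#' @param zpfr_block_min Length in minutes of the alternating-sign gain blocks
#'   used for the zPFR schedule.
#' @param icp_abp_gain Fraction of the slow ABP fluctuation transmitted to ICP.
#' @param perf_baseline Perfusion baseline, mL/hg/min, jittered per epoch to
#'   emulate probe-placement heterogeneity.
#' @param abp_rate,icp_rate,perf_rate Nominal sampling rates in Hz.
#'
#' @return A list of class `pfr_synth_spec`.
#' @export
synth_spec <- function(regime = c("pPFR", "zPFR", "nPFR"),
                       duration_min = 120,
                       heart_rate = 70,
                       abp_mean = 90,
                       pulse_pressure = 40,
                       icp_mean = 12,
                       slow_fluctuation_scale = 5,
                       coupling_gain = NULL,
                       noise_sd = c(abp = 2, icp = 1, perf = 2),
                       gap_spec = NULL,
                       defect_spec = NULL,
                       seed = 1L,
                       zpfr_block_min = 15,
                       icp_abp_gain = 0.2,
                       perf_baseline = 30,
                       abp_rate = 125,
                       icp_rate = 125,
                       perf_rate = 1) {
  regime <- match.arg(regime)
  if (is.null(coupling_gain)) {
    coupling_gain <- switch(regime, pPFR = 1, nPFR = -1, zPFR = 1)
  }
  spec <- structure(list(
    regime = regime, duration_min = duration_min, heart_rate = heart_rate,
    abp_mean = abp_mean, pulse_pressure = pulse_pressure, icp_mean = icp_mean,
    slow_fluctuation_scale = slow_fluctuation_scale,
    coupling_gain = coupling_gain, noise_sd = noise_sd,
    gap_spec = gap_spec, defect_spec = defect_spec, seed = as.integer(seed),
    zpfr_block_min = zpfr_block_min, icp_abp_gain = icp_abp_gain,
    perf_baseline = perf_baseline, abp_rate = abp_rate, icp_rate = icp_rate,
    perf_rate = perf_rate
  ), class = "pfr_synth_spec")
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  fail <- function(field, why) {
    stop(sprintf("invalid synthetic spec: field `%s` %s", field, why),
         call. = FALSE)
  }
  if (!is.numeric(spec$duration_min) || spec$duration_min <= 0) {
    fail("duration_min", "must be > 0")
  }
  if (spec$heart_rate < 30 || spec$heart_rate > 200) {
    fail("heart_rate", "must lie in [30, 200] beats/min")
  }
  if (spec$pulse_pressure < 0) fail("pulse_pressure", "must be >= 0")
  if (any(spec$noise_sd < 0)) fail("noise_sd", "must be >= 0")
  if (!all(c("abp", "icp", "perf") %in% names(spec$noise_sd))) {
    fail("noise_sd", "must name abp, icp and perf entries")
  }
  g <- spec$coupling_gain
  if (spec$regime == "pPFR" && g <= 0) {
    fail("coupling_gain", "must be positive for regime pPFR")
  }
  if (spec$regime == "nPFR" && g >= 0) {
    fail("coupling_gain", "must be negative for regime nPFR")
  }
  if (!is.null(spec$gap_spec)) {
    if (any(spec$gap_spec$length > spec$duration_min * 60)) {
      fail("gap_spec", "contains a gap longer than the epoch duration")
    }
    if (any(spec$gap_spec$start < 0) ||
        any(spec$gap_spec$start + spec$gap_spec$length > spec$duration_min * 60)) {
      fail("gap_spec", "gap windows must lie inside the epoch")
    }
  }
  invisible(spec)
}

# Slow fluctuation process: three sinusoids with periods in the 1-10 min
# band (drawn uniformly in frequency, mimicking the red slow-wave spectrum)
# plus a lighter AR(1) drift, built at 1 Hz and scaled to standard
# deviation `scale`. Consumes RNG state; callers fix the seed.
draw_slow <- function(n_sec, scale) {
  if (scale <= 0) return(numeric(n_sec))
  tt <- seq_len(n_sec) - 1
  periods <- 1 / stats::runif(3, 1 / 600, 1 / 60)
  phases <- stats::runif(3, 0, 2 * pi)
  amps <- stats::runif(3, 0.5, 1)
  s <- rowSums(vapply(1:3, function(k) {
    amps[k] * sin(2 * pi * tt / periods[k] + phases[k])
  }, numeric(n_sec)))
  ar <- as.numeric(stats::filter(stats::rnorm(n_sec), exp(-1 / 120),
                                 method = "recursive"))
  s <- 0.9 * s / max(stats::sd(s), 1e-12) + 0.4 * ar / max(stats::sd(ar), 1e-12)
  s <- s - mean(s)
  s * scale / max(stats::sd(s), 1e-12)
}

# Resample a 1 Hz series to `rate` Hz by linear interpolation.
upsample <- function(x, rate, n_out) {
  if (rate == 1) return(x[seq_len(n_out)])
  t1 <- seq_along(x) - 1
  t_out <- (seq_len(n_out) - 1) / rate
  stats::approx(t1, x, xout = t_out, rule = 2)$y
}

# Mean-centred cardiac pulse component: half-sinusoid systolic upstroke to
# the pulse-pressure peak followed by an exponential diastolic decay.
pulse_train <- function(t, heart_rate, pulse_pressure) {
  if (pulse_pressure <= 0) return(numeric(length(t)))
  period <- 60 / heart_rate
  phase <- (t %% period) / period
  systole <- 0.3
  tau <- 0.25
  p <- ifelse(phase < systole,
              sin(pi * phase / (2 * systole)),
              exp(-(phase - systole) / tau))
  p <- p * pulse_pressure
  p - mean(p)
}

#' Generate a pulsatile arterial blood pressure series
#'
#' Produces an ABP waveform at the spec's nominal rate: the target mean plus
#' slow fluctuations, a cardiac pulse train with the requested pulse
#' pressure, and Gaussian observation noise. The mean over the full duration
#' stays within 1 mmHg of `abp_mean` by construction (all components are
#' mean-centred).
#'
#' @param spec A [synth_spec()].
#' @return A `pfr_channel` named `ABP` at `spec$abp_rate` Hz.
#' @export
generate_pulsatile_abp <- function(spec) {
  validate_synth_spec(spec)
  withr::with_seed(spec$seed, generate_abp_impl(spec)$abp)
}

generate_abp_impl <- function(spec) {
  n_sec <- round(spec$duration_min * 60)
  n <- n_sec * spec$abp_rate
  t <- (seq_len(n) - 1) / spec$abp_rate
  slow1 <- draw_slow(n_sec, spec$slow_fluctuation_scale)
  slow <- upsample(slow1, spec$abp_rate, n)
  noise <- if (spec$noise_sd[["abp"]] > 0) {
    stats::rnorm(n, 0, spec$noise_sd[["abp"]])
  } else numeric(n)
  v <- spec$abp_mean + slow + pulse_train(t, spec$heart_rate, spec$pulse_pressure) + noise
  list(
    abp = channel_series(t, v, "ABP", rate = spec$abp_rate),
    slow1 = slow1
  )
}

# Per-second coupling-gain schedule for a regime.
gain_schedule <- function(spec, n_sec) {
  g <- spec$coupling_gain
  if (spec$regime == "zPFR") {
    block <- round(spec$zpfr_block_min * 60)
    signs <- rep(c(1, -1), length.out = ceiling(n_sec / block))
    rep(signs, each = block)[seq_len(n_sec)] * abs(g)
  } else {
    rep(g, n_sec)
  }
}

#' Generate a labelled synthetic monitoring epoch
#'
#' Builds a full epoch under the requested pressure-flow regime: pulsatile
#' ABP and slowly varying ICP at their nominal rates, and 1 Hz perfusion
#' constructed as `baseline + gain(t) * (CPP(t) - mean(CPP)) + noise`, where
#' the gain follows the regime schedule (constant for pPFR/nPFR, alternating
#' equal-duration blocks for zPFR). Perfusion baseline and output scale are
#' jittered per epoch to emulate probe-placement heterogeneity. Gaps and
#' artifact defects in the spec are applied last. The generating gain per
#' 1-min block is recorded as ground truth.
#'
#' @param spec A [synth_spec()].
#' @return A list of class `pfr_labeled_epoch` with elements `epoch`
#'   (a `pfr_epoch`), `truth` (tibble of per-minute generating gain),
#'   `regime`, and `spec`.
#' @export
generate_regime_epoch <- function(spec) {
  validate_synth_spec(spec)
  withr::with_seed(spec$seed, {
    n_sec <- round(spec$duration_min * 60)
    built <- generate_abp_impl(spec)
    abp <- built$abp
    slow_abp <- built$slow1

    # ICP: mean + transmitted fraction of the ABP slow wave + own fluctuation
    n_icp <- n_sec * spec$icp_rate
    t_icp <- (seq_len(n_icp) - 1) / spec$icp_rate
    slow_icp_own <- draw_slow(n_sec, 1)
    icp_slow1 <- spec$icp_abp_gain * slow_abp + slow_icp_own
    icp_noise <- if (spec$noise_sd[["icp"]] > 0) {
      stats::rnorm(n_icp, 0, spec$noise_sd[["icp"]])
    } else numeric(n_icp)
    icp_v <- spec$icp_mean + upsample(icp_slow1, spec$icp_rate, n_icp) + icp_noise
    icp <- channel_series(t_icp, icp_v, "ICP", rate = spec$icp_rate)

    # noise-free 1 Hz CPP drives the perfusion coordination
    cpp1 <- (spec$abp_mean + slow_abp) - (spec$icp_mean + icp_slow1)
    gain <- gain_schedule(spec, n_sec)
    baseline <- spec$perf_baseline * stats::runif(1, 0.8, 1.2)
    scale_jit <- stats::runif(1, 0.9, 1.1)
    perf_noise <- if (spec$noise_sd[["perf"]] > 0) {
      stats::rnorm(n_sec, 0, spec$noise_sd[["perf"]])
    } else numeric(n_sec)
    # deviations are taken about the mean CPP of each constant-gain segment
    # (the global mean for constant-gain regimes); a sign change modulates
    # the response to pressure fluctuations, not the perfusion level
    seg <- cumsum(c(1, diff(gain) != 0))
    cpp_dev <- cpp1 - stats::ave(cpp1, seg)
    perf_v <- baseline + scale_jit * (gain * cpp_dev + perf_noise)
    t_perf <- seq_len(n_sec) - 1
    keep <- seq(1, n_sec, by = round(1 / spec$perf_rate))
    perf <- channel_series(t_perf[keep], perf_v[keep], "PERF",
                           rate = spec$perf_rate)

    epoch <- as_epoch(list(abp, icp, perf),
                      patient_id = sprintf("SYN%03d", spec$seed %% 1000L),
                      epoch_id = spec$regime)
    if (!is.null(spec$gap_spec)) epoch <- apply_gaps(epoch, spec$gap_spec)
    if (!is.null(spec$defect_spec)) epoch <- inject_defects(epoch, spec$defect_spec)

    minute <- floor(t_perf / 60)
    truth <- tibble::tibble(
      block = sort(unique(minute)),
      t_start = sort(unique(minute)) * 60,
      gain = as.numeric(tapply(scale_jit * gain, minute, mean))
    )
    structure(list(epoch = epoch, truth = truth, regime = spec$regime,
                   spec = spec),
              class = "pfr_labeled_epoch")
  })
}

# Blank gap windows with NA (explicit missingness, nothing dropped).
apply_gaps <- function(epoch, gap_spec) {
  out <- epoch
  for (i in seq_len(nrow(gap_spec))) {
    ch <- gap_spec$channel[i]
    s <- gap_spec$start[i]
    e <- s + gap_spec$length[i]
    sel <- out$channel == ch & out$t >= s & out$t < e
    out$v[sel] <- NA_real_
  }
  rebuild_epoch(out, epoch)
}

.defect_kinds <- c("abp_negative", "abp_spike", "perf_spike",
                   "perf_high_mean", "icp_plateau", "nan_gap")

#' Plant quality-control-violating artifacts in an epoch
#'
#' Writes artifacts into a copy of the epoch so the quality-control rules can
#' be exercised on known ground truth: negative ABP samples, ABP spikes,
#' perfusion spikes above 130 mL/hg/min, sustained elevated 5-min perfusion
#' means, sustained ICP plateaus above 100 mmHg, and `NA` gap runs. The
#' original epoch is untouched; an empty descriptor list returns the epoch
#' unchanged.
#'
#' @param epoch A `pfr_epoch`.
#' @param defects Tibble with columns `kind`, `channel`, `start`, `length`
#'   (seconds) and optional `value`. Recognised kinds:
#'   `"abp_negative"` (default value -5), `"abp_spike"` (default 300),
#'   `"perf_spike"` (default 140), `"perf_high_mean"` (default 96),
#'   `"icp_plateau"` (default 101), `"nan_gap"`.
#' @return A modified copy of `epoch`.
#' @export
inject_defects <- function(epoch, defects) {
  if (is.null(defects) || nrow(defects) == 0L) return(epoch)
  if (!all(defects$kind %in% .defect_kinds)) {
    bad <- setdiff(unique(defects$kind), .defect_kinds)
    stop(sprintf("unknown defect kind(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (!"channel" %in% names(defects)) defects$channel <- NA_character_
  if (!"value" %in% names(defects)) defects$value <- NA_real_
  t_max <- max(epoch$t)
  if (any(defects$start < 0) || any(defects$start + defects$length > t_max + 1)) {
    stop("defect windows must lie inside the epoch", call. = FALSE)
  }
  defaults <- c(abp_negative = -5, abp_spike = 300, perf_spike = 140,
                perf_high_mean = 96, icp_plateau = 101, nan_gap = NA_real_)
  out <- epoch
  for (i in seq_len(nrow(defects))) {
    d <- defects[i, ]
    val <- if ("value" %in% names(d) && !is.na(d$value)) d$value else defaults[[d$kind]]
    ch <- if (!is.na(d$channel)) d$channel else {
      switch(d$kind, abp_negative = "ABP", abp_spike = "ABP",
             perf_spike = "PERF", perf_high_mean = "PERF",
             icp_plateau = "ICP", nan_gap = "PERF")
    }
    sel <- out$channel == ch & out$t >= d$start & out$t < d$start + d$length
    out$v[sel] <- val
  }
  rebuild_epoch(out, epoch)
}
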