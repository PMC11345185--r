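test_that("ABP generator honours mean, rate and pulse morphology", {
  # all variability disabled -> constant at the target mean
  s0 <- synth_spec("pPFR", duration_min = 2, pulse_pressure = 0,
                   noise_sd = c(abp = 0, icp = 0, perf = 0),
                   slow_fluctuation_scale = 0, abp_mean = 90)
  abp0 <- generate_pulsatile_abp(s0)
  expect_equal(unique(abp0$v), 90)

  # 60 bpm -> beat period 1 s -> autocorrelation peak at lag 125 samples
  s1 <- synth_spec("pPFR", duration_min = 2, heart_rate = 60, seed = 7)
  abp1 <- generate_pulsatile_abp(s1)
  ac <- stats::acf(abp1$v, lag.max = 150, plot = FALSE)$acf[-1]
  expect_equal(which.max(ac[100:150]) + 99L, 125L)

  # mean within 1 mmHg of target; nominal 125 Hz
  expect_lt(abs(mean(abp1$v) - s1$abp_mean), 1)
  expect_equal(attr(abp1, "rate"), 125)
  expect_equal(nrow(abp1), 2 * 60 * 125)
})

test_that("same spec (including seed) reproduces identical output", {
  s <- synth_spec("pPFR", duration_min = 2, seed = 7)
  expect_identical(generate_pulsatile_abp(s), generate_pulsatile_abp(s))
  le1 <- generate_regime_epoch(synth_spec("zPFR", duration_min = 40, seed = 11))
  le2 <- generate_regime_epoch(synth_spec("zPFR", duration_min = 40, seed = 11))
  expect_identical(le1$epoch, le2$epoch)
  expect_identical(le1$truth, le2$truth)
})

test_that("invalid specs are rejected with the offending field named", {
  expect_error(synth_spec("pPFR", duration_min = 0), "duration_min")
  expect_error(synth_spec("pPFR", heart_rate = 250), "heart_rate")
  expect_error(synth_spec("pPFR", coupling_gain = -1), "coupling_gain")
  expect_error(synth_spec("nPFR", coupling_gain = 1), "coupling_gain")
  expect_error(
    synth_spec("pPFR", duration_min = 10,
               gap_spec = tibble::tibble(channel = "PERF", start = 0,
                                         length = 3600)),
    "gap"
  )
})

test_that("regime epochs carry channels at nominal rates with full truth", {
  le <- make_small_epoch(3, duration_min = 40)
  ep <- le$epoch
  expect_setequal(unique(ep$channel), c("ABP", "ICP", "PERF"))
  expect_equal(sum(ep$channel == "ABP"), 40 * 60 * 125)
  expect_equal(sum(ep$channel == "ICP"), 40 * 60 * 125)
  expect_equal(sum(ep$channel == "PERF"), 40 * 60)
  # truth covers every minute of the epoch
  expect_equal(le$truth$block, 0:(40 - 1))
  expect_true(all(le$truth$gain > 0))
})

test_that("1-min CPP and perfusion means coordinate with the gain sign", {
  # noise-free: the sample correlation has exactly the sign of the gain
  for (r in c("pPFR", "nPFR")) {
    le <- generate_regime_epoch(synth_spec(
      r, duration_min = 40, seed = 5,
      noise_sd = c(abp = 0, icp = 0, perf = 0)))
    cpp1 <- cpp_series(epoch_channel(le$epoch, "ABP"),
                       epoch_channel(le$epoch, "ICP"), 60)
    perf1 <- block_average(epoch_channel(le$epoch, "PERF"), 60)
    rho <- stats::cor(cpp1$v, perf1$v)
    expect_true(sign(rho) == sign(le$truth$gain[1]))
    expect_gt(abs(rho), 0.95)
  }
})

test_that("coordination sign survives noise at SNR 2 in most seeds", {
  hits <- vapply(1:25, function(s) {
    le <- generate_regime_epoch(synth_spec("pPFR", duration_min = 40,
                                           seed = s))
    cpp1 <- cpp_series(epoch_channel(le$epoch, "ABP"),
                       epoch_channel(le$epoch, "ICP"), 60)
    perf1 <- block_average(epoch_channel(le$epoch, "PERF"), 60)
    stats::cor(cpp1$v, perf1$v) > 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("zPFR gain schedule alternates in equal blocks and sums to zero", {
  le <- generate_regime_epoch(synth_spec("zPFR", duration_min = 60, seed = 2,
                                         zpfr_block_min = 15))
  g <- le$truth$gain
  expect_equal(sum(sign(g)), 0)
  expect_equal(unique(rle(sign(g))$lengths), 15)
})

test_that("gaps are written as explicit NA runs", {
  le <- generate_regime_epoch(synth_spec(
    "pPFR", duration_min = 30, seed = 4,
    gap_spec = tibble::tibble(channel = "PERF", start = 300, length = 120)))
  perf <- epoch_channel(le$epoch, "PERF")
  expect_true(all(is.na(perf$v[perf$t >= 300 & perf$t < 420])))
  expect_false(anyNA(perf$v[perf$t < 300]))
  expect_equal(nrow(perf), 30 * 60)  # nothing dropped
})

test_that("inject_defects writes artifacts without touching the original", {
  le <- make_small_epoch(6, duration_min = 30)
  ep <- le$epoch
  defects <- tibble::tibble(kind = c("icp_plateau", "perf_spike"),
                            channel = NA_character_,
                            start = c(60, 600), length = c(400, 1),
                            value = NA_real_)
  ep2 <- inject_defects(ep, defects)
  icp2 <- epoch_channel(ep2, "ICP")
  expect_true(all(icp2$v[icp2$t >= 60 & icp2$t < 460] == 101))
  perf2 <- epoch_channel(ep2, "PERF")
  expect_equal(perf2$v[perf2$t == 600], 140)
  # original untouched, empty defect list is the identity
  expect_false(any(epoch_channel(ep, "ICP")$v == 101))
  expect_identical(inject_defects(ep, NULL), ep)
  expect_identical(inject_defects(ep, defects[0, ]), ep)
})

test_that("unknown defect kinds and out-of-range windows are rejected", {
  ep <- make_small_epoch(6, duration_min = 30)$epoch
  expect_error(
    inject_defects(ep, tibble::tibble(kind = "flux_capacitor", start = 0,
                                      length = 10)),
    "unknown defect kind")
  expect_error(
    inject_defects(ep, tibble::tibble(kind = "perf_spike", start = 1e6,
                                      length = 10)),
    "inside the epoch")
})
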