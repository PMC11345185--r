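test_that("block averaging follows the left-aligned half-open contract", {
  ch <- channel_series(0:11, 0:11, "PERF")
  ba <- block_average(ch, 12)
  expect_equal(ba$v, 5.5)
  expect_equal(ba$t, 0)

  # constant series stays constant at the new rate
  cc <- channel_series(0:119, rep(3.2, 120), "PERF")
  expect_equal(block_average(cc, 10)$v, rep(3.2, 12))

  # an all-NA block stays missing; neighbours unaffected
  v <- rep(1, 30)
  v[11:20] <- NA
  bn <- block_average(channel_series(0:29, v, "PERF"), 10)
  expect_equal(is.na(bn$v), c(FALSE, TRUE, FALSE))

  # idempotent at the native block width
  b1 <- block_average(ch, 3)
  b2 <- block_average(b1, 3)
  expect_equal(b1$v, b2$v)
  expect_equal(b1$t, b2$t)

  expect_error(block_average(ch, 0.5), "sampling interval")
  expect_error(block_average(ch, -1), "width")
})

test_that("CPP is the difference of block means with NA propagation", {
  abp <- channel_series(0:119, rep(90, 120), "ABP")
  icp <- channel_series(0:119, rep(10, 120), "ICP")
  cpp <- cpp_series(abp, icp, 60)
  expect_true(all(cpp$v == 80))
  expect_identical(attr(cpp, "units"), "mmHg")

  v <- rep(90, 120)
  v[1:60] <- NA
  cppn <- cpp_series(channel_series(0:119, v, "ABP"), icp, 60)
  expect_true(is.na(cppn$v[1]) && cppn$v[2] == 80)

  # self-difference is identically zero
  expect_true(all(cpp_series(abp, abp, 60)$v == 0))

  late <- channel_series(0:9 + 10000, rep(10, 10), "ICP")
  expect_error(cpp_series(abp, late, 60), "disjoint")
})

test_that("interval extraction tiles runs within the length bounds", {
  ep120 <- make_small_epoch(1, duration_min = 120)$epoch
  iv <- extract_intervals(ep120)
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$duration_min, 120)

  ep90 <- make_small_epoch(1, duration_min = 90)$epoch
  expect_equal(nrow(extract_intervals(ep90)), 0L)

  # a 300-min run tiles as 140 + 140 + dropped 20-min remainder
  ep300 <- make_small_epoch(2, duration_min = 300)$epoch
  iv3 <- extract_intervals(ep300)
  expect_equal(iv3$duration_min, c(140, 140))
  # non-overlap
  expect_true(all(iv3$start[-1] >= iv3$end[-nrow(iv3)]))
  expect_true(all(iv3$duration_min >= 100 & iv3$duration_min <= 140))
})

test_that("perfusion gaps split runs only beyond the tolerance", {
  # 240-min epoch with a perfusion gap at minute 110
  gap12 <- generate_regime_epoch(synth_spec(
    "pPFR", duration_min = 240, seed = 3,
    gap_spec = tibble::tibble(channel = "PERF", start = 110 * 60,
                              length = 12 * 60)))$epoch
  iv <- extract_intervals(gap12)
  expect_equal(nrow(iv), 2L)
  expect_equal(iv$duration_min, c(110, 118))

  gap9 <- generate_regime_epoch(synth_spec(
    "pPFR", duration_min = 240, seed = 3,
    gap_spec = tibble::tibble(channel = "PERF", start = 110 * 60,
                              length = 9 * 60)))$epoch
  iv9 <- extract_intervals(gap9)
  expect_equal(iv9$duration_min, c(140, 100))

  # an ABP dropout splits regardless of tolerance
  abp_gap <- generate_regime_epoch(synth_spec(
    "pPFR", duration_min = 240, seed = 3,
    gap_spec = tibble::tibble(channel = "ABP", start = 110 * 60,
                              length = 2 * 60)))$epoch
  expect_equal(extract_intervals(abp_gap)$duration_min, c(110, 128))

  noperf <- as_epoch(list(channel_series(0:99, rnorm(100), "ABP"),
                          channel_series(0:99, rnorm(100), "ICP")))
  expect_error(extract_intervals(noperf), "PERF")
})

test_that("each screening rule fires on its planted defect", {
  ep <- make_small_epoch(5, duration_min = 100)$epoch
  iv <- extract_intervals(ep)
  dat <- iv$data[[1]]

  clean <- qc_filter(dat, abp_upper = iv$abp_q998[1])
  expect_true(clean$passed)
  expect_equal(nrow(clean$reasons), 0L)

  plant <- function(kind, start, length, value = NA_real_) {
    inject_defects(dat, tibble::tibble(kind = kind, channel = NA_character_,
                                       start = start, length = length,
                                       value = value))
  }
  # sustained ICP above 100 mmHg for 6 min
  r <- qc_filter(plant("icp_plateau", 600, 360), abp_upper = iv$abp_q998[1])
  expect_false(r$passed)
  expect_true("icp_plateau" %in% r$reasons$rule)
  # 4 min does not trip the 5-min rule
  r4 <- qc_filter(plant("icp_plateau", 600, 240), abp_upper = iv$abp_q998[1])
  expect_true(r4$passed)

  # single perfusion sample above the 130 ceiling
  r <- qc_filter(plant("perf_spike", 600, 1), abp_upper = iv$abp_q998[1])
  expect_equal(unique(r$reasons$rule), "perf_above_max")

  # sustained perfusion lifting a 5-min mean above 95
  r <- qc_filter(plant("perf_high_mean", 600, 360), abp_upper = iv$abp_q998[1])
  expect_true("perf_high_5min_mean" %in% r$reasons$rule)

  # one negative ABP sample
  r <- qc_filter(plant("abp_negative", 600, 0.01), abp_upper = iv$abp_q998[1])
  expect_true("abp_negative" %in% r$reasons$rule)

  # negative perfusion and negative ICP
  neg <- dat
  neg$v[neg$channel == "PERF"][5] <- -1
  expect_true("perf_negative" %in% qc_filter(neg)$reasons$rule)
})

test_that("QC reports exactly the planted rules, with time ranges", {
  ep <- make_small_epoch(7, duration_min = 100)$epoch
  iv <- extract_intervals(ep)
  dat <- inject_defects(iv$data[[1]], tibble::tibble(
    kind = c("icp_plateau", "perf_spike", "abp_negative"),
    channel = NA_character_,
    start = c(300, 2000, 4000), length = c(400, 1, 1), value = NA_real_))
  r <- qc_filter(dat, abp_upper = iv$abp_q998[1])
  expect_setequal(unique(r$reasons$rule),
                  c("icp_plateau", "perf_above_max", "abp_negative"))
  plateau <- r$reasons[r$reasons$rule == "icp_plateau", ]
  expect_lte(abs(plateau$start - 300), 1)
  expect_gte(plateau$end - plateau$start, 300)
  expect_identical(tidy(r), r$reasons)
})

test_that("QC is monotone: extra defects never rescue a failing interval", {
  ep <- make_small_epoch(9, duration_min = 100)$epoch
  iv <- extract_intervals(ep)
  one <- inject_defects(iv$data[[1]], tibble::tibble(
    kind = "perf_spike", channel = NA_character_, start = 600, length = 1,
    value = NA_real_))
  two <- inject_defects(one, tibble::tibble(
    kind = "icp_plateau", channel = NA_character_, start = 1000,
    length = 400, value = NA_real_))
  r1 <- qc_filter(one, abp_upper = iv$abp_q998[1])
  r2 <- qc_filter(two, abp_upper = iv$abp_q998[1])
  expect_false(r1$passed)
  expect_false(r2$passed)
  expect_true(all(r1$reasons$rule %in% r2$reasons$rule))
})
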