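test_that("moving correlation matches its defining per-window computation", {
  # brute-force oracle: block means then plain cor() per window
  brute <- function(x, y, w, n, step) {
    xb <- as.numeric(tapply(x$v, x$t %/% w, mean))
    yb <- as.numeric(tapply(y$v, y$t %/% w, mean))
    sb <- step / w
    n_win <- floor((length(xb) - n) / sb) + 1
    vapply(seq_len(n_win), function(k) {
      i <- (k - 1) * sb + 1
      suppressWarnings(stats::cor(xb[i:(i + n - 1)], yb[i:(i + n - 1)]))
    }, numeric(1))
  }
  for (s in 1:10) {
    set.seed(s)
    x <- channel_series(0:1799, rnorm(1800), "ABP")
    y <- channel_series(0:1799, rnorm(1800), "ICP")
    got <- moving_corr(x, y, 10, 30, 60)
    expect_lt(max(abs(got$value - brute(x, y, 10, 30, 60))), 1e-12)
  }
})

test_that("self, negated and constant windows give 1, -1 and NA", {
  set.seed(2)
  x <- channel_series(0:1799, rnorm(1800), "ABP")
  same <- channel_series(x$t, x$v, "ICP")
  expect_true(all(abs(moving_corr(x, same, 10, 30)$value - 1) < 1e-12))
  neg <- channel_series(x$t, -x$v, "ICP")
  expect_true(all(abs(moving_corr(x, neg, 10, 30)$value + 1) < 1e-12))

  v <- x$v
  v[1:400] <- 5  # first windows constant -> undefined correlation
  xc <- channel_series(x$t, v, "ABP")
  out <- moving_corr(xc, same, 10, 30)
  expect_true(is.na(out$value[1]))
  expect_false(is.na(out$value[nrow(out)]))

  expect_error(moving_corr(x, same, 10, 30, step = 5), "at least")
})

test_that("window bookkeeping follows floor((T - span)/step) + 1", {
  for (dur in c(900, 1800, 3607)) {
    x <- channel_series(0:(dur - 1), rnorm(dur), "ABP")
    y <- channel_series(0:(dur - 1), rnorm(dur), "ICP")
    got <- moving_corr(x, y, 10, 30, 60)
    span <- 10 * 30
    Tb <- floor(dur / 10) * 10
    expect_equal(nrow(got), floor((Tb - span) / 60) + 1)
    # emitted timestamp is the window end
    expect_equal(got$t[1], span)
  }
})

test_that("Mx uses 6-min windows of 12-s averages and tracks coupling sign", {
  set.seed(3)
  flow <- channel_series(0:3599, rnorm(3600, 30, 3), "PERF")
  cpp <- channel_series(0:3599, rnorm(3600, 80, 5), "CPP")
  m <- mx(flow, cpp)
  expect_equal(attr(m, "avg_width") * attr(m, "n_samples"), 360)
  expect_equal(m$t[1], 360)

  same <- channel_series(0:3599, flow$v, "CPP")
  expect_true(all(abs(mx(flow, same)$value - 1) < 1e-12))

  # strongly negative coupling at low noise -> median Mx below zero
  le <- generate_regime_epoch(synth_spec(
    "nPFR", duration_min = 60, seed = 9,
    noise_sd = c(abp = 0.5, icp = 0.2, perf = 0.5)))
  cppf <- cpp_series(epoch_channel(le$epoch, "ABP"),
                     epoch_channel(le$epoch, "ICP"), 1)
  mxs <- mx(epoch_channel(le$epoch, "PERF"), cppf)
  expect_lt(stats::median(mxs$value, na.rm = TRUE), 0)
})

test_that("PRx behaves as the ABP-ICP moving correlation", {
  set.seed(4)
  abp <- channel_series(0:3599, rnorm(3600, 90, 5), "ABP")
  icp_same <- channel_series(0:3599, abp$v, "ICP")
  expect_true(all(abs(prx(abp, icp_same)$value - 1) < 1e-12))
  icp_neg <- channel_series(0:3599, -abp$v, "ICP")
  expect_true(all(abs(prx(abp, icp_neg)$value + 1) < 1e-12))

  # independent inputs: mean PRx near zero within 2 standard errors
  vals <- unlist(lapply(1:6, function(s) {
    set.seed(100 + s)
    a <- channel_series(0:3599, rnorm(3600), "ABP")
    i <- channel_series(0:3599, rnorm(3600), "ICP")
    prx(a, i)$value
  }))
  se <- stats::sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se + 0.02)
})

test_that("indices are invariant to positive affine maps, negate with sign", {
  set.seed(5)
  a <- channel_series(0:1799, rnorm(1800, 90, 5), "ABP")
  b <- channel_series(0:1799, 0.4 * a$v + rnorm(1800, 12, 2), "ICP")
  base <- prx(a, b)$value
  scaled <- prx(channel_series(a$t, 3 * a$v + 20, "ABP"), b)$value
  expect_equal(base, scaled, tolerance = 1e-12)
  negated <- prx(channel_series(a$t, -a$v, "ABP", units = "mmHg"), b)$value
  expect_equal(negated, -base, tolerance = 1e-12)
})

test_that("neutral-Mx epochs are tested for smaller PRx one-sidedly", {
  # power scenario: neutral group shifted down by 0.2 with sd 0.1, 6 vs 17
  set.seed(6)
  hits <- replicate(300, {
    df <- tibble::tibble(
      mx = c(runif(6, -0.1, 0.1), runif(17, 0.3, 0.8)),
      prx = c(rnorm(6, 0.08, 0.1), rnorm(17, 0.28, 0.1))
    )
    neutral_mx_compare(df)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)

  # identical populations: p is not systematically small
  set.seed(7)
  ps <- replicate(300, {
    df <- tibble::tibble(mx = c(runif(8, -0.1, 0.1), runif(15, 0.3, 0.8)),
                         prx = rnorm(23, 0.2, 0.15))
    neutral_mx_compare(df)$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
  expect_gt(mean(ps < 0.05), 0.0)  # occasional small values are expected
  expect_lt(mean(ps < 0.05), 0.12)

  # degenerate split is an error
  df <- tibble::tibble(mx = runif(10, 0.3, 0.8), prx = rnorm(10))
  expect_error(neutral_mx_compare(df, neutral_cut = 0), "at least 2")
})
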