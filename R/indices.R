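#' Moving-window correlation of two block-averaged signals
#'
#' The computational core shared by the autoregulation indices: both inputs
#' are block-averaged at `avg_width` seconds, then for every window of
#' `n_samples` consecutive blocks, advancing by `step` seconds, the Pearson
#' correlation of the paired block means is emitted. Windows containing any
#' missing pair, or with zero variance in either signal, yield `NA`.
#' Emitted timestamps are window ends.
#'
#' @param x,y `pfr_channel` series covering at least one window.
#' @param avg_width Block-averaging width, seconds.
#' @param n_samples Number of blocks per correlation window.
#' @param step Window advance in seconds; must be at least `avg_width` and a
#'   multiple of it.
#' @return A tibble of class `pfr_indices` with columns `t` (window end,
#'   seconds) and `value` (correlation in `[-1, 1]` or `NA`), carrying the
#'   window parameters as attributes.
#' @export
moving_corr <- function(x, y, avg_width, n_samples, step = 60) {
  if (step < avg_width) {
    stop("`step` must be at least `avg_width`", call. = FALSE)
  }
  if (abs(step / avg_width - round(step / avg_width)) > 1e-9) {
    stop("`step` must be a multiple of `avg_width`", call. = FALSE)
  }
  xb <- block_average(x, avg_width)
  yb <- block_average(y, avg_width)
  common <- sort(intersect(xb$t, yb$t))
  if (length(common) < n_samples) {
    stop("inputs do not cover one full window", call. = FALSE)
  }
  xv <- xb$v[match(common, xb$t)]
  yv <- yb$v[match(common, yb$t)]
  step_blocks <- as.integer(round(step / avg_width))
  vals <- rolling_corr_cpp(xv, yv, as.integer(n_samples), step_blocks)
  n_win <- length(vals)
  starts <- common[1L] + (seq_len(n_win) - 1L) * step
  out <- tibble::tibble(t = starts + n_samples * avg_width, value = vals)
  attr(out, "index") <- paste0(channel_name(x) %||% "x", "~",
                               channel_name(y) %||% "y")
  attr(out, "avg_width") <- avg_width
  attr(out, "n_samples") <- n_samples
  attr(out, "step") <- step
  class(out) <- c("pfr_indices", class(out))
  out
}

#' Mean flow index (Mx)
#'
#' Moving correlation of flow and CPP: 30-sample correlations of 12-s
#' averages, i.e. 6-min windows, advancing by `step` seconds. Values near
#' +1 indicate pressure-passive flow (impaired autoregulation); values near
#' 0 indicate decoupled pressure and flow.
#'
#' @param flow Flow `pfr_channel` (observed perfusion or model CBF).
#' @param cpp CPP `pfr_channel`.
#' @param avg_width,n_samples,step Window parameters (defaults 12 s, 30
#'   samples, 60 s).
#' @return A `pfr_indices` tibble named `Mx`.
#' @export
mx <- function(flow, cpp, avg_width = 12, n_samples = 30, step = 60) {
  out <- moving_corr(flow, cpp, avg_width, n_samples, step)
  attr(out, "index") <- "Mx"
  out
}

#' Pressure reactivity index (PRx)
#'
#' Moving correlation of ABP and ICP. There is no consensus windowing for
#' PRx; the defaults follow the common literature convention of 30-sample
#' correlations of 10-s averages (5-min windows) and are configurable.
#'
#' @param abp,icp `pfr_channel` series.
#' @param avg_width,n_samples,step Window parameters (defaults 10 s, 30
#'   samples, 60 s).
#' @return A `pfr_indices` tibble named `PRx`.
#' @export
prx <- function(abp, icp, avg_width = 10, n_samples = 30, step = 60) {
  out <- moving_corr(abp, icp, avg_width, n_samples, step)
  attr(out, "index") <- "PRx"
  out
}

#' Compare PRx between neutral-Mx and coupled epochs
#'
#' Splits epochs into a neutral group (`|Mx| < neutral_cut`, decoupled
#' pressure and flow) and the remainder, and tests whether the neutral
#' group's mean PRx is smaller (one-sided two-sample t-test), the pattern
#' expected when functional autoregulation decouples flow from pressure.
#'
#' @param data Data frame with one row per epoch.
#' @param mx_col,prx_col Column names of the epoch-mean Mx and PRx values.
#' @param neutral_cut Neutral band half-width on mean Mx (default 0.15).
#' @return A one-row tibble: group sizes and means, the t statistic and the
#'   one-sided p-value.
#' @export
neutral_mx_compare <- function(data, mx_col = "mx", prx_col = "prx",
                               neutral_cut = 0.15) {
  mxv <- data[[mx_col]]
  prxv <- data[[prx_col]]
  if (is.null(mxv) || is.null(prxv)) {
    stop("`data` must contain the Mx and PRx columns", call. = FALSE)
  }
  neutral <- abs(mxv) < neutral_cut
  if (sum(neutral) < 2L || sum(!neutral) < 2L) {
    stop("each group needs at least 2 epochs", call. = FALSE)
  }
  tt <- stats::t.test(prxv[neutral], prxv[!neutral], alternative = "less")
  tibble::tibble(
    n_neutral = sum(neutral), n_other = sum(!neutral),
    mean_prx_neutral = mean(prxv[neutral]),
    mean_prx_other = mean(prxv[!neutral]),
    statistic = unname(tt$statistic),
    p_value = tt$p.value,
    neutral_cut = neutral_cut
  )
}

#' Epoch-level summary of an index series
#'
#' @param index A `pfr_indices` tibble.
#' @return Mean over all valid windows (the epoch-level index summary).
#' @export
index_mean <- function(index) mean(index$value, na.rm = TRUE)
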