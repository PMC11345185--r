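#' Variance-standardised linear calibration of model flow to perfusion
#'
#' Calibrates model CBF to observed perfusion with a linear correction
#' `m * CBF + b`, where `m` is identified by minimising the RMSE between the
#' two signals after each is standardised to zero mean and unit variance.
#' Under that standardisation the least-squares slope `m` equals the Pearson
#' correlation of the two series, so `|m| <= 1` and slopes are comparable
#' across intervals whose perfusion ranges differ with probe placement. The
#' offset `b` is reported back-transformed to perfusion units.
#'
#' @param q_hat Model CBF `pfr_channel` at 1-min resolution.
#' @param perfusion Observed perfusion `pfr_channel` on the same grid.
#' @param min_n Minimum number of jointly valid sample pairs (default 30);
#'   pairs with a missing member are dropped listwise.
#' @return A list of class `pfr_correction` with `m` (standardised slope),
#'   `b` (offset, perfusion units), `rmse` (residual of the standardised
#'   fit), and `n` (pairs used).
#' @export
fit_correction <- function(q_hat, perfusion, min_n = 30) {
  common <- intersect(round(q_hat$t, 6), round(perfusion$t, 6))
  q <- q_hat$v[match(common, round(q_hat$t, 6))]
  p <- perfusion$v[match(common, round(perfusion$t, 6))]
  ok <- !is.na(q) & !is.na(p)
  q <- q[ok]
  p <- p[ok]
  n <- length(q)
  if (n < min_n) {
    stop(sprintf("need at least %d joint samples, got %d", min_n, n),
         call. = FALSE)
  }
  sq <- stats::sd(q)
  sp <- stats::sd(p)
  if (sq == 0 || sp == 0) {
    stop("zero variance in one of the series; standardisation undefined",
         call. = FALSE)
  }
  qs <- (q - mean(q)) / sq
  ps <- (p - mean(p)) / sp
  m <- sum(qs * ps) / sum(qs^2)    # OLS slope on standardised signals
  rmse <- sqrt(mean((m * qs - ps)^2))
  b <- mean(p) - m * sp / sq * mean(q)
  structure(list(m = m, b = b, rmse = rmse, n = n),
            class = "pfr_correction")
}

#' @export
print.pfr_correction <- function(x, ...) {
  cat(sprintf("<pfr_correction> m = %.3f, b = %.2f, rmse = %.3f, n = %d\n",
              x$m, x$b, x$rmse, x$n))
  invisible(x)
}

#' Tidy a calibration fit
#'
#' @param x A `pfr_correction`.
#' @param ... Unused.
#' @return One row per coefficient (`m`, `b`).
#' @export
tidy.pfr_correction <- function(x, ...) {
  tibble::tibble(term = c("m", "b"), estimate = c(x$m, x$b))
}

#' One-row summary of a calibration fit
#'
#' @param x A `pfr_correction`.
#' @param ... Unused.
#' @export
glance.pfr_correction <- function(x, ...) {
  tibble::tibble(m = x$m, b = x$b, rmse = x$rmse, n = x$n)
}

#' Classify the pressure-flow regime from the calibration slope
#'
#' The sign and magnitude of the standardised slope decide the regime of a
#' 2-h interval: `m > threshold` is positive coordination (`pPFR`),
#' `m < -threshold` negative coordination (`nPFR`), and `|m| <= threshold`
#' (boundary inclusive) no net coordination (`zPFR`). Every finite slope
#' maps to exactly one label.
#'
#' @param corr A `pfr_correction`, or a numeric slope.
#' @param threshold Slope band half-width (default 0.2).
#' @return A one-row tibble with `label` (factor pPFR/zPFR/nPFR), `m`, and
#'   `threshold`.
#' @export
classify_pfr <- function(corr, threshold = 0.2) {
  m <- if (inherits(corr, "pfr_correction")) corr$m else as.numeric(corr)
  if (!is.finite(m)) stop("slope must be finite", call. = FALSE)
  label <- if (m > threshold) "pPFR" else if (m < -threshold) "nPFR" else "zPFR"
  tibble::tibble(
    label = factor(label, levels = c("pPFR", "zPFR", "nPFR")),
    m = m, threshold = threshold
  )
}

#' Classify one analysis interval end to end
#'
#' Convenience wrapper running the per-interval pipeline: 1-min CPP from ABP
#' and ICP, 1-min perfusion means, constrained model inversion
#' ([estimate_cbf()]), standardised calibration ([fit_correction()]), and
#' regime classification ([classify_pfr()]).
#'
#' @param interval A `pfr_epoch` slice containing ABP, ICP and PERF.
#' @param threshold Slope band half-width for [classify_pfr()].
#' @param config An [inversion_config()].
#' @param min_n Minimum joint samples for the calibration fit.
#' @return A one-row tibble: `label`, `m`, `b`, `rmse`, `n_samples`,
#'   `cor_q_cpp`, `threshold`.
#' @export
classify_interval <- function(interval, threshold = 0.2,
                              config = inversion_config(), min_n = 30) {
  abp <- epoch_channel(interval, "ABP")
  icp <- epoch_channel(interval, "ICP")
  perf <- epoch_channel(interval, "PERF")
  if (is.null(abp) || is.null(icp) || is.null(perf)) {
    stop("interval must contain ABP, ICP and PERF", call. = FALSE)
  }
  cpp1 <- cpp_series(abp, icp, 60)
  perf1 <- block_average(perf, 60)
  est <- estimate_cbf(cpp1, perf1, config)
  corr <- fit_correction(est$q, perf1, min_n = min_n)
  lab <- classify_pfr(corr, threshold)
  dplyr::mutate(lab, b = corr$b, rmse = corr$rmse, n_samples = corr$n,
                cor_q_cpp = est$cor_q_cpp)
}
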