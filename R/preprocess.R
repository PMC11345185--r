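#' Block-average a channel series
#'
#' Averages samples into non-overlapping, left-aligned, half-open blocks
#' `[k*width, (k+1)*width)`. A block's value is the mean of its non-missing
#' samples; blocks with no valid samples (all `NA`, or no samples at all
#' within the series' span) are `NA`. Output timestamps are the block start
#' times.
#'
#' @param series A `pfr_channel` (tibble with `t`, `v`).
#' @param width Block width in seconds; must be at least the sampling
#'   interval.
#' @return A `pfr_channel` at the new rate `1/width` Hz.
#' @export
block_average <- function(series, width) {
  if (width <= 0) stop("`width` must be > 0", call. = FALSE)
  dt <- stats::median(diff(series$t))
  if (is.finite(dt) && width < dt - 1e-9) {
    stop("`width` is shorter than the sampling interval", call. = FALSE)
  }
  k <- floor(series$t / width)
  valid <- !is.na(series$v)
  sums <- rowsum(ifelse(valid, series$v, 0), k)
  cnts <- rowsum(as.numeric(valid), k)
  k_obs <- as.numeric(rownames(sums))
  k_full <- seq(min(k_obs), max(k_obs))
  v <- rep(NA_real_, length(k_full))
  mu <- sums[, 1L] / cnts[, 1L]          # 0/0 -> NaN for all-NA blocks
  mu[cnts[, 1L] == 0] <- NA_real_
  v[match(k_obs, k_full)] <- mu
  nm <- channel_name(series) %||% "X"
  channel_series(k_full * width, v, nm, units = channel_units(series),
                 rate = 1 / width)
}

#' Cerebral perfusion pressure from ABP and ICP
#'
#' CPP is the difference of the block means, `mean(ABP) - mean(ICP)`, over
#' each block of `width` seconds. A missing block in either input propagates
#' to the output.
#'
#' @param abp,icp `pfr_channel` series with overlapping time support.
#' @param width Averaging block width in seconds.
#' @return A `pfr_channel` named `CPP`, units mmHg.
#' @export
cpp_series <- function(abp, icp, width = 60) {
  a <- block_average(abp, width)
  i <- block_average(icp, width)
  common <- intersect(a$t, i$t)
  if (length(common) == 0L) {
    stop("ABP and ICP have disjoint time supports", call. = FALSE)
  }
  common <- sort(common)
  v <- a$v[match(common, a$t)] - i$v[match(common, i$t)]
  channel_series(common, v, "CPP", rate = 1 / width)
}

# Seconds (integer grid) during which a channel has at least one valid sample.
presence_by_second <- function(ch, t0, t1) {
  grid <- seq(t0, t1 - 1)
  if (is.null(ch)) return(rep(FALSE, length(grid)))
  sec <- floor(ch$t[!is.na(ch$v)])
  grid %in% unique(sec)
}

#' Extract analysis intervals from an epoch
#'
#' Finds the maximal runs over which ABP and ICP are continuously present and
#' every perfusion gap is at most `perf_gap_tol` minutes, then tiles each run
#' left-to-right into non-overlapping intervals of `max_len` minutes, keeping
#' a final shorter interval only if it is at least `min_len` minutes. Runs
#' shorter than `min_len` yield nothing.
#'
#' @param epoch A `pfr_epoch` containing at least ABP, ICP and PERF.
#' @param min_len,max_len Interval length bounds in minutes.
#' @param perf_gap_tol Longest tolerated perfusion gap, minutes.
#' @return A tibble with one row per interval: identifiers, `start`, `end`
#'   (seconds), `duration_min`, the parent epoch's 99.8th-percentile ABP
#'   (`abp_q998`, used by the outlier QC rule), and a `data` list-column of
#'   epoch slices.
#' @export
extract_intervals <- function(epoch, min_len = 100, max_len = 140,
                              perf_gap_tol = 10) {
  for (req in c("ABP", "ICP", "PERF")) {
    if (is.null(epoch_channel(epoch, req))) {
      stop(sprintf("epoch is missing required channel %s", req), call. = FALSE)
    }
  }
  t0 <- floor(min(epoch$t))
  t1 <- ceiling(max(epoch$t)) + 1
  abp_ok <- presence_by_second(epoch_channel(epoch, "ABP"), t0, t1)
  icp_ok <- presence_by_second(epoch_channel(epoch, "ICP"), t0, t1)
  perf_ok <- presence_by_second(epoch_channel(epoch, "PERF"), t0, t1)

  # short perfusion gaps are tolerated
  r <- rle(perf_ok)
  tol_s <- perf_gap_tol * 60
  r$values[!r$values & r$lengths <= tol_s] <- TRUE
  perf_eff <- inverse.rle(r)

  ok <- abp_ok & icp_ok & perf_eff
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1

  abp <- epoch_channel(epoch, "ABP")
  abp_q998 <- stats::quantile(abp$v, 0.998, na.rm = TRUE, names = FALSE)

  out <- list()
  min_s <- min_len * 60
  max_s <- max_len * 60
  for (i in seq_along(runs$lengths)) {
    if (!runs$values[i]) next
    run_start <- t0 + starts[i] - 1
    run_len <- runs$lengths[i]
    if (run_len < min_s) next
    offs <- 0
    while (run_len - offs >= min_s) {
      take <- min(max_s, run_len - offs)
      if (take < min_s) break
      out[[length(out) + 1L]] <- c(run_start + offs, run_start + offs + take)
      offs <- offs + take
    }
  }
  if (length(out) == 0L) {
    return(tibble::tibble(
      interval_id = character(), patient_id = character(),
      epoch_id = character(), start = numeric(), end = numeric(),
      duration_min = numeric(), abp_q998 = numeric(), data = list()
    ))
  }
  pid <- attr(epoch, "patient_id") %||% "P0"
  eid <- attr(epoch, "epoch_id") %||% "E0"
  purrr::imap_dfr(out, function(se, i) {
    slice <- epoch[epoch$t >= se[1] & epoch$t < se[2], , drop = FALSE]
    slice <- rebuild_epoch(slice, epoch)
    tibble::tibble(
      interval_id = sprintf("%s-%s-I%02d", pid, eid, i),
      patient_id = pid, epoch_id = eid,
      start = se[1], end = se[2], duration_min = (se[2] - se[1]) / 60,
      abp_q998 = abp_q998, data = list(slice)
    )
  })
}

#' Quality-control rule configuration
#'
#' Thresholds for the interval screening rules, in the physical units of the
#' signals: perfusion sample ceiling (mL/hg/min), 5-min perfusion mean
#' ceiling, ICP plateau level (mmHg) and maximum tolerated plateau duration
#' (minutes), and the multiplicative factor applied to the epoch-level
#' 99.8th-percentile ABP for the outlier rule.
#'
#' @param perf_max Global perfusion sample ceiling.
#' @param perf_mean_max Ceiling on any 5-min perfusion mean.
#' @param perf_mean_width Width of the perfusion mean window, seconds.
#' @param icp_max ICP plateau threshold, mmHg.
#' @param icp_max_run Longest tolerated continuous exceedance, minutes.
#' @param abp_outlier_factor Factor on the epoch 99.8th percentile above
#'   which an ABP sample is flagged as an outlier.
#' @return A list of class `pfr_qc_rules`.
#' @export
qc_rules <- function(perf_max = 130, perf_mean_max = 95,
                     perf_mean_width = 300,
                     icp_max = 100, icp_max_run = 5,
                     abp_outlier_factor = 1.2) {
  structure(list(perf_max = perf_max, perf_mean_max = perf_mean_max,
                 perf_mean_width = perf_mean_width, icp_max = icp_max,
                 icp_max_run = icp_max_run,
                 abp_outlier_factor = abp_outlier_factor),
            class = "pfr_qc_rules")
}

# contiguous TRUE runs of `flag` over timestamps `t` -> tibble(start, end)
flag_ranges <- function(t, flag) {
  flag[is.na(flag)] <- FALSE
  if (!any(flag)) {
    return(tibble::tibble(start = numeric(), end = numeric()))
  }
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values
  tibble::tibble(start = t[starts[keep]], end = t[ends[keep]])
}

#' Apply quality-control screening to an interval
#'
#' Evaluates the screening rules on an interval's channels and reports every
#' violated rule with the offending time ranges. The rules: (i) any negative
#' ABP sample, or any ABP sample above the epoch-level outlier threshold;
#' (ii) any negative perfusion sample, any sample above the global ceiling,
#' or any 5-min perfusion mean above its ceiling; (iii) any negative ICP
#' sample, or ICP continuously above 100 mmHg for longer than 5 min
#' (evaluated on 1-s averaged ICP, a run being broken by any second at or
#' below threshold). QC never raises on data content.
#'
#' @param interval A `pfr_epoch` slice (e.g. the `data` entry of an
#'   [extract_intervals()] row).
#' @param rules A [qc_rules()] configuration.
#' @param abp_upper Epoch-level 99.8th-percentile ABP; when `NULL` it is
#'   computed from the interval itself.
#' @return A list of class `pfr_qc` with `passed` (logical) and `reasons`
#'   (tibble of `rule`, `start`, `end`). `passed` is `TRUE` iff `reasons` is
#'   empty.
#' @export
qc_filter <- function(interval, rules = qc_rules(), abp_upper = NULL) {
  reasons <- list()
  add <- function(rule, ranges) {
    if (nrow(ranges) > 0L) {
      reasons[[length(reasons) + 1L]] <<-
        dplyr::mutate(ranges, rule = rule, .before = 1L)
    }
  }

  abp <- epoch_channel(interval, "ABP")
  if (!is.null(abp)) {
    add("abp_negative", flag_ranges(abp$t, abp$v < 0))
    thr <- if (is.null(abp_upper)) {
      stats::quantile(abp$v, 0.998, na.rm = TRUE, names = FALSE)
    } else abp_upper
    add("abp_outlier", flag_ranges(abp$t, abp$v > rules$abp_outlier_factor * thr))
  }

  perf <- epoch_channel(interval, "PERF")
  if (!is.null(perf)) {
    add("perf_negative", flag_ranges(perf$t, perf$v < 0))
    add("perf_above_max", flag_ranges(perf$t, perf$v > rules$perf_max))
    pm <- block_average(perf, rules$perf_mean_width)
    bad <- !is.na(pm$v) & pm$v > rules$perf_mean_max
    if (any(bad)) {
      add("perf_high_5min_mean",
          tibble::tibble(start = pm$t[bad], end = pm$t[bad] + rules$perf_mean_width))
    }
  }

  icp <- epoch_channel(interval, "ICP")
  if (!is.null(icp)) {
    add("icp_negative", flag_ranges(icp$t, icp$v < 0))
    icp1 <- block_average(icp, 1)
    over <- !is.na(icp1$v) & icp1$v > rules$icp_max
    rr <- flag_ranges(icp1$t, over)
    rr <- rr[rr$end - rr$start + 1 > rules$icp_max_run * 60, , drop = FALSE]
    add("icp_plateau", rr)
  }

  reasons <- if (length(reasons)) dplyr::bind_rows(reasons) else {
    tibble::tibble(rule = character(), start = numeric(), end = numeric())
  }
  structure(list(passed = nrow(reasons) == 0L, reasons = reasons),
            class = "pfr_qc")
}

#' @export
print.pfr_qc <- function(x, ...) {
  cat(if (x$passed) "QC: passed\n" else "QC: FAILED\n")
  if (!x$passed) print(x$reasons)
  invisible(x)
}

#' Tidy a quality-control result
#'
#' @param x A `pfr_qc` result.
#' @param ... Unused.
#' @return The tibble of violated rules with their time ranges.
#' @export
tidy.pfr_qc <- function(x, ...) x$reasons
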