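#' Joint (PRx, Mx) kernel densities per regime group
#'
#' Kernel-smoothed densities of pooled per-window (PRx, Mx) points on a
#' common grid over the index support `[-1, 1]^2`, one surface per group,
#' each renormalised to integrate to 1 over the clipped support. The
#' difference surface between the positive regime and the pooled remainder
#' is appended as group `"difference"`.
#'
#' @param cloud Data frame with columns `prx`, `mx`, `group`.
#' @param grid_n Grid resolution per axis.
#' @param bw Optional length-2 bandwidth (PRx, Mx); defaults to the normal
#'   reference rule per coordinate.
#' @param positive Group treated as the positive regime for the difference
#'   surface.
#' @return A tibble of class `pfr_density` with columns `group`, `prx`,
#'   `mx`, `density`.
#' @export
joint_density <- function(cloud, grid_n = 101, bw = NULL, positive = "pPFR") {
  groups <- unique(as.character(cloud$group))
  if (length(groups) == 0L || any(!table(cloud$group) > 0)) {
    stop("every group must be non-empty", call. = FALSE)
  }
  counts <- table(cloud$group)
  if (any(counts < 100)) {
    warning("groups with fewer than 100 points give unstable densities")
  }
  dx <- 2 / (grid_n - 1)
  one_surface <- function(px, mxv) {
    h <- bw %||% c(MASS::bandwidth.nrd(px), MASS::bandwidth.nrd(mxv))
    h[h <= 0] <- 0.1
    kd <- MASS::kde2d(px, mxv, h = h, n = grid_n, lims = c(-1, 1, -1, 1))
    z <- kd$z / (sum(kd$z) * dx * dx)
    tibble::tibble(
      prx = rep(kd$x, times = grid_n),
      mx = rep(kd$y, each = grid_n),
      density = as.vector(z)
    )
  }
  surfaces <- purrr::map_dfr(groups, function(g) {
    sel <- cloud$group == g
    dplyr::mutate(one_surface(cloud$prx[sel], cloud$mx[sel]), group = g,
                  .before = 1L)
  })
  if (positive %in% groups && length(groups) > 1L) {
    pos <- surfaces[surfaces$group == positive, ]
    rest_pts <- cloud[cloud$group != positive, ]
    rest <- one_surface(rest_pts$prx, rest_pts$mx)
    diff_surf <- tibble::tibble(group = "difference", prx = pos$prx,
                                mx = pos$mx,
                                density = pos$density - rest$density)
    surfaces <- dplyr::bind_rows(surfaces, diff_surf)
  }
  class(surfaces) <- c("pfr_density", class(surfaces))
  surfaces
}

ks_tail <- function(lambda) {
  if (lambda < 1e-8) return(1)
  j <- 1:101
  p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample two-dimensional Kolmogorov-Smirnov test
#'
#' Quadrant-based two-sample statistic in the Fasano-Franceschini
#' construction: with every data point of either sample taken as origin, the
#' statistic `D` is the largest absolute difference between the two samples'
#' empirical quadrant probabilities over the four quadrant orientations.
#' Significance is assessed by label permutation (default), whose stream is
#' fixed by `seed`; the classical asymptotic approximation is available as
#' an alternative.
#'
#' @param a,b Two-column data frames or matrices of points.
#' @param n_perm Number of label permutations (at least 100).
#' @param seed Optional integer fixing the permutation stream.
#' @param method `"permutation"` or `"asymptotic"`.
#' @return A one-row tibble of class `pfr_ks2d`: `statistic`, `p_value`,
#'   `n_a`, `n_b`, `n_perm`, `method`.
#' @export
ks2d_two_sample <- function(a, b, n_perm = 999, seed = NULL,
                            method = c("permutation", "asymptotic")) {
  method <- match.arg(method)
  a <- as.matrix(a)
  b <- as.matrix(b)
  if (ncol(a) != 2L || ncol(b) != 2L) {
    stop("samples must have exactly two columns", call. = FALSE)
  }
  if (nrow(a) < 20L || nrow(b) < 20L) {
    stop("need at least 20 points per sample", call. = FALSE)
  }
  if (method == "permutation") {
    if (n_perm < 100L) stop("n_perm must be at least 100 for a stable p",
                            call. = FALSE)
    run <- function() ks2d_perm_fast_cpp(a[, 1L], a[, 2L], b[, 1L], b[, 2L],
                                         as.integer(n_perm))
    res <- if (is.null(seed)) run() else withr::with_seed(seed, run())
    D <- res$D
    p <- (res$count_ge + 1) / (n_perm + 1)
  } else {
    D <- ks2d_stat_cpp(a[, 1L], a[, 2L], b[, 1L], b[, 2L])
    n_eff <- nrow(a) * nrow(b) / (nrow(a) + nrow(b))
    r2 <- mean(c(stats::cor(a[, 1L], a[, 2L])^2,
                 stats::cor(b[, 1L], b[, 2L])^2), na.rm = TRUE)
    denom <- 1 + sqrt(1 - r2) * (0.25 - 0.75 / sqrt(n_eff))
    p <- ks_tail(sqrt(n_eff) * D / denom)
    n_perm <- NA_integer_
  }
  out <- tibble::tibble(statistic = D, p_value = p,
                        n_a = nrow(a), n_b = nrow(b),
                        n_perm = n_perm, method = method)
  class(out) <- c("pfr_ks2d", class(out))
  out
}

#' Joint-index rule for impaired autoregulation
#'
#' The one-parameter linear discriminant `Mx > c * (1 - PRx)` over the joint
#' (PRx, Mx) plane. With `c = 0` it reduces to the plain `Mx > 0` rule; at
#' `PRx = 0` it reduces to `Mx > c`; the boundary always passes through
#' `(PRx, Mx) = (1, 0)`.
#'
#' @param prx,mx Index values (vectorised).
#' @param c Boundary coefficient (default 0.43).
#' @return Logical: `TRUE` where the point lies in the impaired
#'   (pressure-passive) region.
#' @export
ca_impaired <- function(prx, mx, c = 0.43) {
  mx > c * (1 - prx)
}

#' Fit the joint-index discriminant coefficient
#'
#' Grid search over the boundary family `Mx = c * (1 - PRx)` for the
#' coefficient that best separates the positive regime from the rest,
#' maximising balanced accuracy of the rule `positive <=> Mx > c * (1 -
#' PRx)`; ties break toward the smaller coefficient. An alternative
#' objective integrates the group density difference over the implied
#' region.
#'
#' @param cloud Data frame with columns `prx`, `mx`, `group`.
#' @param positive Group treated as positive.
#' @param c_grid Candidate coefficients.
#' @param method `"balanced_accuracy"` (classification of points) or
#'   `"density_contour"` (integral of the kernel-density difference over the
#'   super-boundary region).
#' @return A list of class `pfr_discriminant`: `c`, `objective`, `method`,
#'   and the full `grid` of scores.
#' @export
fit_discriminant <- function(cloud, positive = "pPFR",
                             c_grid = seq(0, 1, by = 0.01),
                             method = c("balanced_accuracy",
                                        "density_contour")) {
  method <- match.arg(method)
  is_pos <- as.character(cloud$group) == positive
  if (!any(is_pos) || all(is_pos)) {
    stop("need both the positive group and at least one other", call. = FALSE)
  }
  if (method == "balanced_accuracy") {
    scores <- vapply(c_grid, function(cc) {
      pred <- cloud$mx > cc * (1 - cloud$prx)
      (mean(pred[is_pos]) + mean(!pred[!is_pos])) / 2
    }, numeric(1))
  } else {
    dens <- joint_density(cloud, grid_n = 101, positive = positive)
    dsurf <- dens[dens$group == "difference", ]
    scores <- vapply(c_grid, function(cc) {
      above <- dsurf$mx > cc * (1 - dsurf$prx)
      sum(dsurf$density[above])
    }, numeric(1))
    scores <- scores / max(abs(scores))
  }
  best <- which.max(scores)   # first max = smallest c on an ascending grid
  structure(list(c = c_grid[best], objective = scores[best], method = method,
                 grid = tibble::tibble(c = c_grid, score = scores),
                 n_pos = sum(is_pos), n_neg = sum(!is_pos)),
            class = "pfr_discriminant")
}

#' @export
print.pfr_discriminant <- function(x, ...) {
  cat(sprintf("<pfr_discriminant> Mx > %.2f * (1 - PRx); %s = %.3f\n",
              x$c, x$method, x$objective))
  invisible(x)
}

#' Tidy a discriminant fit
#'
#' @param x A `pfr_discriminant`.
#' @param ... Unused.
#' @export
tidy.pfr_discriminant <- function(x, ...) {
  tibble::tibble(term = "c", estimate = x$c, objective = x$objective,
                 method = x$method)
}

#' One-row summary of a discriminant fit
#'
#' @param x A `pfr_discriminant`.
#' @param ... Unused.
#' @export
glance.pfr_discriminant <- function(x, ...) {
  tibble::tibble(c = x$c, objective = x$objective, method = x$method,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Synthetic joint-index cloud around a known discriminant boundary
#'
#' Generates labelled (PRx, Mx) points on either side of the boundary
#' `Mx = c * (1 - PRx)` with a stochastic margin, for discriminant-recovery
#' experiments.
#'
#' @param c_true True boundary coefficient.
#' @param n_pos,n_neg Points per class.
#' @param margin_mean,margin_sd Mean and spread of the distance from the
#'   boundary (in Mx units).
#' @param seed Integer seed.
#' @return Tibble with `prx`, `mx`, `group` (`"pPFR"` / `"nonpPFR"`).
#' @export
simulate_index_cloud <- function(c_true = 0.43, n_pos = 300, n_neg = 300,
                                 margin_mean = 0.15, margin_sd = 0.08,
                                 seed = 1L) {
  withr::with_seed(seed, {
    mk <- function(n, sgn, grp) {
      prx <- stats::runif(n, -0.5, 1)
      margin <- abs(stats::rnorm(n, margin_mean, margin_sd)) + 0.01
      mxv <- c_true * (1 - prx) + sgn * margin
      tibble::tibble(prx = prx, mx = pmin(pmax(mxv, -1), 1), group = grp)
    }
    dplyr::bind_rows(mk(n_pos, 1, "pPFR"), mk(n_neg, -1, "nonpPFR"))
  })
}

#' Compare 1-min variable distributions between regime groups
#'
#' For every variable and every pair of regime groups: the two-sample 1D
#' Kolmogorov-Smirnov statistic and p-value, the two-sample t-test p-value,
#' and group medians with quartiles. Pairs passing the printed thresholds
#' (`ks_p < 0.005`, `t_p < 0.05`) are flagged. Thresholds are applied
#' without correction by default; Bonferroni is available. An optional
#' permutation test on the median difference is provided for readers who
#' want the median claim tested as such.
#'
#' @param data Data frame with columns `variable`, `group`, `value` (long
#'   form, pooled 1-min samples).
#' @param ks_alpha,t_alpha Flagging thresholds.
#' @param p_adjust Multiplicity correction applied to both p-value columns
#'   (`"none"` or any [stats::p.adjust()] method).
#' @param median_test When `TRUE`, adds a label-permutation p-value for the
#'   absolute median difference.
#' @param n_perm Permutations for the median test.
#' @return A tibble, one row per (variable, group pair).
#' @export
group_compare <- function(data, ks_alpha = 0.005, t_alpha = 0.05,
                          p_adjust = "none", median_test = FALSE,
                          n_perm = 999) {
  need <- c("variable", "group", "value")
  if (!all(need %in% names(data))) {
    stop("`data` must have columns variable, group, value", call. = FALSE)
  }
  res <- list()
  for (v in unique(data$variable)) {
    dv <- data[data$variable == v & !is.na(data$value), ]
    groups <- sort(unique(as.character(dv$group)))
    if (length(groups) < 2L) {
      warning(sprintf("variable %s has fewer than 2 non-empty groups; skipped", v))
      next
    }
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq(i + 1L, length(groups))) {
        x <- dv$value[dv$group == groups[i]]
        y <- dv$value[dv$group == groups[j]]
        if (length(x) < 2L || length(y) < 2L) {
          warning(sprintf("empty cell for %s (%s vs %s); omitted",
                          v, groups[i], groups[j]))
          next
        }
        ks <- suppressWarnings(stats::ks.test(x, y))
        tt <- stats::t.test(x, y)
        row <- tibble::tibble(
          variable = v, group1 = groups[i], group2 = groups[j],
          n1 = length(x), n2 = length(y),
          ks_D = unname(ks$statistic), ks_p = ks$p.value,
          t_p = tt$p.value,
          median1 = stats::median(x), q25_1 = stats::quantile(x, 0.25, names = FALSE),
          q75_1 = stats::quantile(x, 0.75, names = FALSE),
          median2 = stats::median(y), q25_2 = stats::quantile(y, 0.25, names = FALSE),
          q75_2 = stats::quantile(y, 0.75, names = FALSE)
        )
        if (median_test) {
          obs <- abs(stats::median(x) - stats::median(y))
          pool <- c(x, y)
          nx <- length(x)
          cnt <- 0L
          for (k in seq_len(n_perm)) {
            idx <- sample.int(length(pool), nx)
            d <- abs(stats::median(pool[idx]) - stats::median(pool[-idx]))
            if (d >= obs - 1e-12) cnt <- cnt + 1L
          }
          row$median_perm_p <- (cnt + 1) / (n_perm + 1)
        }
        res[[length(res) + 1L]] <- row
      }
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0L && p_adjust != "none") {
    out$ks_p <- stats::p.adjust(out$ks_p, method = p_adjust)
    out$t_p <- stats::p.adjust(out$t_p, method = p_adjust)
  }
  if (nrow(out) > 0L) {
    out$ks_flag <- out$ks_p < ks_alpha
    out$t_flag <- out$t_p < t_alpha
  }
  out
}
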