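test_that("joint densities integrate to one and locate mass correctly", {
  set.seed(1)
  cloud <- tibble::tibble(
    prx = c(rnorm(300, 0.5, 0.05), rnorm(300, -0.4, 0.05)),
    mx = c(rnorm(300, 0.6, 0.05), rnorm(300, -0.5, 0.05)),
    group = rep(c("pPFR", "nPFR"), each = 300)
  )
  dens <- joint_density(cloud, grid_n = 81)
  dx <- 2 / 80
  for (g in c("pPFR", "nPFR")) {
    z <- dens$density[dens$group == g]
    expect_equal(sum(z) * dx * dx, 1, tolerance = 1e-6)
    # mode within one cell of the cluster mean
    peak <- dens[dens$group == g, ][which.max(z), ]
    ctr <- if (g == "pPFR") c(0.5, 0.6) else c(-0.4, -0.5)
    expect_lt(abs(peak$prx - ctr[1]), 2 * dx)
    expect_lt(abs(peak$mx - ctr[2]), 2 * dx)
  }
  # difference surface present and signed correctly at the positive mode
  dsurf <- dens[dens$group == "difference", ]
  expect_gt(dsurf$density[which.min((dsurf$prx - 0.5)^2 + (dsurf$mx - 0.6)^2)], 0)

  expect_error(joint_density(cloud[0, ]), "non-empty")
  expect_warning(joint_density(tibble::tibble(prx = rnorm(30), mx = rnorm(30),
                                              group = "pPFR")),
                 "fewer than 100")
})

test_that("the quadrant statistic vanishes on identical samples", {
  set.seed(2)
  a <- cbind(stats::rnorm(30), stats::rnorm(30))
  expect_equal(icpfr:::ks2d_stat_cpp(a[, 1], a[, 2], a[, 1], a[, 2]), 0)
})

test_that("fast sweep and quadratic scan agree on tie-free data", {
  for (s in 1:10) {
    set.seed(s)
    a <- cbind(stats::rnorm(40), stats::rnorm(40))
    b <- cbind(stats::rnorm(55, 0.3), stats::rnorm(55))
    slow <- icpfr:::ks2d_stat_cpp(a[, 1], a[, 2], b[, 1], b[, 2])
    fast <- withr::with_seed(1, icpfr:::ks2d_perm_fast_cpp(
      a[, 1], a[, 2], b[, 1], b[, 2], 100L))$D
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("separated clouds are detected at the permutation floor", {
  # index-scale clouds displaced by 2 units in the Mx coordinate
  set.seed(3)
  a <- cbind(stats::runif(100, -1, 1), stats::runif(100, -1, -0.5))
  b <- cbind(stats::runif(100, -1, 1), stats::runif(100, -1, -0.5) + 2)
  r <- ks2d_two_sample(a, b, n_perm = 999, seed = 4)
  expect_gt(r$statistic, 0.9)
  expect_lte(r$p_value, 1 / 1000 + 1e-12)
})

test_that("the statistic is invariant under monotone coordinate transforms", {
  set.seed(5)
  a <- cbind(stats::rnorm(60), stats::rnorm(60))
  b <- cbind(stats::rnorm(60, 0.5), stats::rnorm(60))
  d0 <- icpfr:::ks2d_stat_cpp(a[, 1], a[, 2], b[, 1], b[, 2])
  # same strictly increasing map applied to one coordinate of both samples
  d1 <- icpfr:::ks2d_stat_cpp(exp(a[, 1]), a[, 2], exp(b[, 1]), b[, 2])
  expect_equal(d0, d1, tolerance = 1e-12)
})

test_that("degenerate 2D KS inputs are refused", {
  a <- cbind(stats::rnorm(30), stats::rnorm(30))
  expect_error(ks2d_two_sample(a[1:10, ], a), "at least 20")
  expect_error(ks2d_two_sample(a, a, n_perm = 50), "at least 100")
  expect_error(ks2d_two_sample(cbind(1:30), a), "two columns")
})

test_that("the joint-index impairment rule and its limits are exact", {
  expect_true(ca_impaired(0, 0.5))            # 0.5 > 0.43
  expect_false(ca_impaired(0.3, 0.3))         # 0.43 * 0.7 = 0.301 >= 0.3
  expect_true(ca_impaired(1, 0.01))           # boundary height zero at PRx=1
  # c = 0 reduces to mx > 0; prx = 0 reduces to mx > c
  set.seed(6)
  prxv <- runif(50, -1, 1)
  mxv <- runif(50, -1, 1)
  expect_equal(ca_impaired(prxv, mxv, c = 0), mxv > 0)
  expect_equal(ca_impaired(0, mxv, c = 0.43), mxv > 0.43)
})

test_that("discriminant fitting recovers a planted boundary", {
  for (s in 1:5) {
    cl <- simulate_index_cloud(0.43, seed = s)
    fd <- fit_discriminant(cl)
    expect_lte(abs(fd$c - 0.43), 0.05)
    expect_equal(fd$objective, 1)  # margin construction is separable
  }
  # shuffled labels: no better than chance, roughly
  cl <- simulate_index_cloud(0.43, seed = 99)
  cl$group <- withr::with_seed(1, sample(cl$group))
  fd0 <- fit_discriminant(cl)
  expect_lt(fd0$objective, 0.62)

  expect_error(fit_discriminant(dplyr::mutate(cl, group = "pPFR")),
               "both")
})

test_that("discriminant is insensitive to class prevalence when separable", {
  cl <- simulate_index_cloud(0.43, n_pos = 400, n_neg = 400, seed = 7)
  pos <- cl[cl$group == "pPFR", ]
  neg <- cl[cl$group != "pPFR", ]
  balanced <- fit_discriminant(dplyr::bind_rows(pos, neg))
  skewed <- fit_discriminant(dplyr::bind_rows(pos[1:80, ], neg))
  expect_lte(abs(balanced$c - skewed$c), 0.02)
})

test_that("the density-contour objective lands near the classification fit", {
  cl <- simulate_index_cloud(0.43, n_pos = 500, n_neg = 500, seed = 8)
  fd <- fit_discriminant(cl, method = "density_contour")
  expect_lte(abs(fd$c - 0.43), 0.1)
})

test_that("group comparisons flag planted separations and not identity", {
  set.seed(9)
  ident <- tibble::tibble(
    variable = "icp",
    group = rep(c("pPFR", "zPFR"), each = 300),
    value = stats::rnorm(600, 12, 3)
  )
  r0 <- group_compare(ident)
  expect_false(r0$ks_flag)
  expect_false(r0$t_flag)

  shifted <- ident
  shifted$value[shifted$group == "zPFR"] <-
    shifted$value[shifted$group == "zPFR"] + 3
  r1 <- group_compare(shifted)
  expect_true(r1$ks_flag)
  expect_true(r1$t_flag)
  expect_equal(r1$median2 - r1$median1, 3, tolerance = 0.5)

  # three groups -> three pairs per variable
  tri <- tibble::tibble(variable = "hr",
                        group = rep(c("a", "b", "c"), each = 50),
                        value = stats::rnorm(150))
  expect_equal(nrow(suppressWarnings(group_compare(tri))), 3L)
})

test_that("location-shifted groups are flagged in nearly all replicates", {
  set.seed(10)
  hits <- replicate(60, {
    df <- tibble::tibble(
      variable = "v",
      group = rep(c("g1", "g2"), each = 500),
      value = c(stats::rnorm(500), stats::rnorm(500, 1))
    )
    r <- group_compare(df)
    r$ks_flag && r$t_flag
  })
  expect_gte(mean(hits), 0.99)
})

test_that("the 1D KS statistic equals the brute-force ECDF gap", {
  # integer-valued toy inputs, exact comparison
  x <- c(1L, 2L, 2L, 3L, 5L, 7L)
  y <- c(2L, 4L, 4L, 6L)
  grid <- sort(unique(c(x, y)))
  gap <- max(abs(stats::ecdf(x)(grid) - stats::ecdf(y)(grid)))
  df <- tibble::tibble(variable = "v",
                       group = rep(c("a", "b"), c(length(x), length(y))),
                       value = c(x, y))
  expect_equal(group_compare(df)$ks_D, gap)
})

test_that("the optional median permutation test behaves", {
  set.seed(11)
  df <- tibble::tibble(
    variable = "v",
    group = rep(c("a", "b"), each = 80),
    value = c(stats::rnorm(80), stats::rnorm(80, 2))
  )
  r <- group_compare(df, median_test = TRUE, n_perm = 199)
  expect_lt(r$median_perm_p, 0.05)
})
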