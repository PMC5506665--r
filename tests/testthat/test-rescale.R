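test_that("outlier-bin selection takes the top k with deterministic tie-breaks", {
  cov <- make_cov(c(5, 1, 9))
  sel <- select_outlier_bins(cov, 2)
  expect_equal(sel$bin, c(1, 3))
  expect_equal(sel$value, c(5, 9))

  ties <- make_cov(rep(2, 6))
  expect_equal(select_outlier_bins(ties, 3)$bin, 1:3)

  expect_error(select_outlier_bins(cov, 4), "exceeds")
  expect_error(select_outlier_bins(make_cov(c(3, 0, 0)), 2), "positive coverage")
})

test_that("fold-change distribution matches hand arithmetic and drops zero bins", {
  u <- make_cov(c(100, 90, 80))
  t_ <- make_cov(c(200, 171, 168))
  sel <- select_outlier_bins(u, 3)
  fcs <- fold_change_distribution(t_, u, sel)
  expect_equal(sort(fcs$fc), c(1.9, 2.0, 2.1))
  expect_equal(median(fcs$fc), 2.0)
  expect_equal(attr(fcs, "n_used"), 3)

  # identity and uniform scaling
  expect_equal(fold_change_distribution(u, u, sel)$fc, rep(1, 3))
  half <- u; half$value <- u$value * 2
  expect_equal(median(fold_change_distribution(half, u, sel)$fc), 2)

  # zero-coverage bins are excluded and counted, not pseudocounted
  tz <- t_; tz$value[2] <- 0
  fcs2 <- fold_change_distribution(tz, u, sel)
  expect_equal(attr(fcs2, "n_used"), 2)
  expect_equal(attr(fcs2, "n_dropped"), 1)
  expect_error(
    fold_change_distribution(make_cov(c(0, 0, 0)), u, sel),
    "zero coverage"
  )
  expect_error(fold_change_distribution(make_cov(c(1, 2)), u, sel), "grid")
})

test_that("scaling factor is the reciprocal median fold change", {
  u <- make_cov(c(10, 50, 3, 80, 20, 1))
  fit_id <- estimate_scaling(u, u, k = 4)
  expect_equal(fit_id$factor, 1)

  doubled <- u; doubled$value <- u$value * 2
  fit2 <- estimate_scaling(doubled, u, k = 4)
  expect_equal(fit2$factor, 0.5)
  expect_equal(fit2$factor * fit2$median_fc, 1, tolerance = 1e-12)

  g <- glance(fit2)
  expect_equal(g$factor, 0.5)
  expect_equal(g$k, 4)
  expect_equal(nrow(tidy(fit2)), 4)
})

test_that("the estimator is exactly scale-equivariant and monotone in treated signal", {
  set.seed(7)
  u <- make_cov(rexp(200, 1 / 10) + 0.1)
  t_ <- make_cov(rexp(200, 1 / 10) + 0.1)
  base <- estimate_scaling(t_, u, k = 50)
  for (c_ in c(0.25, 2, 17.3)) {
    scaled <- t_; scaled$value <- t_$value * c_
    expect_equal(estimate_scaling(scaled, u, k = 50)$factor, base$factor / c_,
                 tolerance = 1e-12)
  }
  # raising every treated value at the outlier bins strictly lowers the factor
  up <- t_; up$value <- t_$value * 1.3
  expect_lt(estimate_scaling(up, u, k = 50)$factor, base$factor)
})

test_that("rescaling by the estimated factor self-normalizes the outlier median", {
  set.seed(8)
  for (i in 1:5) {
    u <- make_cov(rexp(300, 1 / 5) + 0.05)
    t_ <- make_cov((rexp(300, 1 / 5) + 0.05) * runif(1, 0.3, 3))
    fit <- estimate_scaling(t_, u, k = 100)
    sel <- select_outlier_bins(u, 100)
    renorm <- fold_change_distribution(scale_coverage(t_, fit$factor), u, sel)
    expect_equal(median(renorm$fc), 1, tolerance = 1e-9)
  }
})

test_that("scale_coverage applies and composes multiplicatively", {
  cov <- make_cov(c(1, 2, 0, 4.5))
  expect_equal(scale_coverage(cov, 1), cov)
  expect_equal(scale_coverage(scale_coverage(cov, 0.5), 2)$value, cov$value)
  expect_equal(scale_coverage(make_cov(rep(1, 3)), 0.57)$value, rep(0.57, 3))
  expect_equal(coverage_total_bases(scale_coverage(cov, 0.57)),
               0.57 * coverage_total_bases(cov))
  expect_error(scale_coverage(cov, 0), "positive")
  expect_error(scale_coverage(cov, -1), "positive")
})

test_that("k sweep is flat under exact proportionality and handles a single k", {
  u <- make_cov(rexp(400, 1 / 5) + 0.05)
  t_ <- u; t_$value <- u$value * 1.6
  sw <- sweep_outlier_k(t_, u, k_values = c(10, 50, 100, 200))
  expect_equal(sw$factor, rep(1 / 1.6, 4), tolerance = 1e-12)
  expect_equal(glance(sw)$relative_spread, 0, tolerance = 1e-12)

  one <- sweep_outlier_k(t_, u, k_values = 25)
  expect_equal(nrow(one), 1)
  expect_equal(glance(one)$relative_spread, 0)
  expect_error(sweep_outlier_k(t_, u, k_values = numeric()), "non-empty")
  expect_error(sweep_outlier_k(t_, u, k_values = c(10, 1e6)), "exceeds")
})

test_that("input consistency is exact under exact depth-only proportionality", {
  set.seed(9)
  u <- make_cov(rexp(300, 1 / 5) + 0.05)
  t_ <- u; t_$value <- u$value * 1.3
  sel <- select_outlier_bins(u, 50)
  rep_ <- check_input_consistency(t_, u, sel, log2_tol = 0.1)
  expect_equal(rep_$total_fc, 1.3, tolerance = 1e-12)
  expect_equal(rep_$outlier_median_fc, 1.3, tolerance = 1e-12)
  expect_equal(rep_$abs_log2_gap, 0, tolerance = 1e-12)
  expect_true(rep_$consistent)
  zero <- make_cov(rep(0, 300))
  expect_error(check_input_consistency(zero, u, sel), "zero total")
})
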