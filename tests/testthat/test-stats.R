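test_that("pooled t-test matches hand computation", {
  r <- student_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$t, -sqrt(3 / 2))
  expect_equal(r$df, 4L)
  expect_equal(r$mean_diff, -1)
  same <- student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(student_t(rnorm(9), rnorm(10))$df, 17L)
  expect_error(student_t(c(1, 1), c(1, 1)), "pooled variance")
  # cross-check against the base implementation
  x <- c(5.1, 4.2, 6.3, 5.5)
  y <- c(4.0, 4.8, 5.2)
  expect_equal(student_t(x, y)$t,
               unname(t.test(x, y, var.equal = TRUE)$statistic))
})

test_that("Hedges' g applies the small-sample corrected formula", {
  j <- 1 - 3 / (4 * 19 - 9)
  expect_equal(hedges_g(-0.229, 9, 10), j * 0.229 * sqrt(1 / 9 + 1 / 10))
  expect_lt(abs(hedges_g(0.042, 9, 10) - 0.018), 5e-4)
  expect_equal(hedges_g(0, 9, 10), 0)
  expect_gte(hedges_g(-2, 9, 10), 0)  # reported as a magnitude
})

test_that("Pearson correlation matches hand values and errors on degenerate input", {
  expect_equal(pearson_r(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_r(1:10, -(1:10)), -1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(rep(1, 5), 1:5), "variance")
})

test_that("BH adjustment matches the step-up closed form and stats::p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(13)
  for (i in 1:100) {
    p <- runif(sample(1:20, 1))^sample(1:3, 1)
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    # nondecreasing in the sorted order
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cohen's f2 reproduces the variance-explained table", {
  expect_equal(cohens_f2(0), 0)
  # printed (variance %, f2) pairs from the study's regression blocks
  pairs <- rbind(c(30.00, 0.429), c(31.50, 0.460), c(42.80, 0.748),
                 c(44.20, 0.792), c(68.00, 2.125), c(65.90, 1.933),
                 c(45.20, 0.825), c(47.90, 0.919))
  for (i in seq_len(nrow(pairs))) {
    expect_equal(round(cohens_f2(pairs[i, 1] / 100), 3), pairs[i, 2])
  }
  # incremental form
  expect_equal(cohens_f2(0.5, 0.3), 0.4)
  expect_error(cohens_f2(1), "\\[0, 1\\)")
})

test_that("BCa interval handles degenerate and symmetric reduction cases", {
  expect_warning(ci <- bca_ci(mean, rep(2, 10), B = 200, seed = 1),
                 "degenerate")
  expect_equal(as.numeric(ci), c(2, 2))

  # with z0 = 0 and a = 0 the BCa endpoints equal the plain percentile ones
  bs <- list(theta_hat = 0, t_boot = seq(-1, 1, length.out = 2001), B = 2001,
             jack = rep(0, 20))
  ci2 <- aptemporal:::bca_from_boot(bs, 0.95)
  expect_equal(unname(ci2),
               unname(quantile(bs$t_boot, c(0.025, 0.975), type = 6)),
               tolerance = 1e-10)
})

test_that("BCa intervals are deterministic under seed and shrink-stable in B", {
  x <- rnorm(25, 1, 2)
  a <- bca_ci(mean, x, B = 500, seed = 4)
  b <- bca_ci(mean, x, B = 500, seed = 4)
  expect_identical(a, b)
  wide <- bca_ci(mean, x, B = 4000, seed = 4)
  expect_equal(as.numeric(a), as.numeric(wide), tolerance = 0.15)
})

test_that("BCa agrees with the boot package on the same statistic", {
  skip_if_not_installed("boot")
  set.seed(5)
  x <- rexp(30)
  ours <- bca_ci(mean, x, B = 4000, seed = 6)
  bt <- boot::boot(x, function(d, i) mean(d[i]), R = 4000)
  ref <- boot::boot.ci(bt, type = "bca")$bca[4:5]
  expect_equal(as.numeric(ours), as.numeric(ref), tolerance = 0.05)
})

test_that("CI-inversion p-values are consistent with the 95% interval decision", {
  set.seed(7)
  for (i in 1:60) {
    x <- rnorm(12, mean = runif(1, -1, 1))
    p <- suppressWarnings(
      p_from_ci_inversion(mean, x, null_value = 0, B = 400, seed = i))
    ci <- bca_ci(mean, x, B = 400, seed = i)
    excluded <- 0 < ci[1] || 0 > ci[2]
    expect_equal(p < 0.05, excluded)
  }
  # null at the point estimate -> p near 1
  set.seed(8)
  x <- rnorm(30)
  p1 <- p_from_ci_inversion(mean, x, null_value = mean(x), B = 400, seed = 9)
  expect_gte(p1, 0.9)
  # bootstrap distribution entirely above the null -> p bounded by 2/B
  y <- rnorm(20, mean = 50)
  expect_warning(
    p0 <- p_from_ci_inversion(mean, y, null_value = 0, B = 400, seed = 10),
    "bounded below")
  expect_equal(p0, 2 / 400)
})
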