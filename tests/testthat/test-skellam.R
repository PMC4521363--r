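test_that("Skellam pmf matches the Poisson-convolution oracle", {
  k <- -60:60
  for (p in list(c(1, 1), c(5, 2), c(0.5, 3), c(50, 5), c(30, 30))) {
    expect_equal(dskellam(k, p[1], p[2]),
                 skellam_pmf_conv(k, p[1], p[2]),
                 tolerance = 1e-12)
  }
})

test_that("Skellam pmf normalizes and is symmetric for equal rates", {
  for (lam in c(0.5, 1, 5, 50)) {
    C <- ceiling(2 * lam + 10 * sqrt(2 * lam + 1))
    k <- -C:C
    expect_lt(abs(sum(dskellam(k, lam, lam)) - 1), 1e-8)
    expect_equal(dskellam(k, lam, lam), dskellam(-k, lam, lam))
  }
})

test_that("degenerate rates reduce to point mass / Poisson limits", {
  expect_identical(dskellam(0, 0, 0), 1)
  expect_identical(dskellam(c(-2, 1), 0, 0), c(0, 0))
  expect_equal(dskellam(0:10, 3, 0), dpois(0:10, 3))
  expect_identical(dskellam(-1, 2, 0), 0)
  expect_equal(dskellam(-(0:10), 0, 4), dpois(0:10, 4))
  expect_error(dskellam(0, -1, 2), "non-negative")
})

test_that("folded pmf folds correctly and normalizes", {
  y <- 0:80
  expect_equal(dfskellam(y, 3, 7), folded_pmf_conv(y, 3, 7),
               tolerance = 1e-12)
  expect_identical(dfskellam(0, 1, 1), dskellam(0, 1, 1))
  expect_equal(dfskellam(3, 4, 4), 2 * dskellam(3, 4, 4))
  expect_lt(abs(sum(dfskellam(0:200, 40, 25)) - 1), 1e-8)
  expect_error(dfskellam(-1, 1, 1), "support")
})

test_that("fold identity holds to machine precision", {
  y <- 1:100
  for (p in list(c(2, 9), c(66, 66), c(90, 160))) {
    expect_equal(dfskellam(y, p[1], p[2]),
                 dskellam(y, p[1], p[2]) + dskellam(-y, p[1], p[2]),
                 tolerance = 1e-13)
  }
})

test_that("log-likelihood sums log pmf and flags impossible data", {
  expect_identical(fskellam_loglik(0, 0, 0), 0)
  expect_equal(fskellam_loglik(c(0, 0), 1, 1), 2 * log(exp(-2) * besselI(2, 0)),
               tolerance = 1e-10)
  expect_identical(fskellam_loglik(5, 0, 0), -Inf)
  expect_error(fskellam_loglik(numeric(0), 1, 1), "empty")
})

test_that("sampler is reproducible and matches the exact pmf", {
  set.seed(1); a <- rfskellam(100, 3, 5)
  set.seed(1); b <- rfskellam(100, 3, 5)
  expect_identical(a, b)
  expect_true(all(rfskellam(100, 0, 0) == 0))
  set.seed(2)
  y <- rfskellam(1e5, 5, 5)
  emp <- tabulate(y + 1L, nbins = 31) / 1e5
  ex <- dfskellam(0:30, 5, 5)
  mc_se <- sqrt(ex * (1 - ex) / 1e5)
  expect_true(all(abs(emp - ex) <= 3.5 * mc_se + 1e-12))
  # moments of the signed variable
  set.seed(3)
  z <- rskellam(1e5, 8, 3)
  expect_lt(abs(mean(z) - 5), 3 * sqrt(11 / 1e5))
  expect_lt(abs(var(z) - 11), 4 * 11 * sqrt(2 / 1e5))
})

test_that("method-of-moments null estimator computes mean(d^2)/2", {
  expect_identical(mom_lambda_null(c(0, 0, 0)), 0)
  expect_equal(mom_lambda_null(c(0, 4, 2)), 10 / 3)
  expect_identical(mom_lambda_null(c(-4, 4)), mom_lambda_null(c(4, 4)))
  expect_error(mom_lambda_null(numeric(0)), "empty")
  set.seed(4)
  d <- rskellam(1e5, 20, 20)
  expect_lt(abs(mom_lambda_null(d) - 20) / 20, 0.01)
})

test_that("chi-square(1) upper tail behaves", {
  expect_identical(chisq1_pvalue(0), 1)
  expect_equal(chisq1_pvalue(3.841459), 0.05, tolerance = 1e-5)
  expect_lt(chisq1_pvalue(214), 1e-5)
  expect_true(all(diff(chisq1_pvalue(c(0, 1, 5, 20))) < 0))
  expect_error(chisq1_pvalue(-1), "non-negative")
})

test_that("LRT helper clamps and converts to p-values", {
  t1 <- fskellam_lrt(-2074, -1967)
  expect_equal(t1$stat, 214)
  expect_lt(t1$p.value, 1e-5)
  t2 <- fskellam_lrt(-17852, -17864)
  expect_identical(t2$stat, 0)
  expect_identical(t2$p.value, 1)
})
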