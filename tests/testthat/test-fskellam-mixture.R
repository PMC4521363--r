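test_that("single-component fits recover rates (up to pair order)", {
  set.seed(1)
  f0 <- fit_fskellam_mixture(rep(0L, 50), 1)
  expect_lt(f0$lambda1 + f0$lambda2, 0.1)
  y <- rfskellam(1e4, 90, 160)
  f <- fit_fskellam_mixture(y, 1)
  got <- sort(c(f$lambda1, f$lambda2))
  expect_lt(max(abs(got - c(90, 160)) / c(90, 160)), 0.05)
  expect_gte(f$lambda1, f$lambda2)          # canonical pair order
})

test_that("two-component recovery and EM monotonicity", {
  set.seed(2)
  y <- c(rfskellam(7000, 5, 5), rfskellam(3000, 90, 160))
  f <- fit_fskellam_mixture(y, 2)
  expect_true(all(diff(f$loglik_trace) > -1e-8))
  expect_lt(abs(f$weights[1] - 0.7), 0.03)
  expect_lt(max(abs(sort(c(f$lambda1[2], f$lambda2[2])) - c(90, 160)) /
                  c(90, 160)), 0.10)
  expect_lt(abs(f$lambda1[1] + f$lambda2[1] - 10) / 10, 0.10)
})

test_that("BIC selection over K and the trivial single-K range", {
  set.seed(3)
  y1 <- rfskellam(3000, 20, 20)
  expect_identical(select_fskellam_k(y1, 1:3, restarts = 3, seed = 1)$K, 1L)
  y2 <- c(rfskellam(2000, 3, 3), rfskellam(1000, 90, 160))
  expect_identical(select_fskellam_k(y2, 1:4, restarts = 3, seed = 2)$K, 2L)
  expect_identical(select_fskellam_k(y2, k_range = 4, seed = 3)$K, 4L)
})

test_that("posterior probabilities normalize and concentrate in the tail", {
  set.seed(4)
  y <- c(rfskellam(2000, 3, 3), rfskellam(500, 90, 160))
  f <- fit_fskellam_mixture(y, 2)
  post <- predict(f, c(0L, 2L, 70L, 90L))
  expect_equal(rowSums(post), rep(1, 4))
  expect_gt(post[3, 2], 0.99)              # deep tail -> wide component
  expect_gt(post[1, 1], 0.9)
  expect_identical(predict(fskmix_object(1, 5, 5), 0:5),
                   matrix(1, 6, 1))
})

test_that("component LRT reproduces published-style worked cases", {
  # the statistic/p-value arithmetic on given log-likelihoods
  expect_equal(fskellam_lrt(-650, -522)$stat, 256)
  expect_lt(fskellam_lrt(-650, -522)$p.value, 1e-5)
  # full path: clear imbalance is detected, a symmetric fit is not
  set.seed(5)
  y <- c(rfskellam(3000, 4, 4), rfskellam(500, 93, 166))
  f <- fit_fskellam_mixture(y, 2)
  tst <- lrt_equal_means(f, y)
  wide <- which.max(abs(f$lambda1 - f$lambda2))
  expect_true(tst$tested[wide])
  expect_lt(tst$pvalue[wide], 1e-6)
  expect_gt(tst$pvalue[-wide], 0.001)
  expect_true(all(tst$stat[tst$tested] >= 0))
})

test_that("small components are not tested (NA, per the min_test_n rule)", {
  set.seed(6)
  y <- c(rfskellam(500, 3, 3), rfskellam(4, 200, 60))
  f <- fskmix_object(c(0.99, 0.01), c(3.1, 200), c(3.0, 60))
  tst <- lrt_equal_means(f, y, min_test_n = 10)
  expect_false(tst$tested[2])
  expect_true(is.na(tst$pvalue[2]))
  expect_true(tst$tested[1])
})

test_that("signal designation follows the LRT + inheritance + reference rule", {
  # six-component configuration: weights/rates as in a fitted brain 3'UTR
  # model; components 2 and 4 significant, 3 and 5 untested with larger
  # gaps, 1 and 6 near-symmetric
  m <- fskmix_object(c(0.54, 0.1, 0.0065, 0.037, 0.0003, 0.3),
                     c(65.7, 83.8, 268, 92.7, 214.8, 4.81),
                     c(69.2, 106, 80.3, 166.0, 78.1, 5.39))
  tests <- data.frame(component = 1:6,
                      pvalue = c(1, 1e-6, NA, 1e-6, NA, 1),
                      tested = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  expect_identical(designate_signal_components(m, tests), c(2L, 3L, 4L, 5L))
  # no significant LRT -> empty signal set
  tests0 <- transform(tests, pvalue = ifelse(tested, 1, NA))
  expect_identical(designate_signal_components(m, tests0), integer(0))
  # untested component with a gap smaller than every significant gap is out
  m2 <- fskmix_object(c(0.5, 0.3, 0.2), c(5, 90, 30), c(5, 160, 25))
  t2 <- data.frame(component = 1:3, pvalue = c(1, 1e-8, NA),
                   tested = c(TRUE, TRUE, FALSE))
  expect_identical(designate_signal_components(m2, t2), 2L)
  # the smallest-gap component is the no-signal reference even if its
  # test rejects
  t3 <- data.frame(component = 1:3, pvalue = c(1e-4, 1e-8, NA),
                   tested = c(TRUE, TRUE, FALSE))
  expect_identical(designate_signal_components(m2, t3), 2L)
})

test_that("SNP classification rules and tiers", {
  m <- fskmix_object(c(0.7, 0.3), c(4, 90), c(4, 160))
  y <- c(0L, 1L, 70L, 200L)
  cls <- classify_snps(m, y, signal = 2L, rule = "max_prob")
  expect_identical(cls$designation[3:4], c("AEI", "AEI"))
  expect_identical(cls$designation[1], "no_AEI")
  expect_true(all(cls$signal_prob >= 0 & cls$signal_prob <= 1))
  expect_identical(cls$tier[cls$signal_prob > 0.99], rep("p99", 2))
  # threshold rule: 0.75 aggregated probability misses an 0.80 cutoff
  ylow <- 9L
  p <- predict(m, ylow)[, 2]
  skip_if_not(p > 0.05 && p < 0.8)          # guard the construction
  ct <- classify_snps(m, ylow, signal = 2L, rule = "threshold",
                      threshold = 0.8)
  expect_identical(ct$designation, "uncertain")
  # empty signal set -> everything no_AEI with zero probability
  c0 <- classify_snps(m, y, signal = integer(0))
  expect_true(all(c0$designation == "no_AEI"))
  expect_true(all(c0$signal_prob == 0))
})

test_that("K exceeding the distinct-value count errors", {
  expect_error(fit_fskellam_mixture(c(0L, 0L, 1L), 3), "distinct")
})

test_that("simulate() from a fitted mixture is reproducible and labelled", {
  m <- fskmix_object(c(0.6, 0.4), c(3, 90), c(3, 160))
  s1 <- simulate(m, 200, seed = 7)
  s2 <- simulate(m, 200, seed = 7)
  expect_identical(s1, s2)
  expect_true(all(s1$component %in% 1:2))
  expect_true(all(s1$y >= 0))
})
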