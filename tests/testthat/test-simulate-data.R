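test_that("the generator is reproducible and schema-complete", {
  cfg <- sim_config(n_subjects = 2, tissues_per_subject = 2, n_genes = 10)
  s1 <- simulate_aei_counts(cfg, seed = 5)
  s2 <- simulate_aei_counts(cfg, seed = 5)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth, s2$truth)
  expect_true(all(c("subject", "tissue", "gene", "snp", "region",
                    "ref_count", "var_count") %in% names(s1$counts)))
  expect_true(all(s1$counts$ref_count >= 0 & s1$counts$var_count >= 0))
  s3 <- simulate_aei_counts(cfg, seed = 6)
  expect_false(identical(s1$counts, s3$counts))
})

test_that("the SNP-per-gene law puts ~78% of genes at 4 SNPs or fewer", {
  set.seed(1)
  n <- 1 + rgeom(2e4, 0.315)
  expect_lt(abs(mean(n <= 4) - 0.78), 0.01)
})

test_that("a symmetric null gives balanced alleles", {
  cfg <- sim_config(n_subjects = 4, tissues_per_subject = 4, n_genes = 40,
                    aei_fraction = 0, z_family = "none", library_sdlog = 0)
  s <- simulate_aei_counts(cfg, seed = 7)
  n <- nrow(s$counts)
  se <- sd(s$counts$ref_count - s$counts$var_count) / sqrt(n)
  expect_lt(abs(mean(s$counts$ref_count) - mean(s$counts$var_count)), 3 * se)
})

test_that("the shared component drives the allele-read correlation", {
  cfg_hi <- sim_config(n_subjects = 4, tissues_per_subject = 4, n_genes = 60,
                       aei_fraction = 0, coverage_weights = 1,
                       coverage_totals = 30, z_intensity = 0.92,
                       library_sdlog = 0)
  s_hi <- simulate_aei_counts(cfg_hi, seed = 8)
  expect_gt(cor(s_hi$counts$ref_count, s_hi$counts$var_count), 0.8)
  cfg_no <- sim_config(n_subjects = 4, tissues_per_subject = 4, n_genes = 60,
                       aei_fraction = 0, coverage_weights = 1,
                       coverage_totals = 30, z_family = "none",
                       library_sdlog = 0)
  s_no <- simulate_aei_counts(cfg_no, seed = 8)
  expect_lt(abs(cor(s_no$counts$ref_count, s_no$counts$var_count)), 0.15)
})

test_that("the read-difference law is invariant to the shared component", {
  base <- list(n_subjects = 4, tissues_per_subject = 4, n_genes = 60,
               aei_fraction = 0, coverage_weights = 1, coverage_totals = 24,
               library_sdlog = 0)
  # same Y rates (same z_intensity), very different Z laws: the difference
  # P - M = Y1 - Y2 must follow the same folded law either way
  s0 <- simulate_aei_counts(
    do.call(sim_config, c(base, list(z_intensity = 0.92,
                                     z_family = "poisson"))), seed = 9)
  sz <- simulate_aei_counts(
    do.call(sim_config, c(base, list(z_intensity = 0.92,
                                     z_family = "overdispersed",
                                     z_shape = 2))), seed = 10)
  d0 <- abs(s0$counts$ref_count - s0$counts$var_count)
  dz <- abs(sz$counts$ref_count - sz$counts$var_count)
  # same folded law despite very different Z: compare binned frequencies
  br <- c(-0.5, 0.5, 1.5, 2.5, Inf)
  t0 <- table(cut(d0, br)); tz <- table(cut(dz, br))
  p <- suppressWarnings(chisq.test(rbind(t0, tz))$p.value)
  expect_gt(p, 0.001)
  expect_lt(abs(mean(d0) - mean(dz)) / max(mean(d0), 0.1), 0.25)
})

test_that("truth_eval counts confusion correctly", {
  truth <- data.frame(subject = "S", tissue = "T", gene = "g",
                      snp = paste0("rs", 1:6), rho = c(1, 1, 1, 3, 3, 3),
                      lambda_p = 1, lambda_m = 1, z_rate = 0,
                      aei_label = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  calls <- data.frame(subject = "S", tissue = "T", gene = "g",
                      snp = paste0("rs", 1:6),
                      designation = c("no_AEI", "no_AEI", "AEI",
                                      "AEI", "AEI", "no_AEI"))
  ev <- truth_eval(calls, truth)
  expect_identical(ev$overall$tp, 2L)
  expect_identical(ev$overall$fp, 1L)
  expect_equal(ev$overall$sensitivity, 2 / 3)
  expect_equal(ev$overall$fdr, 1 / 3)
  # perfect calls
  calls2 <- transform(calls,
                      designation = ifelse(truth$aei_label, "AEI", "no_AEI"))
  ev2 <- truth_eval(calls2, truth)
  expect_equal(ev2$overall$sensitivity, 1)
  expect_equal(ev2$overall$specificity, 1)
  # all-negative calls
  calls3 <- transform(calls, designation = "no_AEI")
  ev3 <- truth_eval(calls3, truth)
  expect_equal(ev3$overall$sensitivity, 0)
  expect_equal(ev3$overall$specificity, 1)
  # SNPs missing from the calls count as negatives
  ev4 <- truth_eval(calls2[1:4, ], truth)
  expect_identical(ev4$overall$fn, 2L)
  # unknown keys error
  calls5 <- calls; calls5$snp[1] <- "rs99"
  expect_error(truth_eval(calls5, truth), "absent")
})
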