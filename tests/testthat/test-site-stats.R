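# Conversion QC, DMC and DVC statistics against independent oracles,
# overlap significance, BER classification, and top-variable clustering.

test_that("conversion control QC passes, fails or is indeterminate", {
  region <- gr_interval("chrS", 0, 450)
  s_hi <- sample_from_betas(rep(0.95, 5), cov = 20L)
  expect_equal(qc_conversion_control(s_hi, region, 0.8), "pass")
  s_lo <- sample_from_betas(rep(0.3, 5), cov = 20L)
  expect_equal(qc_conversion_control(s_lo, region, 0.8), "fail")
  empty_region <- gr_interval("chrS", 10000, 10100)
  expect_equal(
    qc_conversion_control(s_hi, empty_region, 0.8), "indeterminate"
  )
})

test_that("DMC likelihood-ratio statistic matches a glm oracle", {
  set.seed(7)
  B <- matrix(rbeta(5 * 6, 2, 2), 5, 6)
  samples <- cohort_from_beta_matrix(
    B, rep(c("RA", "OA"), each = 3),
    cov = 20L
  )
  res <- test_dmc(samples, min_cov = 1)
  for (i in seq_len(5)) {
    meth <- round(B[i, ] * 20)
    grp <- factor(rep(c("RA", "OA"), each = 3))
    fit1 <- glm(cbind(meth, 20 - meth) ~ grp, family = binomial())
    fit0 <- glm(cbind(meth, 20 - meth) ~ 1, family = binomial())
    p_oracle <- pchisq(
      fit0$deviance - fit1$deviance, 1,
      lower.tail = FALSE
    )
    expect_equal(res$p_dmc[i], p_oracle, tolerance = 1e-9)
  }
})

test_that("DMC rules combine effect size and Bonferroni significance", {
  # clear separation: diff = 1 at high counts
  B <- cbind(matrix(1, 4, 3), matrix(0, 4, 3))
  B <- rbind(B, 0.5) # one null site to keep variety
  samples <- cohort_from_beta_matrix(B, rep(c("RA", "OA"), each = 3),
    cov = 10L
  )
  res <- test_dmc(samples, min_cov = 1)
  expect_equal(res$diff[1], 1)
  expect_true(res$is_dmc[1])
  expect_equal(res$direction[1], "hyper")
  expect_false(res$is_dmc[5])
  expect_equal(res$diff[5], 0)
  expect_equal(attr(res, "bonferroni"), 0.05 / 5)
  expect_error(
    test_dmc(list(samples[[1]], samples[[4]])), "at least 2"
  )
})

test_that("a small p with sub-threshold effect is not a DMC", {
  # diff 0.15 with very deep coverage: p is tiny but the effect rule fails
  B <- matrix(c(rep(0.50, 3), rep(0.35, 3)), 1, 6)
  samples <- cohort_from_beta_matrix(B, rep(c("RA", "OA"), each = 3),
    cov = 10000L
  )
  res <- test_dmc(samples, min_cov = 1)
  expect_lt(res$p_dmc[1], 1e-20)
  expect_equal(res$diff[1], 0.15, tolerance = 1e-6)
  expect_false(res$is_dmc[1])
})

test_that("Levene W matches the hand-computed deviation formula", {
  x <- c(0.5, 0.5, 0.5, 0.1, 0.5, 0.9)
  g <- rep(c("RA", "OA"), each = 3)
  # deviations {0,0,0} and {0.4,0,0.4}: brute-force one-way anova on them
  d <- abs(x - ave(x, g, FUN = mean))
  dg <- tapply(d, g, mean)
  ssb <- sum(3 * (dg - mean(d))^2)
  ssw <- sum((d - ave(d, g, FUN = mean))^2)
  W_oracle <- (4 / 1) * ssb / ssw
  lw <- methylscape:::levene_w(x, g)
  expect_equal(lw$W, W_oracle, tolerance = 1e-10)
  expect_equal(lw$W, 4, tolerance = 1e-10)
  # the cohort-level test reproduces it from counts
  samples <- cohort_from_beta_matrix(matrix(x, 1, 6), g, cov = 10L)
  res <- test_dvc(samples, min_cov = 1)
  expect_equal(res$W[1], W_oracle, tolerance = 1e-10)
})

test_that("degenerate DVC sites are skipped with zero deviations", {
  B <- matrix(0.5, 2, 6)
  samples <- cohort_from_beta_matrix(B, rep(c("RA", "OA"), each = 3),
    cov = 10L
  )
  res <- test_dvc(samples, min_cov = 1)
  expect_true(all(res$skipped))
  expect_true(all(is.na(res$W)))
  expect_false(any(res$is_dvc))
})

test_that("Levene calibration on equal-variance nulls is near nominal", {
  set.seed(11)
  n_sites <- 2000
  B <- matrix(rbeta(n_sites * 20, 5, 5), n_sites, 20)
  g <- rep(c("RA", "OA"), times = c(12, 8))
  ps <- vapply(seq_len(n_sites), function(i) {
    methylscape:::levene_w(B[i, ], g)$p
  }, numeric(1))
  # classic mean-centred Levene runs slightly liberal in small samples;
  # the empirical size must still sit near the nominal 5%
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.09)
})

test_that("Fisher overlap p equals the hypergeometric tail exactly", {
  for (case in list(
    c(U = 100, a = 10, b = 10, k = 10),
    c(U = 100, a = 10, b = 10, k = 1),
    c(U = 200, a = 40, b = 25, k = 12),
    c(U = 150, a = 30, b = 30, k = 6)
  )) {
    ov <- dmc_dvc_overlap_significance(
      seq_len(case["a"]),
      c(seq_len(case["k"]), case["a"] + seq_len(case["b"] - case["k"])),
      universe_size = case["U"], n_perm = 9
    )
    oracle <- sum(dhyper(
      case["k"]:min(case["a"], case["b"]),
      case["a"], case["U"] - case["a"], case["b"]
    ))
    expect_equal(ov$fisher_p, unname(oracle), tolerance = 1e-12)
  }
  expect_error(
    dmc_dvc_overlap_significance(1:5, 6:10, universe_size = 8),
    "universe"
  )
})

test_that("permutation p respects the add-one floor", {
  ov <- dmc_dvc_overlap_significance(
    1:10, 1:10,
    universe_size = 1000, n_perm = 999, seed = 3
  )
  expect_equal(ov$permutation_p, 1 / 1000)
  expect_gte(ov$permutation_p, 1 / (ov$n_permutations + 1))
})

test_that("an overlap at its expectation is unremarkable", {
  # |A||B|/U = 10 expected; observe exactly 10
  a <- seq_len(100)
  b <- c(seq_len(10), 100 + seq_len(90))
  ov <- dmc_dvc_overlap_significance(a, b, universe_size = 1000, n_perm = 99)
  expect_gt(ov$fisher_p, 0.4)
})

test_that("perfectly separating features give zero balanced error rate", {
  set.seed(5)
  B <- rbind(
    matrix(rep(c(0.1, 0.9), times = c(3, 3)), 20, 6, byrow = TRUE),
    matrix(0.5 + rnorm(5 * 6, 0, 0.01), 5, 6)
  )
  samples <- cohort_from_beta_matrix(B, rep(c("RA", "OA"), each = 3),
    cov = 50L
  )
  bb <- balanced_error_classification(
    samples,
    feature_sets = list(sep = 1:20, noise = 21:25),
    min_cov = 1, n_boot = 20, boot_size = 20, n_perm = 49, seed = 2
  )
  expect_equal(unname(bb$ber_point["sep"]), 0)
  expect_true(all(bb$ber[["sep"]] == 0))
  expect_error(
    balanced_error_classification(
      samples, list(empty = integer(0)), min_cov = 1
    ),
    "empty"
  )
})

test_that("permuted labels push the balanced error rate toward one half", {
  set.seed(9)
  B <- matrix(rbeta(50 * 12, 5, 5), 50, 12)
  samples <- cohort_from_beta_matrix(B, rep(c("RA", "OA"), each = 6),
    cov = 30L
  )
  cc <- methylscape:::align_cohort_counts(samples, 1L)
  X <- cc$meth / cc$cov
  bers <- vapply(1:50, function(i) {
    methylscape:::ber_loo(X, sample(cc$groups))
  }, numeric(1))
  expect_lt(abs(mean(bers) - 0.5), 0.1)
})

test_that("top-variable CpG selection is exact with genomic-order ties", {
  set.seed(3)
  n <- 50
  B <- matrix(0.5, n, 6)
  hi <- c(4, 9, 40) # planted variable sites
  B[hi, ] <- rep(c(0.05, 0.95), each = 3)
  B <- B + matrix(rnorm(n * 6, 0, 0.001), n, 6)
  B[B < 0] <- 0
  B[B > 1] <- 1
  samples <- cohort_from_beta_matrix(B, rep(c("RA", "OA"), each = 3),
    cov = 1000L
  )
  out <- top_variable_cpg_clustering(samples, n_top = 3, min_cov = 1)
  expect_setequal(out$selected$pos, samples[[1]]$sites$pos[hi])
  expect_s3_class(out$hclust, "hclust")
  expect_error(
    top_variable_cpg_clustering(samples, n_top = 1000, min_cov = 1),
    "exceeds"
  )
})
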