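# Cohort generator: determinism, coverage model, planted structure, and
# the couplings feeding the downstream integration stages.

small_cfg <- function(...) {
  args <- utils::modifyList(list(
    n_ra = 3, n_oa = 3, n_cpg = 5000, n_pmd = 1, pmd_cpgs = 400,
    n_umr = 3, n_lmr = 5, n_lmr_ra = 2, n_lmr_oa = 1,
    n_dmc = 10, n_dvc = 10, n_coupled_mirna = 2, n_mirna = 10,
    n_genes = 20, n_coupled_genes = 2, rng_seed = 7
  ), list(...))
  do.call(cohort_config, args)
}

test_that("identical seeds give identical cohorts, different seeds differ", {
  a <- simulate_methylome_cohort(small_cfg())
  b <- simulate_methylome_cohort(small_cfg())
  expect_identical(a, b)
  c <- simulate_methylome_cohort(small_cfg(rng_seed = 8))
  expect_false(identical(a$samples[[1]]$sites, c$samples[[1]]$sites))
})

test_that("realized coverage matches the truncated-Poisson target", {
  cfg <- cohort_config(
    n_ra = 1, n_oa = 1, n_cpg = 1e5, mean_cov = 22,
    n_pmd = 0, n_umr = 0, n_lmr = 0, n_lmr_ra = 0, n_lmr_oa = 0,
    n_dmc = 0, n_dvc = 0, n_coupled_mirna = 0, rng_seed = 3
  )
  mc <- simulate_methylome_cohort(cfg)
  cov <- mc$samples[[1]]$sites$cov
  expect_true(all(cov >= 1))
  expect_lt(abs(mean(cov) - 22) / 22, 0.01)
})

test_that("samples satisfy the methylome invariants", {
  mc <- simulate_methylome_cohort(small_cfg())
  for (s in mc$samples) {
    expect_true(all(diff(s$sites$pos) > 0))
    expect_true(all(s$sites$meth <= s$sites$cov))
    expect_true(all(s$sites$meth >= 0))
  }
})

test_that("group-specific LMR truth records realized support", {
  cfg <- small_cfg(penetrance = 1.0)
  mc <- simulate_methylome_cohort(cfg)
  spec <- mc$truth$regions[mc$truth$regions$group == "RA", ]
  expect_true(all(spec$n_ra_detected == 3))
  expect_true(all(spec$n_oa_detected == 0))
  # penetrant samples really are hypomethylated, others are not
  r <- spec[1, ]
  idx <- r$start_idx:r$end_idx
  mb <- vapply(mc$samples, function(s) {
    sum(s$sites$meth[idx]) / sum(s$sites$cov[idx])
  }, numeric(1))
  grp <- mc$truth$sample_info$group
  expect_true(all(mb[grp == "RA"] < 0.35))
  expect_true(all(mb[grp == "OA"] > 0.6))
})

test_that("overlapping planted regions are rejected", {
  expect_error(
    simulate_methylome_cohort(cohort_config(
      n_cpg = 500, n_pmd = 2, pmd_cpgs = 300, rng_seed = 1
    )),
    "capacity|overlap"
  )
})

test_that("planted low-to-intermediate fraction matches the background mix", {
  cfg <- cohort_config(
    n_ra = 1, n_oa = 1, n_cpg = 2e4,
    n_pmd = 0, n_umr = 0, n_lmr = 0, n_lmr_ra = 0, n_lmr_oa = 0,
    n_dmc = 0, n_dvc = 0, n_coupled_mirna = 0, rng_seed = 5
  )
  mc <- simulate_methylome_cohort(cfg)
  s <- mc$samples[[1]]
  beta <- s$sites$meth / s$sites$cov
  # low mixture component is 20% of background loci
  expect_lt(abs(mean(beta < 0.5) - 0.2), 0.02)
})

test_that("expression coupling is monotone negative and seeded", {
  cfg <- small_cfg(expr_noise_sd = 0, gene_coupling_strength = 4)
  mc <- simulate_methylome_cohort(cfg)
  ex <- simulate_expression_profiles(cfg, mc$truth, mc$samples)
  ex2 <- simulate_expression_profiles(cfg, mc$truth, mc$samples)
  expect_identical(ex$expr, ex2$expr)
  r1 <- ex$couplings$region_id[1]
  reg <- mc$truth$regions[mc$truth$regions$region_id == r1, ]
  idx <- reg$start_idx:reg$end_idx
  m <- vapply(mc$samples, function(s) {
    sum(s$sites$meth[idx]) / sum(s$sites$cov[idx])
  }, numeric(1))
  # noiseless coupling: log-expression is an exact linear function of
  # the region's methylation
  r <- cor(log2(ex$expr[ex$couplings$gene[1], ]), m)
  expect_equal(r, -1, tolerance = 1e-12)
})

test_that("uncoupled genes are uncorrelated with LMR methylation", {
  cfg <- small_cfg(n_genes = 60, n_coupled_genes = 0)
  mc <- simulate_methylome_cohort(cfg)
  ex <- simulate_expression_profiles(cfg, mc$truth, mc$samples)
  reg <- mc$truth$regions[mc$truth$regions$group == "RA", ][1, ]
  idx <- reg$start_idx:reg$end_idx
  m <- vapply(mc$samples, function(s) {
    sum(s$sites$meth[idx]) / sum(s$sites$cov[idx])
  }, numeric(1))
  rs <- apply(log2(ex$expr), 1, cor, y = m)
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("miRNA counts are seeded and coupled miRNAs track methylation", {
  cfg <- small_cfg(mirna_dispersion = 0.01, mirna_coupling_strength = 4)
  mc <- simulate_methylome_cohort(cfg)
  mi <- simulate_mirna_counts(cfg, mc$truth, mc$samples)
  mi2 <- simulate_mirna_counts(cfg, mc$truth, mc$samples)
  expect_identical(mi$counts, mi2$counts)
  lev <- mc$truth$vmr_level[mi$couplings$region_id[1], ]
  rho <- cor(rank(mi$counts[mi$couplings$mirna[1], ]), rank(lev))
  expect_lt(rho, -0.7)
})

test_that("near-Poisson planted group fold change is realized", {
  cfg <- cohort_config(
    n_ra = 6, n_oa = 6, n_cpg = 5000, n_pmd = 0, n_umr = 0, n_lmr = 0,
    n_lmr_ra = 0, n_lmr_oa = 0, n_dmc = 0, n_dvc = 0,
    n_mirna = 20, n_coupled_mirna = 4, mirna_dispersion = 0,
    mirna_coupling_strength = 0, mirna_group_fc = 4,
    rng_seed = 13
  )
  mc <- simulate_methylome_cohort(cfg)
  mi <- simulate_mirna_counts(cfg, mc$truth, mc$samples)
  grp <- mc$truth$sample_info$group
  # zero-dispersion limit: on raw counts the realized group mean ratio is
  # close to the planted 4 (library-size factors are group-independent)
  fc <- rowMeans(mi$counts[mi$couplings$mirna, grp == "RA"]) /
    rowMeans(mi$counts[mi$couplings$mirna, grp == "OA"])
  expect_true(all(abs(fc / 4 - 1) < 0.3))
})

test_that("variant tables respect rates, planting and determinism", {
  cfg <- small_cfg()
  va <- simulate_variant_tables(cfg)
  va2 <- simulate_variant_tables(cfg)
  expect_identical(va$variants, va2$variants)
  # all-zero mutation probabilities give an empty table
  cfg0 <- cohort_config(
    n_ra = 3, n_oa = 3, mu_range = c(0, 0), n_excess_genes = 0,
    rng_seed = 2
  )
  expect_equal(nrow(simulate_variant_tables(cfg0)$variants), 0L)
  expect_error(
    simulate_variant_tables(cohort_config(mu_range = c(-1e-5, 1e-5))),
    "mu_range"
  )
  # a strongly inflated gene reaches >= 2 RA samples and no OA excess
  cfgx <- cohort_config(
    n_ra = 11, n_oa = 7, n_mut_genes = 50, n_excess_genes = 1,
    excess_factor = 1e4, rng_seed = 9
  )
  vx <- simulate_variant_tables(cfgx)
  hit <- unique(vx$variants[vx$variants$gene == vx$excess_genes, "sample"])
  expect_gte(sum(startsWith(hit, "RA")), 2)
})
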