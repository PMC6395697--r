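# Alpha track against a grid-search ML oracle, PMD detection and sharing
# rules, FDR cutoff selection, and the UMR/LMR class boundary.

test_that("alpha fit matches the grid-search ML oracle on 101-CpG windows", {
  set.seed(42)
  cases <- list(
    polarized = c(
      rbeta(50, 20, 2), rbeta(51, 2, 20)
    )[sample(101)],
    dispersed = rbeta(101, 1.5, 1.5),
    near_half = rep(c(0.45, 0.5, 0.55), length.out = 101)
  )
  for (nm in names(cases)) {
    b <- cases[[nm]]
    s <- sample_from_betas(b, cov = 1000L) # high coverage: smoothed ~ raw
    tr <- compute_alpha_track(s, 101L)
    expect_equal(nrow(tr), 1L)
    bb <- (s$sites$meth + 0.5) / (s$sites$cov + 1)
    expect_lt(abs(tr$alpha - alpha_grid_oracle(bb)), 0.01)
  }
})

test_that("alpha separates polarized from dispersed landscapes", {
  s_pol <- sample_from_betas(rep(c(0.02, 0.98, 0.03, 0.97), 26)[1:101],
    cov = 100L
  )
  expect_lt(compute_alpha_track(s_pol, 101L)$alpha, 1)
  s_disp <- sample_from_betas(rep(0.5, 101), cov = 100L)
  expect_gt(compute_alpha_track(s_disp, 101L)$alpha, 1)
})

test_that("too-short samples give an empty track with a warning", {
  s <- sample_from_betas(rep(0.5, 5))
  expect_warning(tr <- compute_alpha_track(s, 101L), "fewer CpGs")
  expect_equal(nrow(tr), 0L)
})

test_that("a planted PMD is recovered with high base-level Jaccard", {
  cfg <- cohort_config(
    n_ra = 1, n_oa = 1, n_cpg = 3e4, n_pmd = 1, pmd_cpgs = 2000,
    n_umr = 0, n_lmr = 0, n_lmr_ra = 0, n_lmr_oa = 0, n_dmc = 0,
    n_dvc = 0, n_coupled_mirna = 0, rng_seed = 17
  )
  mc <- simulate_methylome_cohort(cfg)
  s <- mc$samples[[1]]
  pmds <- detect_pmds(compute_alpha_track(s), s)
  expect_length(pmds, 1L)
  tru <- truth_region_ranges(mc$truth, "PMD", s$sample_id)
  expect_gte(interval_f1(pmds, tru)["jaccard"], 0.9)
})

test_that("a PMD-free polarized genome yields no PMDs", {
  cfg <- cohort_config(
    n_ra = 1, n_oa = 1, n_cpg = 2e4, n_pmd = 0,
    n_umr = 2, n_lmr = 5, n_lmr_ra = 0, n_lmr_oa = 0, n_dmc = 0,
    n_dvc = 0, n_coupled_mirna = 0, rng_seed = 19
  )
  s <- simulate_methylome_cohort(cfg)$samples[[1]]
  expect_length(detect_pmds(compute_alpha_track(s), s), 0L)
})

test_that("an all-dispersed genome becomes one PMD spanning the track", {
  set.seed(23)
  s <- sample_from_betas(rbeta(2000, 1.5, 1.5), cov = 22L)
  pmds <- detect_pmds(compute_alpha_track(s), s)
  expect_length(pmds, 1L)
  expect_equal(S4Vectors::mcols(pmds)$n_cpg, 2000L)
})

test_that("PMD sharing follows the overlap and uniqueness rules", {
  pmds <- list(
    RA1 = gr_interval("chr1", 0, 1000),
    OA1 = gr_interval("chr1", 500, 2000),
    RA2 = gr_interval("chr2", 0, 500)
  )
  groups <- c(RA1 = "RA", OA1 = "OA", RA2 = "RA")
  lab <- classify_pmd_sharing(pmds, groups)
  expect_equal(lab$label[lab$sample == "RA1"], "shared")
  expect_equal(lab$label[lab$sample == "OA1"], "shared")
  expect_equal(lab$label[lab$sample == "RA2"], "specific")
  # a PMD shared within one group but absent from the other is neither
  pmds2 <- list(
    RA1 = gr_interval("chr1", 0, 1000),
    RA2 = gr_interval("chr1", 100, 900),
    OA1 = gr_interval("chr2", 0, 100)
  )
  lab2 <- classify_pmd_sharing(pmds2, c(RA1 = "RA", RA2 = "RA", OA1 = "OA"))
  expect_equal(
    lab2$label[lab2$sample %in% c("RA1", "RA2")],
    c("private_multi", "private_multi")
  )
  expect_equal(
    nrow(classify_pmd_sharing(list(), c(RA1 = "RA"))), 0L
  )
  expect_error(
    classify_pmd_sharing(pmds, c(RA1 = "XX", OA1 = "OA", RA2 = "RA")),
    "unknown group"
  )
})

test_that("FDR cutoff selection is seeded and fails on structureless input", {
  cfg <- cohort_config(
    n_ra = 1, n_oa = 1, n_cpg = 2e4, n_pmd = 0,
    n_umr = 4, n_lmr = 10, n_lmr_ra = 0, n_lmr_oa = 0, n_dmc = 0,
    n_dvc = 0, n_coupled_mirna = 0, rng_seed = 29
  )
  s <- simulate_methylome_cohort(cfg)$samples[[1]]
  none <- GenomicRanges::GRanges()
  a <- select_fdr_cutoff(s, none, seed = 4)
  b <- select_fdr_cutoff(s, none, seed = 4)
  expect_identical(a, b)
  expect_lte(a$fdr, 0.05)
  expect_true(a$m %in% seq(0.30, 0.70, by = 0.05))
  # destroy the spatial structure: every cutoff looks like its permutation
  set.seed(99)
  sites <- s$sites
  perm <- sample(nrow(sites))
  sites$meth <- sites$meth[perm]
  sites$cov <- sites$cov[perm]
  s_perm <- methylome_sample("perm", "RA", sites)
  expect_error(
    select_fdr_cutoff(s_perm, none, seed = 4),
    "no cutoff|no callable"
  )
})

test_that("UMR/LMR classification splits exactly at 30 CpGs", {
  # two hypomethylated runs separated by high background, 35 and 29 CpGs
  betas <- c(
    rep(0.9, 20), rep(0.02, 35), rep(0.9, 20), rep(0.2, 29), rep(0.9, 20)
  )
  s <- sample_from_betas(betas, cov = 50L)
  segs <- call_umr_lmr(
    s, GenomicRanges::GRanges(), list(m = 0.3, n = 5)
  )
  expect_length(segs, 2L)
  expect_equal(S4Vectors::mcols(segs)$klass, c("UMR", "LMR"))
  expect_equal(S4Vectors::mcols(segs)$n_cpg, c(35L, 29L))
  # no CpG below the cutoff: nothing called
  s_hi <- sample_from_betas(rep(0.9, 100), cov = 50L)
  expect_length(
    call_umr_lmr(s_hi, GenomicRanges::GRanges(), list(m = 0.3, n = 5)), 0L
  )
})

test_that("UMR/LMR segments never intersect same-sample PMDs", {
  cfg <- cohort_config(
    n_ra = 1, n_oa = 1, n_cpg = 5e4, n_pmd = 1, pmd_cpgs = 1500,
    n_umr = 5, n_lmr = 10, n_lmr_ra = 0, n_lmr_oa = 0,
    n_dmc = 0, n_dvc = 0, n_coupled_mirna = 0, rng_seed = 31
  )
  s <- simulate_methylome_cohort(cfg)$samples[[1]]
  seg <- segment_methylome(s, seed = 3)
  expect_equal(
    sum(GenomicRanges::countOverlaps(seg$segments, seg$pmds)), 0L
  )
  # segments within the sample are sorted and non-overlapping
  st <- GenomicRanges::start(seg$segments)
  expect_true(!is.unsorted(st))
  expect_true(all(
    GenomicRanges::start(seg$segments)[-1] >
      GenomicRanges::end(seg$segments)[-length(seg$segments)]
  ))
})
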