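# Group-specific LMR rules, profile clustering, Jaccard clustering,
# genomic annotation, and enhancer overlap enrichment.

test_that("group-specific LMR support rules are exact", {
  # one consensus region with controllable per-sample detection
  reg <- function(detected) {
    if (detected) gr_interval("chr1", 1000, 1500) else GenomicRanges::GRanges()
  }
  build <- function(n_ra_hit, n_oa_hit) {
    lmrs <- c(
      lapply(seq_len(3), function(i) reg(i <= n_ra_hit)),
      lapply(seq_len(3), function(i) reg(i <= n_oa_hit))
    )
    names(lmrs) <- c(paste0("RA", 1:3), paste0("OA", 1:3))
    groups <- c(rep("RA", 3), rep("OA", 3))
    names(groups) <- names(lmrs)
    call_group_specific_lmrs(lmrs, groups)
  }
  expect_length(build(3, 0)$RA, 1L) # 3 RA / 0 OA: accepted
  expect_length(build(2, 0)$RA, 0L) # 2 RA: rejected (> 2 required)
  expect_length(build(3, 1)$RA, 0L) # any OA support: rejected
  spec <- build(3, 0)
  expect_equal(S4Vectors::mcols(spec$RA)$n_ra_detected, 3)
  expect_equal(S4Vectors::mcols(spec$RA)$n_oa_detected, 0)
})

test_that("per-sample LMRs merge by single-linkage overlap", {
  lmrs <- list(
    RA1 = gr_interval("chr1", c(100, 190), c(200, 300)),
    RA2 = gr_interval("chr1", 150, 250),
    RA3 = gr_interval("chr1", 120, 220),
    OA1 = GenomicRanges::GRanges(),
    OA2 = GenomicRanges::GRanges(),
    OA3 = GenomicRanges::GRanges()
  )
  groups <- stats::setNames(
    c(rep("RA", 3), rep("OA", 3)), names(lmrs)
  )
  out <- call_group_specific_lmrs(lmrs, groups)
  expect_length(out$consensus, 1L)
  expect_equal(GenomicRanges::start(out$consensus) - 1, 100)
  expect_equal(GenomicRanges::end(out$consensus), 300)
  expect_length(out$RA, 1L)
  expect_error(
    call_group_specific_lmrs(lmrs[1:3], groups[1:3]),
    "both groups"
  )
})

test_that("profile clustering recovers two planted profile shapes", {
  cfg <- cohort_config(
    n_ra = 3, n_oa = 3, n_cpg = 3e4, n_pmd = 0, n_umr = 0,
    n_lmr = 0, n_lmr_ra = 4, n_lmr_oa = 4, n_dmc = 0, n_dvc = 0,
    n_coupled_mirna = 0, rng_seed = 47
  )
  mc <- simulate_methylome_cohort(cfg)
  tr <- mc$truth$regions
  regions <- GenomicRanges::GRanges(
    "chrS", IRanges::IRanges(tr$start + 1, tr$end)
  )
  pc <- profile_and_cluster_lmrs(regions, mc$samples, k = 2, seed = 5)
  # RA-specific rows are hypomethylated in the RA half of the profile,
  # OA-specific rows in the OA half: k-means must separate them exactly
  expect_equal(length(unique(pc$cluster[tr$group == "RA"])), 1L)
  expect_equal(length(unique(pc$cluster[tr$group == "OA"])), 1L)
  expect_false(
    pc$cluster[tr$group == "RA"][1] == pc$cluster[tr$group == "OA"][1]
  )
  # k = 1 puts everything together
  pc1 <- profile_and_cluster_lmrs(regions, mc$samples, k = 1, seed = 5)
  expect_equal(unique(pc1$cluster), 1L)
  # duplicated identical rows do not crash k-means
  pc2 <- profile_and_cluster_lmrs(
    rep(regions[1], 3), mc$samples,
    k = 2, seed = 5
  )
  expect_length(pc2$cluster, 3L)
})

test_that("Jaccard index follows hand-computed base-pair overlap", {
  lmrs <- list(
    A = gr_interval("chr1", 0, 100),
    B = gr_interval("chr1", 50, 150),
    C = gr_interval("chr1", 0, 100)
  )
  jc <- jaccard_sample_clustering(lmrs)
  expect_equal(jc$jaccard["A", "B"], 50 / 150)
  expect_equal(jc$jaccard["A", "C"], 1)
  expect_true(isSymmetric(jc$jaccard))
  expect_true(all(diag(jc$jaccard) == 1))
  expect_true(all(jc$jaccard >= 0 & jc$jaccard <= 1))
  expect_match(jc$dendrogram_newick, "^\\(")

  # disjoint and empty sets
  lmrs2 <- list(
    A = gr_interval("chr1", 0, 100),
    B = gr_interval("chr1", 200, 300),
    E1 = GenomicRanges::GRanges(),
    E2 = GenomicRanges::GRanges()
  )
  expect_warning(jc2 <- jaccard_sample_clustering(lmrs2), "convention")
  expect_equal(jc2$jaccard["A", "B"], 0)
  expect_equal(jc2$jaccard["A", "E1"], 0)
  expect_equal(jc2$jaccard["E1", "E2"], 1)
})

test_that("midpoint annotation respects precedence and strand", {
  genes <- c(
    toy_gene(
      start = 10000, end = 13000, strand = "+", name = "plus",
      exon_starts = c(10000, 11000, 12000),
      exon_ends = c(10400, 11400, 13000)
    ),
    toy_gene(
      start = 20000, end = 23000, strand = "-", name = "minus",
      exon_starts = c(20000, 21000, 22000),
      exon_ends = c(20400, 21400, 23000)
    )
  )
  regions <- gr_interval(
    "chrS",
    c(10500, 9000, 10100, 21500, 20500, 30000),
    c(10900, 9100, 10200, 21700, 20700, 30100)
  )
  ann <- annotate_lmr_position(regions, genes)
  # midpoint 10700: between exon1 and exon2 of the + gene -> intron 1
  expect_equal(ann$category[1], "intron")
  expect_equal(ann$intron_index[1], 1L)
  # midpoint 9050: 950 bp upstream of the + TSS -> promoter
  expect_equal(ann$category[2], "promoter")
  # midpoint 10150: inside exon 1
  expect_equal(ann$category[3], "exon")
  # minus-strand gene, midpoint 21600: genomically second intron = first
  # intron from the 5' end of the transcript
  expect_equal(ann$category[4], "intron")
  expect_equal(ann$intron_index[4], 1L)
  # minus-strand gene, midpoint 20600: genomically first intron = last
  expect_equal(ann$intron_index[5], 2L)
  # relative position is strand-aware and clipped to [0, 1]
  expect_equal(ann$relative_position[4], (23000 - 21600) / 3000)
  expect_equal(ann$category[6], "intergenic")
})

test_that("regions on unknown chromosomes fall back to intergenic", {
  genes <- toy_gene()
  expect_warning(
    ann <- annotate_lmr_position(gr_interval("chrX", 0, 100), genes),
    "absent"
  )
  expect_equal(ann$category, "intergenic")
})

test_that("enhancer overlap ratio and chi-squared match the oracle", {
  # 8/10 RA regions overlap, 2/10 OA regions overlap
  ra <- gr_interval("chr1", seq(0, 9000, by = 1000), seq(100, 9100, by = 1000))
  oa <- gr_interval(
    "chr1", seq(20000, 29000, by = 1000), seq(20100, 29100, by = 1000)
  )
  enh <- c(
    gr_interval("chr1", seq(0, 7000, by = 1000), seq(50, 7050, by = 1000)),
    gr_interval("chr1", c(20000, 21000), c(20050, 21050))
  )
  res <- enhancer_overlap_ratio(ra, oa, list(ct1 = enh))
  expect_equal(res$p_ra, 0.8)
  expect_equal(res$p_oa, 0.2)
  expect_equal(res$ratio, 4)
  oracle <- stats::chisq.test(
    matrix(c(8, 2, 2, 8), 2, 2),
    correct = FALSE
  )$p.value
  expect_equal(res$chi2_p, oracle, tolerance = 1e-12)

  # identical fractions: ratio 1, p = 1
  res2 <- enhancer_overlap_ratio(ra, ra, list(ct1 = enh))
  expect_equal(res2$ratio, 1)
  expect_gt(res2$chi2_p, 0.99)

  # zero OA overlap: infinite-ratio sentinel, chi-squared still computed
  res3 <- enhancer_overlap_ratio(
    ra, oa, list(ct1 = gr_interval("chr1", 0, 7050))
  )
  expect_equal(res3$ratio, Inf)
  expect_true(is.finite(res3$chi2_p))
})
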