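# Single-CpG statistics: bisulfite conversion-control QC, differential
# (DMC) and variability (DVC) tests, their overlap significance, balanced
# error rate classification, and variability-based sample clustering.

#' Bisulfite conversion control QC
#'
#' A control region expected to be fully methylated (e.g. a constitutively
#' methylated gene-body marker) is checked: if its mean beta drops below
#' the threshold the conversion likely over-converted methylated cytosines
#' and the sample is flagged for exclusion.
#'
#' @param sample A [methylome_sample()].
#' @param control_region A single-interval `GRanges` (or list with chrom,
#'   start, end, 0-based half-open).
#' @param min_mean_beta Pass threshold on the region's mean beta.
#' @return "pass", "fail", or "indeterminate" (no covered CpG in region).
#' @export
qc_conversion_control <- function(sample, control_region,
                                  min_mean_beta = 0.8) {
  if (!methods::is(control_region, "GRanges")) {
    control_region <- GenomicRanges::GRanges(
      control_region$chrom,
      IRanges::IRanges(control_region$start + 1, control_region$end)
    )
  }
  s <- sample$sites
  cg <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1, s$pos + 1))
  hit <- GenomicRanges::countOverlaps(cg, control_region) > 0 & s$cov > 0
  if (!any(hit)) {
    return("indeterminate")
  }
  mb <- mean(s$meth[hit] / s$cov[hit])
  if (mb >= min_mean_beta) "pass" else "fail"
}

# Assemble aligned per-site count matrices across a cohort, keeping CpGs
# covered >= min_cov in every sample. Returns list(pos, meth, cov) with
# matrices sites x samples.
align_cohort_counts <- function(samples, min_cov = 5L) {
  keys <- lapply(samples, function(s) paste(s$sites$chrom, s$sites$pos))
  common <- Reduce(intersect, keys)
  idx <- lapply(keys, match, x = common)
  meth <- matrix(
    vapply(seq_along(samples), function(i) {
      samples[[i]]$sites$meth[idx[[i]]]
    }, numeric(length(common))),
    nrow = length(common)
  )
  cov <- matrix(
    vapply(seq_along(samples), function(i) {
      samples[[i]]$sites$cov[idx[[i]]]
    }, numeric(length(common))),
    nrow = length(common)
  )
  keep <- rowSums(cov >= min_cov) == length(samples)
  first <- samples[[1]]$sites[idx[[1]], c("chrom", "pos")]
  list(
    chrom = first$chrom[keep], pos = first$pos[keep],
    meth = meth[keep, , drop = FALSE], cov = cov[keep, , drop = FALSE],
    groups = vapply(samples, `[[`, character(1), "group"),
    sample_ids = vapply(samples, `[[`, character(1), "sample_id")
  )
}

# Vectorized binomial log-likelihood of pooled counts at rate p
pooled_binll <- function(m, u, p) {
  t1 <- ifelse(m > 0, m * log(p), 0)
  t2 <- ifelse(u > 0, u * log1p(-p), 0)
  t1 + t2
}

#' Differentially methylated CpG test (logistic regression)
#'
#' Per CpG, (methylated, unmethylated) counts are regressed on the group
#' indicator by binomial logistic regression; with a single binary
#' covariate the likelihood-ratio statistic has the closed form
#' 2 [ll(per-group pooled rates) - ll(overall pooled rate)] and is compared
#' to chi-squared with 1 df. The methylation difference is the difference
#' of unweighted per-sample mean betas (RA - OA). A CpG is a DMC iff
#' |diff| > `diff_threshold` and p < alpha / N_tested (Bonferroni over the
#' tested universe).
#'
#' @param samples List of [methylome_sample()] (both groups, >= 2 each).
#' @param min_cov Minimum coverage required in every sample (default 5).
#' @param diff_threshold Methylation-difference threshold (default 0.2).
#' @param alpha Family-wise error rate for Bonferroni (default 0.05).
#' @return data.frame: chrom, pos, mean_beta_ra, mean_beta_oa, diff, p_dmc,
#'   is_dmc, direction ("hyper"/"hypo" for DMCs), plus attributes
#'   `n_tested` and `bonferroni` (the per-test threshold).
#' @export
test_dmc <- function(samples, min_cov = 5L, diff_threshold = 0.2,
                     alpha = 0.05) {
  groups <- vapply(samples, `[[`, character(1), "group")
  check_groups(groups)
  if (sum(groups == "RA") < 2 || sum(groups == "OA") < 2) {
    stop("each group needs at least 2 samples")
  }
  cc <- align_cohort_counts(samples, min_cov)
  ra <- cc$groups == "RA"
  m_ra <- rowSums(cc$meth[, ra, drop = FALSE])
  u_ra <- rowSums(cc$cov[, ra, drop = FALSE]) - m_ra
  m_oa <- rowSums(cc$meth[, !ra, drop = FALSE])
  u_oa <- rowSums(cc$cov[, !ra, drop = FALSE]) - m_oa
  p_ra_hat <- m_ra / (m_ra + u_ra)
  p_oa_hat <- m_oa / (m_oa + u_oa)
  p_all <- (m_ra + m_oa) / (m_ra + u_ra + m_oa + u_oa)
  ll_full <- pooled_binll(m_ra, u_ra, p_ra_hat) +
    pooled_binll(m_oa, u_oa, p_oa_hat)
  ll_null <- pooled_binll(m_ra, u_ra, p_all) + pooled_binll(m_oa, u_oa, p_all)
  lrt <- pmax(2 * (ll_full - ll_null), 0)
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  betas <- cc$meth / cc$cov
  mb_ra <- rowMeans(betas[, ra, drop = FALSE])
  mb_oa <- rowMeans(betas[, !ra, drop = FALSE])
  diff <- mb_ra - mb_oa
  n_tested <- length(p)
  thr <- alpha / n_tested
  is_dmc <- abs(diff) > diff_threshold & p < thr
  out <- data.frame(
    chrom = cc$chrom, pos = cc$pos,
    mean_beta_ra = mb_ra, mean_beta_oa = mb_oa, diff = diff,
    p_dmc = p,
    is_dmc = is_dmc,
    direction = ifelse(is_dmc, ifelse(diff > 0, "hyper", "hypo"),
      NA_character_
    ),
    stringsAsFactors = FALSE
  )
  attr(out, "n_tested") <- n_tested
  attr(out, "bonferroni") <- thr
  out
}

# Levene's W on one site: one-way ANOVA F statistic on absolute deviations
# from the group center (mean or median)
levene_w <- function(values, groups, center = c("mean", "median")) {
  center <- match.arg(center)
  cf <- if (center == "mean") mean else stats::median
  g <- unique(groups)
  d <- abs(values - ave(values, groups, FUN = cf))
  k <- length(g)
  n <- length(values)
  dbar <- mean(d)
  dg <- tapply(d, groups, mean)
  ng <- tapply(d, groups, length)
  ssb <- sum(ng * (dg - dbar)^2)
  ssw <- sum((d - ave(d, groups, FUN = mean))^2)
  if (ssw == 0) {
    return(list(W = NA_real_, p = NA_real_))
  }
  W <- ((n - k) / (k - 1)) * ssb / ssw
  list(W = W, p = stats::pf(W, k - 1, n - k, lower.tail = FALSE))
}

#' Differentially variable CpG test (Levene)
#'
#' Per CpG, Levene's test on per-sample beta values with group-mean
#' centering (classic Levene; median centering, i.e. Brown-Forsythe, is
#' available). P-values are Benjamini-Hochberg adjusted across tested
#' CpGs; a CpG is a DVC iff q < `q_threshold`, hypervariable iff the RA
#' variance exceeds the OA variance. Sites with zero within-group
#' deviations in both groups are skipped.
#'
#' @param samples List of [methylome_sample()].
#' @param min_cov Minimum coverage in every sample.
#' @param q_threshold FDR threshold (default 0.05).
#' @param center "mean" (Levene) or "median" (Brown-Forsythe).
#' @return data.frame: chrom, pos, var_ra, var_oa, W, p_dvc, q_dvc, is_dvc,
#'   direction, skipped (logical with reason attribute dropped), with
#'   attribute `n_tested`.
#' @export
test_dvc <- function(samples, min_cov = 5L, q_threshold = 0.05,
                     center = "mean") {
  groups <- vapply(samples, `[[`, character(1), "group")
  check_groups(groups)
  if (sum(groups == "RA") < 2 || sum(groups == "OA") < 2) {
    stop("each group needs at least 2 samples")
  }
  cc <- align_cohort_counts(samples, min_cov)
  betas <- cc$meth / cc$cov
  ra <- cc$groups == "RA"
  cf <- if (center == "mean") rowMeans else function(x) apply(x, 1, stats::median)
  ctr_ra <- cf(betas[, ra, drop = FALSE])
  ctr_oa <- cf(betas[, !ra, drop = FALSE])
  ctr <- matrix(0, nrow(betas), ncol(betas))
  ctr[, ra] <- ctr_ra
  ctr[, !ra] <- ctr_oa
  d <- abs(betas - ctr)
  n <- ncol(betas)
  k <- 2L
  n_ra <- sum(ra)
  n_oa <- n - n_ra
  d_ra <- rowMeans(d[, ra, drop = FALSE])
  d_oa <- rowMeans(d[, !ra, drop = FALSE])
  dbar <- rowMeans(d)
  ssb <- n_ra * (d_ra - dbar)^2 + n_oa * (d_oa - dbar)^2
  ssw <- rowSums((d[, ra, drop = FALSE] - d_ra)^2) +
    rowSums((d[, !ra, drop = FALSE] - d_oa)^2)
  skipped <- ssw == 0
  W <- ifelse(skipped, NA_real_, ((n - k) / (k - 1)) * ssb / ssw)
  p <- stats::pf(W, k - 1, n - k, lower.tail = FALSE)
  q <- rep(NA_real_, length(p))
  q[!skipped] <- stats::p.adjust(p[!skipped], method = "BH")
  var_ra <- apply(betas[, ra, drop = FALSE], 1, stats::var)
  var_oa <- apply(betas[, !ra, drop = FALSE], 1, stats::var)
  is_dvc <- !skipped & q < q_threshold
  out <- data.frame(
    chrom = cc$chrom, pos = cc$pos,
    var_ra = var_ra, var_oa = var_oa,
    W = W, p_dvc = p, q_dvc = q,
    is_dvc = is_dvc,
    direction = ifelse(is_dvc, ifelse(var_ra > var_oa, "hyper", "hypo"),
      NA_character_
    ),
    skipped = skipped,
    stringsAsFactors = FALSE
  )
  attr(out, "n_tested") <- sum(!skipped)
  out
}

#' Significance of the DMC/DVC overlap
#'
#' One-sided (enrichment) Fisher's exact test on the 2x2 table
#' [in-both, DMC-only, DVC-only, neither] over the tested universe, plus a
#' permutation test that redraws one set's membership uniformly over the
#' universe (seeded) and applies the add-one rule.
#'
#' @param dmc_set,dvc_set Integer or character identifiers of the member
#'   sites (subsets of the universe).
#' @param universe_size Number of tested sites.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutations.
#' @return List: table (2x2), fisher_p, permutation_p, n_permutations.
#' @export
dmc_dvc_overlap_significance <- function(dmc_set, dvc_set, universe_size,
                                         n_perm = 999L, seed = 1L) {
  a <- unique(dmc_set)
  b <- unique(dvc_set)
  if (length(union(a, b)) > universe_size) {
    stop("universe smaller than the union of the two sets")
  }
  both <- length(intersect(a, b))
  tab <- matrix(
    c(
      both, length(a) - both,
      length(b) - both, universe_size - length(union(a, b))
    ),
    2, 2,
    byrow = TRUE
  )
  fisher_p <- stats::fisher.test(tab, alternative = "greater")$p.value
  set.seed(seed)
  hits <- 0L
  nb <- length(b)
  for (i in seq_len(n_perm)) {
    # redraw B uniformly; by exchangeability the overlap with A has the
    # same law as the overlap with the first |A| universe slots
    perm_b <- sample.int(universe_size, nb)
    if (sum(perm_b <= length(a)) >= both) hits <- hits + 1L
  }
  list(
    table = tab,
    fisher_p = fisher_p,
    permutation_p = perm_pvalue(hits, n_perm),
    n_permutations = n_perm
  )
}

# leave-one-out nearest-centroid balanced error rate
ber_loo <- function(X, groups) {
  # X: features x samples
  n <- ncol(X)
  pred <- character(n)
  for (i in seq_len(n)) {
    tr <- setdiff(seq_len(n), i)
    cen_ra <- rowMeans(X[, tr[groups[tr] == "RA"], drop = FALSE])
    cen_oa <- rowMeans(X[, tr[groups[tr] == "OA"], drop = FALSE])
    d_ra <- sum((X[, i] - cen_ra)^2)
    d_oa <- sum((X[, i] - cen_oa)^2)
    pred[i] <- if (d_ra <= d_oa) "RA" else "OA"
  }
  err_ra <- mean(pred[groups == "RA"] != "RA")
  err_oa <- mean(pred[groups == "OA"] != "OA")
  (err_ra + err_oa) / 2
}

#' Balanced-error-rate comparison of CpG feature sets
#'
#' Leave-one-out nearest-centroid classification of samples on the beta
#' values of each feature set. For each set, a distribution of balanced
#' error rates (BER, the mean of the two per-class error rates) is obtained
#' over seeded bootstrap resamples of the features (size `boot_size`); the
#' significance of the BER difference between two sets is estimated by
#' group-label permutation (999 Monte Carlo replications by default).
#'
#' @param samples List of [methylome_sample()] (>= 3 per group).
#' @param feature_sets Named list of site identifier vectors (indices into
#'   the aligned tested universe, or "chrom:pos" keys).
#' @param min_cov Coverage filter for the aligned matrix.
#' @param n_boot Bootstrap resamples per set (default 100).
#' @param boot_size Features per resample (default 100).
#' @param n_perm Label permutations for the pairwise BER-difference test.
#' @param seed Seed.
#' @return List: `ber` (named list of bootstrap BER vectors), `ber_point`
#'   (named numeric, full-set BER), `perm_p` (matrix of pairwise
#'   permutation p-values for observed BER differences).
#' @export
balanced_error_classification <- function(samples, feature_sets,
                                          min_cov = 5L, n_boot = 100L,
                                          boot_size = 100L, n_perm = 999L,
                                          seed = 1L) {
  groups <- vapply(samples, `[[`, character(1), "group")
  if (sum(groups == "RA") < 3 || sum(groups == "OA") < 3) {
    stop("each group needs at least 3 samples")
  }
  cc <- align_cohort_counts(samples, min_cov)
  betas <- cc$meth / cc$cov
  keys <- paste(cc$chrom, cc$pos, sep = ":")
  resolve <- function(ids) {
    if (is.character(ids)) match(ids, keys) else as.integer(ids)
  }
  set.seed(seed)
  ber_boot <- list()
  ber_point <- numeric(0)
  for (nm in names(feature_sets)) {
    idx <- resolve(feature_sets[[nm]])
    idx <- idx[!is.na(idx)]
    if (length(idx) == 0) stop("empty feature set: ", nm)
    X <- betas[idx, , drop = FALSE]
    ber_point[nm] <- ber_loo(X, cc$groups)
    ber_boot[[nm]] <- vapply(seq_len(n_boot), function(b) {
      take <- sample(seq_along(idx), boot_size, replace = TRUE)
      ber_loo(X[take, , drop = FALSE], cc$groups)
    }, numeric(1))
  }
  nms <- names(feature_sets)
  perm_p <- matrix(NA_real_, length(nms), length(nms),
    dimnames = list(nms, nms)
  )
  for (i in seq_along(nms)) {
    for (j in seq_along(nms)) {
      if (i == j) next
      Xi <- betas[resolve(feature_sets[[nms[i]]]), , drop = FALSE]
      Xj <- betas[resolve(feature_sets[[nms[j]]]), , drop = FALSE]
      obs <- ber_point[nms[i]] - ber_point[nms[j]]
      hits <- 0L
      for (p in seq_len(n_perm)) {
        gp <- sample(cc$groups)
        if ((ber_loo(Xi, gp) - ber_loo(Xj, gp)) <= obs) hits <- hits + 1L
      }
      perm_p[i, j] <- perm_pvalue(hits, n_perm)
    }
  }
  list(ber = ber_boot, ber_point = ber_point, perm_p = perm_p)
}

#' Hierarchical clustering of samples on the most variable CpGs
#'
#' Selects the `n_top` CpGs with the highest cross-sample beta standard
#' deviation (ties at the boundary broken by genomic order) and clusters
#' samples hierarchically (Euclidean distance, average linkage).
#'
#' @param samples List of [methylome_sample()].
#' @param n_top Number of CpGs (e.g. 500).
#' @param min_cov Coverage filter.
#' @return List: `hclust`, `selected` (data.frame chrom, pos, sd),
#'   `betas` (selected-site beta matrix).
#' @export
top_variable_cpg_clustering <- function(samples, n_top = 500L, min_cov = 5L) {
  cc <- align_cohort_counts(samples, min_cov)
  betas <- cc$meth / cc$cov
  if (n_top > nrow(betas)) {
    stop("n_top exceeds the number of CpGs covered in all samples")
  }
  sds <- apply(betas, 1, stats::sd)
  ord <- order(-sds, cc$chrom, cc$pos)
  sel <- ord[seq_len(n_top)]
  X <- betas[sel, , drop = FALSE]
  colnames(X) <- cc$sample_ids
  hc <- stats::hclust(stats::dist(t(X)), method = "average")
  list(
    hclust = hc,
    selected = data.frame(
      chrom = cc$chrom[sel], pos = cc$pos[sel], sd = sds[sel]
    ),
    betas = X
  )
}
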