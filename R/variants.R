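# Rare-variant burden: RA-specific candidate gene selection, per-gene
# mutation-excess Poisson test (expected count 2 N mu), and a check that
# carrier status is independent of gene-body methylation.

#' Select genes with RA-restricted variants
#'
#' Genes whose variants appear in at least `min_ra_samples` RA samples and
#' in no OA sample.
#'
#' @param variant_table data.frame (gene, sample, consequence).
#' @param groups Named character vector sample id -> group.
#' @param min_ra_samples Minimum RA samples carrying a variant (default 2).
#' @return Character vector of gene names (sorted).
#' @export
select_candidate_genes <- function(variant_table, groups,
                                   min_ra_samples = 2L) {
  stopifnot(all(c("gene", "sample", "consequence") %in% names(variant_table)))
  if (nrow(variant_table) == 0) {
    return(character(0))
  }
  check_groups(groups)
  vt <- unique(variant_table[, c("gene", "sample")])
  vt$group <- groups[vt$sample]
  if (anyNA(vt$group)) stop("variant sample missing from the group map")
  n_ra <- tapply(vt$group == "RA", vt$gene, sum)
  n_oa <- tapply(vt$group == "OA", vt$gene, sum)
  sort(names(n_ra)[n_ra >= min_ra_samples & n_oa == 0])
}

#' Poisson mutation-excess test for one gene
#'
#' Under the de novo mutation framework the expected variant count in N
#' individuals is lambda = 2 N mu (two copies each); the p-value is the
#' upper Poisson tail P(X >= observed). A gene is significant iff
#' p < `threshold` and at least one variant was observed.
#'
#' @param mu Per-generation, per-copy mutation probability (> 0).
#' @param n_individuals Number of individuals in the target group.
#' @param observed Observed variant count (non-negative integer).
#' @param threshold Significance threshold (default 1e-8).
#' @return List: lambda_expected, p_poisson, significant.
#' @export
mutation_excess_test <- function(mu, n_individuals, observed,
                                 threshold = 1e-8) {
  stopifnot(mu > 0, n_individuals >= 1, observed >= 0,
    observed == round(observed)
  )
  lambda <- 2 * n_individuals * mu
  p <- if (observed == 0) {
    1.0
  } else {
    stats::ppois(observed - 1, lambda, lower.tail = FALSE)
  }
  list(
    lambda_expected = lambda,
    p_poisson = p,
    significant = (p < threshold) && observed >= 1
  )
}

#' Mutation-excess test across candidate genes
#'
#' @param variant_table data.frame (gene, sample, consequence).
#' @param mu_table data.frame (gene, mu).
#' @param groups Named character vector sample id -> group.
#' @param target_group Group whose samples are counted (default "RA").
#' @param threshold Significance threshold (default 1e-8).
#' @param genes Genes to test (default: all genes in `mu_table`).
#' @return data.frame: gene, mu, n_individuals, observed, lambda_expected,
#'   p_poisson, significant.
#' @export
mutation_excess_scan <- function(variant_table, mu_table, groups,
                                 target_group = "RA", threshold = 1e-8,
                                 genes = NULL) {
  check_groups(groups)
  if (is.null(genes)) genes <- mu_table$gene
  n_ind <- sum(groups == target_group)
  tgt_samples <- names(groups)[groups == target_group]
  vt <- variant_table[variant_table$sample %in% tgt_samples, , drop = FALSE]
  obs <- table(factor(vt$gene, levels = genes))
  mu <- mu_table$mu[match(genes, mu_table$gene)]
  if (anyNA(mu)) stop("gene missing from the mutation probability table")
  if (any(mu <= 0)) stop("non-positive mutation probability")
  res <- lapply(seq_along(genes), function(i) {
    t <- mutation_excess_test(mu[i], n_ind, as.integer(obs[i]), threshold)
    data.frame(
      gene = genes[i], mu = mu[i], n_individuals = n_ind,
      observed = as.integer(obs[i]),
      lambda_expected = t$lambda_expected,
      p_poisson = t$p_poisson, significant = t$significant,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Check independence of carrier status and gene-body methylation
#'
#' For each selected gene, the point-biserial correlation between per-sample
#' carrier status (any variant in the gene) and mean gene-body beta, with a
#' two-sided seeded permutation p. Genes where all samples are carriers or
#' none are, are skipped.
#'
#' @param selected_genes Character vector of genes.
#' @param variant_table data.frame (gene, sample, consequence).
#' @param samples List of [methylome_sample()].
#' @param gene_bodies `GRanges` with mcols name covering the genes.
#' @param n_perm Permutations (default 999).
#' @param seed Seed.
#' @return data.frame: gene, r_pb, perm_p, n_carriers, skipped.
#' @export
methylation_independence_check <- function(selected_genes, variant_table,
                                           samples, gene_bodies,
                                           n_perm = 999L, seed = 1L) {
  sample_ids <- vapply(samples, `[[`, character(1), "sample_id")
  meth <- region_methylation_matrix(gene_bodies, samples)
  rownames(meth) <- mcols(gene_bodies)$name
  set.seed(seed)
  res <- lapply(selected_genes, function(g) {
    if (!g %in% rownames(meth)) {
      return(data.frame(
        gene = g, r_pb = NA_real_, perm_p = NA_real_,
        n_carriers = NA_integer_, skipped = TRUE
      ))
    }
    carrier <- as.numeric(
      sample_ids %in% variant_table$sample[variant_table$gene == g]
    )
    m <- meth[g, ]
    ok <- is.finite(m)
    carrier <- carrier[ok]
    m <- m[ok]
    if (sum(carrier) == 0 || sum(carrier) == length(carrier) ||
      stats::sd(m) == 0) {
      return(data.frame(
        gene = g, r_pb = NA_real_, perm_p = NA_real_,
        n_carriers = as.integer(sum(carrier)), skipped = TRUE
      ))
    }
    pr <- perm_cor_p(m, carrier, stats::cor, n_perm)
    data.frame(
      gene = g, r_pb = pr$stat, perm_p = pr$p,
      n_carriers = as.integer(sum(carrier)), skipped = FALSE
    )
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(
      gene = character(), r_pb = numeric(), perm_p = numeric(),
      n_carriers = integer(), skipped = logical()
    )
  }
  rownames(out) <- NULL
  out
}
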