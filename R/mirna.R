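# miRNA differential expression and integration with CpG methylation and
# target mRNA expression.

#' Normalize miRNA counts to counts per million
#'
#' Each column is divided by its total count and scaled to one million.
#'
#' @param counts Non-negative integer matrix (miRNA x samples).
#' @return Numeric CPM matrix.
#' @export
normalize_mirna <- function(counts) {
  stopifnot(all(counts >= 0))
  tot <- colSums(counts)
  if (any(tot == 0)) {
    stop(
      "zero total count in sample(s): ",
      paste(colnames(counts)[tot == 0], collapse = ", ")
    )
  }
  sweep(counts, 2, tot, "/") * 1e6
}

#' Differential miRNA expression test
#'
#' P-values come from a negative-binomial Wald test (DESeq2 with default
#' median-of-ratios size factors and local dispersion fit). The reported
#' fold change is the ratio of group mean CPM with a 0.5 pseudocount.
#' A miRNA is a DEmiR iff fold change > `fc_threshold` or <
#' 1/`fc_threshold`, unadjusted p < `p_threshold`, and it is expressed
#' (nonzero raw count) in at least `expressed_min` of the samples.
#'
#' @param counts Raw count matrix (miRNA x samples).
#' @param groups Group label per column ("RA"/"OA").
#' @param fc_threshold Fold-change threshold (default 2).
#' @param p_threshold Unadjusted p threshold (default 0.05).
#' @param expressed_min Minimum expressed fraction (default 0.5).
#' @return data.frame: mirna, fold_change (RA/OA), p, expressed_fraction,
#'   is_demir. miRNAs with zero counts in all samples are excluded.
#' @export
test_demir <- function(counts, groups, fc_threshold = 2,
                       p_threshold = 0.05, expressed_min = 0.5) {
  check_groups(groups)
  if (sum(groups == "RA") < 3 || sum(groups == "OA") < 3) {
    stop("each group needs at least 3 samples")
  }
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  mode(counts) <- "integer"
  coldata <- S4Vectors::DataFrame(
    group = factor(groups, levels = c("OA", "RA"))
  )
  dds <- DESeq2::DESeqDataSetFromMatrix(counts, coldata, ~group)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds, contrast = c("group", "RA", "OA"))
  cpm <- normalize_mirna(counts)
  ra <- groups == "RA"
  fc <- (rowMeans(cpm[, ra, drop = FALSE]) + 0.5) /
    (rowMeans(cpm[, !ra, drop = FALSE]) + 0.5)
  expressed_fraction <- rowMeans(counts > 0)
  p <- res$pvalue
  p[is.na(p)] <- 1
  is_demir <- (fc > fc_threshold | fc < 1 / fc_threshold) &
    p < p_threshold & expressed_fraction >= expressed_min
  data.frame(
    mirna = rownames(counts),
    fold_change = fc,
    p = p,
    expressed_fraction = expressed_fraction,
    is_demir = is_demir,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Spearman correlation with average-rank ties
spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# permutation p for a correlation statistic by sample shuffling (add-one)
perm_cor_p <- function(x, y, stat_fun, n_perm, two_sided = TRUE) {
  obs <- stat_fun(x, y)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    r <- stat_fun(x, sample(y))
    ok <- if (two_sided) abs(r) >= abs(obs) else r <= obs
    if (isTRUE(ok)) hits <- hits + 1L
  }
  list(stat = obs, p = perm_pvalue(hits, n_perm))
}

#' Correlate CpG methylation with miRNA expression
#'
#' For each differentially expressed miRNA, every CpG within the miRNA gene
#' body plus `upstream` bp strand-aware upstream is tested: Spearman rho of
#' per-sample beta versus normalized (CPM) expression, with a seeded
#' sample-shuffling permutation p (add-one). A pair is retained iff
#' |rho| > `rho_threshold` and p < `p_threshold`.
#'
#' @param samples List of [methylome_sample()] (same subjects as the count
#'   columns, in column order).
#' @param counts Raw miRNA count matrix.
#' @param demirs Character vector of miRNA names to test.
#' @param mirna_genes `GRanges` of miRNA genes (mcols name).
#' @param upstream Upstream window in bp (default 5000).
#' @param min_cov Minimum coverage in every sample for a CpG to be tested.
#' @param n_perm Permutations (default 999).
#' @param rho_threshold,p_threshold Retention thresholds.
#' @param seed Seed.
#' @return data.frame: mirna, chrom, pos, spearman_rho, perm_p, retained.
#' @export
correlate_cpg_mirna <- function(samples, counts, demirs, mirna_genes,
                                upstream = 5000L, min_cov = 5L,
                                n_perm = 999L, rho_threshold = 0.5,
                                p_threshold = 0.05, seed = 1L) {
  if (length(samples) < 4) stop("fewer than 4 paired samples")
  stopifnot(length(samples) == ncol(counts))
  cpm <- normalize_mirna(counts)
  cc <- align_cohort_counts(samples, min_cov)
  betas <- cc$meth / cc$cov
  cg <- GenomicRanges::GRanges(
    cc$chrom, IRanges::IRanges(cc$pos + 1, cc$pos + 1)
  )
  set.seed(seed)
  n <- ncol(counts)
  rows <- list()
  for (mir in demirs) {
    gi <- which(mcols(mirna_genes)$name == mir)
    if (length(gi) == 0) next
    g <- mirna_genes[gi]
    win <- GenomicRanges::promoters(
      g,
      upstream = upstream,
      downstream = GenomicRanges::width(g)
    )
    hit <- which(GenomicRanges::countOverlaps(cg, win) > 0)
    if (length(hit) == 0) next
    y <- cpm[mir, ]
    ry <- rank(y)
    if (stats::sd(ry) == 0) next
    ys <- (ry - mean(ry)) / stats::sd(ry)
    # one permutation panel per miRNA, shared by all its CpGs
    perm_ys <- vapply(
      seq_len(n_perm), function(p) sample(ys), numeric(n)
    )
    for (i in hit) {
      rx <- rank(betas[i, ])
      if (stats::sd(rx) == 0) {
        rows[[length(rows) + 1]] <- data.frame(
          mirna = mir, chrom = cc$chrom[i], pos = cc$pos[i],
          spearman_rho = NA_real_, perm_p = NA_real_, retained = FALSE,
          stringsAsFactors = FALSE
        )
        next
      }
      xs <- (rx - mean(rx)) / stats::sd(rx)
      rho <- sum(xs * ys) / (n - 1)
      perm_rho <- as.numeric(crossprod(perm_ys, xs)) / (n - 1)
      p <- perm_pvalue(sum(abs(perm_rho) >= abs(rho)), n_perm)
      rows[[length(rows) + 1]] <- data.frame(
        mirna = mir, chrom = cc$chrom[i], pos = cc$pos[i],
        spearman_rho = rho, perm_p = p,
        retained = abs(rho) > rho_threshold && p < p_threshold,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) {
    return(data.frame(
      mirna = character(), chrom = character(), pos = integer(),
      spearman_rho = numeric(), perm_p = numeric(), retained = logical()
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlate miRNAs with their predicted target mRNAs
#'
#' Per predicted (miRNA, gene) pair, Spearman rho between normalized miRNA
#' expression and gene expression; retained iff rho < 0 and one-sided
#' permutation p < `p_threshold` (seeded, add-one). Pairs referencing
#' unknown identifiers are skipped with a warning, pairs with a constant
#' vector are skipped silently (flagged).
#'
#' @param counts Raw miRNA counts.
#' @param expr Gene expression matrix (same sample order).
#' @param predicted_pairs data.frame (mirna, gene).
#' @param n_perm Permutations.
#' @param p_threshold Retention threshold.
#' @param seed Seed.
#' @return data.frame: mirna, gene, spearman_rho, perm_p, retained, skipped.
#' @export
correlate_mirna_targets <- function(counts, expr, predicted_pairs,
                                    n_perm = 999L, p_threshold = 0.05,
                                    seed = 1L) {
  stopifnot(ncol(counts) == ncol(expr))
  cpm <- normalize_mirna(counts)
  set.seed(seed)
  res <- lapply(seq_len(nrow(predicted_pairs)), function(i) {
    mir <- predicted_pairs$mirna[i]
    gene <- predicted_pairs$gene[i]
    if (!mir %in% rownames(cpm) || !gene %in% rownames(expr)) {
      warning("unknown id in predicted pair: ", mir, " / ", gene)
      return(NULL)
    }
    x <- cpm[mir, ]
    y <- expr[gene, ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(
        mirna = mir, gene = gene, spearman_rho = NA_real_,
        perm_p = NA_real_, retained = FALSE, skipped = TRUE
      ))
    }
    pr <- perm_cor_p(x, y, spearman_rho, n_perm, two_sided = FALSE)
    data.frame(
      mirna = mir, gene = gene, spearman_rho = pr$stat, perm_p = pr$p,
      retained = pr$stat < 0 && pr$p < p_threshold, skipped = FALSE
    )
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0) {
    return(data.frame(
      mirna = character(), gene = character(), spearman_rho = numeric(),
      perm_p = numeric(), retained = logical(), skipped = logical()
    ))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
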