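# LMR-target enrichment: differential-expression ranking, LMR gene-set
# construction, weighted Kolmogorov-Smirnov running enrichment score with a
# gene-label permutation null, and per-LMR expression correlation.

#' Rank genes by signal-to-noise between groups
#'
#' Genes are scored by (mean_RA - mean_OA) / (sd_RA + sd_OA) with each
#' group's standard deviation floored at 0.2 |mean| (0.2 when the mean is
#' zero), the canonical GSEA convention, and ranked descending (top =
#' up in RA).
#'
#' @param expr Genes x samples matrix.
#' @param groups Character vector of group labels per column.
#' @return data.frame (gene, score) sorted descending by score.
#' @export
rank_genes_by_de <- function(expr, groups) {
  check_groups(groups)
  if (sum(groups == "RA") < 2 || sum(groups == "OA") < 2) {
    stop("each group needs at least 2 samples")
  }
  ra <- groups == "RA"
  m1 <- rowMeans(expr[, ra, drop = FALSE])
  m2 <- rowMeans(expr[, !ra, drop = FALSE])
  s1 <- apply(expr[, ra, drop = FALSE], 1, stats::sd)
  s2 <- apply(expr[, !ra, drop = FALSE], 1, stats::sd)
  s1 <- pmax(s1, ifelse(m1 != 0, 0.2 * abs(m1), 0.2))
  s2 <- pmax(s2, ifelse(m2 != 0, 0.2 * abs(m2), 0.2))
  score <- (m1 - m2) / (s1 + s2)
  out <- data.frame(
    gene = rownames(expr), score = score, stringsAsFactors = FALSE
  )
  out[order(-out$score), , drop = FALSE]
}

#' Build the LMR target gene set
#'
#' A gene belongs to the set iff an LMR overlaps its gene body, or the
#' gene's TSS lies within `window` bp downstream (strand-aware with respect
#' to the gene: the LMR sits on the gene's 5' side) of an LMR end.
#'
#' @param specific_lmrs `GRanges` of LMRs.
#' @param genes Gene models `GRanges` with mcols name and tss.
#' @param window Distance in bp (default 5000).
#' @return Character vector of gene names.
#' @export
build_lmr_gene_set <- function(specific_lmrs, genes, window = 5000L) {
  if (length(specific_lmrs) == 0 || length(genes) == 0) {
    return(character(0))
  }
  body_hit <- GenomicRanges::countOverlaps(
    genes, specific_lmrs,
    ignore.strand = TRUE
  ) > 0
  tss <- mcols(genes)$tss
  strand <- as.character(GenomicRanges::strand(genes))
  lmr_start <- GenomicRanges::start(specific_lmrs) - 1
  lmr_end <- GenomicRanges::end(specific_lmrs)
  lmr_chr <- as.character(GenomicRanges::seqnames(specific_lmrs))
  g_chr <- as.character(GenomicRanges::seqnames(genes))
  tss_hit <- vapply(seq_along(genes), function(i) {
    same <- lmr_chr == g_chr[i]
    if (!any(same)) {
      return(FALSE)
    }
    if (strand[i] == "-") {
      # upstream of a minus-strand gene = to the right of its TSS
      any(same & lmr_start >= tss[i] & lmr_start - tss[i] <= window)
    } else {
      any(same & lmr_end <= tss[i] & tss[i] - lmr_end <= window)
    }
  }, logical(1))
  mcols(genes)$name[body_hit | tss_hit]
}

# weighted KS running enrichment score (weight exponent 1 on |score|);
# returns the signed maximum deviation from zero and the running sum
running_es <- function(scores, in_set) {
  n <- length(scores)
  nh <- sum(in_set)
  if (nh == 0 || nh == n) {
    return(list(es = 0, running = rep(0, n)))
  }
  w <- abs(scores) * in_set
  sw <- sum(w)
  if (sw == 0) w[in_set] <- 1 / nh else w <- w / sw
  miss <- (!in_set) / (n - nh)
  running <- cumsum(w - miss)
  i <- which.max(abs(running))
  list(es = running[i], running = running)
}

#' GSEA-style enrichment of a gene set in a ranked list
#'
#' Computes the weighted Kolmogorov-Smirnov running enrichment score
#' (weight exponent 1 on |score|, ES = signed maximum deviation from zero)
#' of the gene set in the ranking, a null ES sample by seeded gene-label
#' permutation, the normalized ES (observed ES over the mean same-sign null
#' magnitude), the add-one permutation p, and an FDR q estimated from the
#' null NES distribution.
#'
#' @param ranking data.frame (gene, score) from [rank_genes_by_de()].
#' @param gene_set Character vector, subset of the ranked genes.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed.
#' @return List: es, nes, running (vector), perm_scores, perm_p, fdr_q,
#'   n_perm.
#' @export
lmr_target_gsea <- function(ranking, gene_set, n_perm = 999L, seed = 1L) {
  genes <- ranking$gene
  in_set <- genes %in% gene_set
  if (!any(in_set)) stop("gene set empty or disjoint from the ranked universe")
  obs <- running_es(ranking$score, in_set)
  nh <- sum(in_set)
  set.seed(seed)
  perm_scores <- vapply(seq_len(n_perm), function(i) {
    pick <- sample.int(length(genes), nh)
    flag <- logical(length(genes))
    flag[pick] <- TRUE
    running_es(ranking$score, flag)$es
  }, numeric(1))
  same_sign <- perm_scores[sign(perm_scores) == sign(obs$es)]
  nes <- if (length(same_sign) > 0) {
    obs$es / mean(abs(same_sign))
  } else {
    sign(obs$es) * Inf
  }
  hits <- if (obs$es >= 0) {
    sum(perm_scores >= obs$es)
  } else {
    sum(perm_scores <= obs$es)
  }
  perm_p <- perm_pvalue(hits, n_perm)
  # FDR q from the normalized null: share of null NES magnitudes at least
  # as extreme as the observed NES (single-set family)
  fdr_q <- if (is.finite(nes)) {
    null_nes <- perm_scores / mean(abs(same_sign))
    min(1, mean(abs(null_nes) >= abs(nes)))
  } else {
    perm_p
  }
  list(
    es = obs$es, nes = nes, running = obs$running,
    perm_scores = perm_scores, perm_p = perm_p, fdr_q = min(fdr_q, 1),
    n_perm = n_perm
  )
}

#' Assign LMRs to their nearest gene by TSS distance
#'
#' @param lmrs `GRanges` of LMRs.
#' @param genes Gene models `GRanges` (mcols name, tss).
#' @return Character vector of gene names, one per LMR (ties broken by
#'   smaller genomic start).
#' @export
nearest_gene_by_tss <- function(lmrs, genes) {
  centers <- (GenomicRanges::start(lmrs) + GenomicRanges::end(lmrs)) %/% 2
  l_chr <- as.character(GenomicRanges::seqnames(lmrs))
  g_chr <- as.character(GenomicRanges::seqnames(genes))
  tss <- mcols(genes)$tss
  starts <- GenomicRanges::start(genes)
  vapply(seq_along(lmrs), function(i) {
    cand <- which(g_chr == l_chr[i])
    if (length(cand) == 0) {
      return(NA_character_)
    }
    d <- abs(tss[cand] - centers[i])
    best <- cand[order(d, starts[cand])][1]
    mcols(genes)$name[best]
  }, character(1))
}

#' Correlate LMR methylation with expression of matched genes
#'
#' Pearson correlation of each LMR's per-sample mean beta with its matched
#' gene's expression; permutation p by sample-label shuffling (seeded,
#' add-one). Pairs are retained iff |r| > `r_threshold` and p <
#' `p_threshold`; direction is recorded. Pairs with a constant methylation
#' or expression vector are skipped.
#'
#' @param lmr_meth LMRs x samples matrix of per-sample mean beta.
#' @param expr Genes x samples matrix (same sample order).
#' @param pairs data.frame (lmr, gene): lmr is a rowname/index of
#'   `lmr_meth`, gene a rowname of `expr`.
#' @param n_perm Permutations (default 999).
#' @param r_threshold,p_threshold Retention thresholds.
#' @param seed Seed.
#' @return data.frame: lmr, gene, pearson_r, perm_p, direction, retained,
#'   skipped.
#' @export
correlate_lmr_expression <- function(lmr_meth, expr, pairs, n_perm = 999L,
                                     r_threshold = 0.5, p_threshold = 0.05,
                                     seed = 1L) {
  stopifnot(ncol(lmr_meth) == ncol(expr))
  if (ncol(lmr_meth) < 4) stop("at least 4 paired samples required")
  set.seed(seed)
  n <- ncol(expr)
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    lm_row <- pairs$lmr[i]
    gx_row <- pairs$gene[i]
    x <- lmr_meth[lm_row, ]
    y <- expr[gx_row, ]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]
    y <- y[ok]
    if (length(x) < 4 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(data.frame(
        lmr = as.character(lm_row), gene = as.character(gx_row),
        pearson_r = NA_real_, perm_p = NA_real_,
        direction = NA_character_, retained = FALSE, skipped = TRUE
      ))
    }
    r <- stats::cor(x, y)
    hits <- sum(vapply(seq_len(n_perm), function(p) {
      abs(stats::cor(x, sample(y))) >= abs(r)
    }, logical(1)))
    p <- perm_pvalue(hits, n_perm)
    data.frame(
      lmr = as.character(lm_row), gene = as.character(gx_row),
      pearson_r = r, perm_p = p,
      direction = if (r < 0) "negative" else "positive",
      retained = abs(r) > r_threshold && p < p_threshold,
      skipped = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-sample mean methylation of a set of regions
#'
#' @param regions `GRanges`.
#' @param samples List of [methylome_sample()].
#' @return Regions x samples matrix of mean beta (coverage-weighted within
#'   each region).
#' @export
region_methylation_matrix <- function(regions, samples) {
  out <- vapply(samples, function(s) {
    sites <- s$sites
    cg <- GenomicRanges::GRanges(
      sites$chrom, IRanges::IRanges(sites$pos + 1, sites$pos + 1)
    )
    hits <- GenomicRanges::findOverlaps(cg, regions)
    v <- rep(NA_real_, length(regions))
    if (length(hits) > 0) {
      mm <- tapply(sites$meth[queryHits(hits)], subjectHits(hits), sum)
      cc <- tapply(sites$cov[queryHits(hits)], subjectHits(hits), sum)
      v[as.integer(names(mm))] <- mm / cc
    }
    v
  }, numeric(length(regions)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(regions))
  rownames(out) <- if (!is.null(mcols(regions)$name)) {
    mcols(regions)$name
  } else {
    sprintf("region_%04d", seq_along(regions))
  }
  colnames(out) <- vapply(samples, `[[`, character(1), "sample_id")
  out
}
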