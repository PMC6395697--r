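# Disease-specific LMR calling, profiling/clustering, sample clustering by
# LMR overlap, genomic annotation, and enhancer overlap enrichment.

lmrs_only <- function(gr) {
  if (length(gr) == 0) {
    return(gr)
  }
  if (!is.null(mcols(gr)$klass)) gr[mcols(gr)$klass == "LMR"] else gr
}

#' Call group-specific LMRs
#'
#' Per-sample LMRs are merged into consensus regions by single-linkage on
#' >= 1 bp overlap; a consensus region is "detected in" a sample iff at
#' least `min_overlap_frac` of one of that sample's LMRs overlaps it (>= 1
#' bp by default). A consensus region is group-specific iff detected in
#' more than `min_support` samples of that group (default > 2, i.e. >= 3)
#' and in no sample of the other group.
#'
#' @param lmrs_by_sample Named list of `GRanges` (per-sample LMR calls; if a
#'   `klass` column is present only LMR rows are used).
#' @param groups Named character vector sample id -> group ("RA"/"OA").
#' @param min_support Minimum same-group detection count minus one; a
#'   region must be detected in strictly more than this many samples
#'   (default 2).
#' @return A list with two `specific_region_set` objects (`RA`, `OA`), each
#'   a `GRanges` with mcols n_ra_detected, n_oa_detected, plus the full
#'   consensus `GRanges` as element `consensus`.
#' @export
call_group_specific_lmrs <- function(lmrs_by_sample, groups,
                                     min_support = 2L) {
  ids <- names(lmrs_by_sample)
  check_groups(groups)
  grp <- groups[ids]
  if (!any(grp == "RA") || !any(grp == "OA")) {
    stop("both groups must be represented among the samples")
  }
  per <- lapply(lmrs_by_sample, lmrs_only)
  nonempty <- vapply(per, length, 1L) > 0
  if (!any(nonempty)) stop("no LMRs in any sample")
  all_lmrs <- do.call(c, unname(lapply(per[nonempty], GenomicRanges::granges)))
  consensus <- GenomicRanges::reduce(all_lmrs, min.gapwidth = 0L)
  detected <- vapply(per, function(g) {
    GenomicRanges::countOverlaps(consensus, g, minoverlap = 1L) > 0
  }, logical(length(consensus)))
  if (is.null(dim(detected))) detected <- matrix(detected, nrow = 1)
  n_ra <- rowSums(detected[, grp == "RA", drop = FALSE])
  n_oa <- rowSums(detected[, grp == "OA", drop = FALSE])
  mcols(consensus)$n_ra_detected <- n_ra
  mcols(consensus)$n_oa_detected <- n_oa
  ra <- consensus[n_ra > min_support & n_oa == 0]
  oa <- consensus[n_oa > min_support & n_ra == 0]
  mcols(ra)$group <- if (length(ra)) "RA" else character(0)
  mcols(oa)$group <- if (length(oa)) "OA" else character(0)
  list(RA = ra, OA = oa, consensus = consensus)
}

# per-sample mean beta of CpGs falling in each of a set of ranges
mean_beta_in_ranges <- function(sample, ranges) {
  s <- sample$sites
  cg <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1, s$pos + 1))
  hits <- GenomicRanges::findOverlaps(cg, ranges)
  out <- rep(NA_real_, length(ranges))
  if (length(hits) > 0) {
    b <- s$meth[queryHits(hits)] / s$cov[queryHits(hits)]
    agg <- tapply(b, subjectHits(hits), mean)
    out[as.integer(names(agg))] <- agg
  }
  out
}

#' Profile specific LMRs around their centers and cluster the profiles
#'
#' Mean methylation is computed in 100-bp bins spanning +/- 1.5 kb from each
#' region center, per group (averaging per-sample beta values of the CpGs in
#' each bin across the group's samples). The row-concatenated group
#' profiles (RA bins then OA bins) are clustered by k-means with seeded
#' deterministic initialization (50 restarts, best within-cluster sum of
#' squares kept).
#'
#' @param regions A `GRanges` of specific LMRs.
#' @param samples List of [methylome_sample()] objects.
#' @param k Number of clusters (default 2).
#' @param flank Half-window in bp (default 1500).
#' @param bin_width Bin width in bp (default 100).
#' @param seed Seed for the k-means restarts.
#' @return List: `profile` (matrix regions x 2*bins, attr "groups"),
#'   `cluster` (integer vector, NA for dropped rows), `centers`.
#' @export
profile_and_cluster_lmrs <- function(regions, samples, k = 2L,
                                     flank = 1500L, bin_width = 100L,
                                     seed = 1L) {
  stopifnot(length(regions) > 0, k >= 1)
  n_bins <- as.integer(2 * flank / bin_width)
  centers <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2
  groups <- vapply(samples, `[[`, character(1), "group")
  # one GRanges covering every (region, bin) combination
  bin_off <- rep((seq_len(n_bins) - 1L) * bin_width, each = length(regions))
  bs <- rep(centers - flank, n_bins) + bin_off
  bin_start <- pmax(bs + 1, 1)
  bin_end <- pmax(bs + bin_width, bin_start - 1) # bins before 0 are empty
  bins_gr <- GenomicRanges::GRanges(
    rep(as.character(GenomicRanges::seqnames(regions)), n_bins),
    IRanges::IRanges(start = bin_start, end = bin_end)
  )
  prof_by_group <- lapply(c("RA", "OA"), function(g) {
    gs <- samples[groups == g]
    acc <- array(NA_real_, c(length(regions), n_bins, length(gs)))
    for (si in seq_along(gs)) {
      v <- mean_beta_in_ranges(gs[[si]], bins_gr)
      acc[, , si] <- matrix(v, length(regions), n_bins)
    }
    apply(acc, c(1, 2), mean, na.rm = TRUE)
  })
  prof <- do.call(cbind, prof_by_group)
  prof[is.nan(prof)] <- NA_real_
  colnames(prof) <- c(
    sprintf("RA_bin%02d", seq_len(n_bins)),
    sprintf("OA_bin%02d", seq_len(n_bins))
  )
  all_missing <- rowSums(!is.na(prof)) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " region(s) with all-missing profile dropped")
  }
  cluster <- rep(NA_integer_, length(regions))
  keep <- which(!all_missing)
  km_centers <- NULL
  if (length(keep) > 0) {
    x <- prof[keep, , drop = FALSE]
    # impute residual missing bins with the row mean
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (i in seq_len(nrow(x))) x[i, is.na(x[i, ])] <- rm_[i]
    kk <- min(k, nrow(unique(x)))
    set.seed(seed)
    km <- suppressWarnings(
      stats::kmeans(x, centers = kk, nstart = 50, iter.max = 100)
    )
    cluster[keep] <- km$cluster
    km_centers <- km$centers
  }
  attr(prof, "groups") <- c(
    rep("RA", n_bins), rep("OA", n_bins)
  )
  list(profile = prof, cluster = cluster, centers = km_centers)
}

#' Jaccard similarity of samples based on LMR base-pair overlap
#'
#' Jaccard(a, b) is the overlapping base pairs divided by the union base
#' pairs of the two samples' (reduced) LMR sets. Samples are clustered
#' hierarchically with average linkage on distance 1 - J.
#'
#' @param lmrs_by_sample Named list of `GRanges`.
#' @return List: `jaccard` (symmetric matrix), `hclust` (stats::hclust),
#'   `dendrogram_newick` (character, via ape).
#' @export
jaccard_sample_clustering <- function(lmrs_by_sample) {
  ids <- names(lmrs_by_sample)
  n <- length(ids)
  stopifnot(n >= 2)
  sets <- lapply(lmrs_by_sample, function(g) {
    GenomicRanges::reduce(GenomicRanges::granges(lmrs_only(g)))
  })
  J <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sets[[i]]
      b <- sets[[j]]
      if (length(a) == 0 && length(b) == 0) {
        warning(
          "two samples with empty LMR sets (", ids[i], ", ", ids[j],
          "); Jaccard set to 1 by convention"
        )
        J[i, j] <- J[j, i] <- 1
        next
      }
      if (length(a) == 0 || length(b) == 0) {
        J[i, j] <- J[j, i] <- 0
        next
      }
      inter <- sum(IRanges::width(GenomicRanges::intersect(a, b)))
      uni <- sum(IRanges::width(GenomicRanges::union(a, b)))
      J[i, j] <- J[j, i] <- inter / uni
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - J), method = "average")
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(jaccard = J, hclust = hc, dendrogram_newick = nwk)
}

# expand comma-string exon blocks of a gene models GRanges
gene_exons <- function(genes, i) {
  es <- as.numeric(strsplit(mcols(genes)$exon_starts[i], ",")[[1]])
  ee <- as.numeric(strsplit(mcols(genes)$exon_ends[i], ",")[[1]])
  stopifnot(length(es) == length(ee), all(es < ee))
  data.frame(start = es, end = ee)
}

#' Read gene models from a BED12-like file
#'
#' Columns: chrom, start, end, name, score, strand, thickStart, thickEnd,
#' rgb, blockCount, blockSizes, blockStarts (block starts relative to the
#' record start, BED12 convention).
#'
#' @param path Path to the BED12 file.
#' @return A `GRanges` with mcols name, tss, exon_starts, exon_ends
#'   (absolute 0-based comma strings).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12)) stop("gene model file is not BED12")
  m <- do.call(rbind, parts)
  start0 <- as.numeric(m[, 2])
  end0 <- as.numeric(m[, 3])
  strand <- m[, 6]
  sizes <- lapply(strsplit(m[, 11], ","), as.numeric)
  offs <- lapply(strsplit(m[, 12], ","), as.numeric)
  ex_s <- mapply(function(s, o) paste(s + o, collapse = ","),
    start0, offs
  )
  ex_e <- mapply(function(s, o, w) paste(s + o + w, collapse = ","),
    start0, offs, sizes
  )
  GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand,
    name = m[, 4],
    tss = ifelse(strand == "-", end0, start0),
    exon_starts = ex_s,
    exon_ends = ex_e
  )
}

#' Write gene models as BED12
#'
#' @param genes Gene models `GRanges` as produced by [read_gene_models()]
#'   or [simulate_expression_profiles()].
#' @param path Output path.
#' @export
write_gene_models <- function(genes, path) {
  lines <- vapply(seq_along(genes), function(i) {
    s0 <- GenomicRanges::start(genes)[i] - 1
    e0 <- GenomicRanges::end(genes)[i]
    ex <- gene_exons(genes, i)
    paste(
      as.character(GenomicRanges::seqnames(genes))[i], s0, e0,
      mcols(genes)$name[i], 0, as.character(GenomicRanges::strand(genes))[i],
      s0, e0, "0", nrow(ex),
      paste(ex$end - ex$start, collapse = ","),
      paste(ex$start - s0, collapse = ","),
      sep = "\t"
    )
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Annotate region positions relative to gene models
#'
#' Each region is classified by its midpoint with precedence
#' promoter > exon > intron > intergenic. The promoter is TSS -1000/+100 bp
#' (strand-aware). For intronic regions the intron index is counted 1-based
#' from the 5' end of the transcript, and the relative position is the
#' strand-aware distance from the TSS divided by the transcript length,
#' clipped to [0, 1].
#'
#' @param regions `GRanges` of regions.
#' @param genes Gene models `GRanges` (mcols name, tss, exon_starts,
#'   exon_ends).
#' @param promoter_up,promoter_down Promoter window around the TSS in bp.
#' @return data.frame: region index, chrom, midpoint, category, gene,
#'   intron_index, relative_position.
#' @export
annotate_lmr_position <- function(regions, genes,
                                  promoter_up = 1000L, promoter_down = 100L) {
  n <- length(regions)
  mid <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2
  chrom <- as.character(GenomicRanges::seqnames(regions))
  out <- data.frame(
    region = seq_len(n), chrom = chrom, midpoint = mid,
    category = "intergenic", gene = NA_character_,
    intron_index = NA_integer_, relative_position = NA_real_,
    stringsAsFactors = FALSE
  )
  known_chroms <- unique(as.character(GenomicRanges::seqnames(genes)))
  missing_chr <- !chrom %in% known_chroms
  if (any(missing_chr)) {
    warning(
      sum(missing_chr),
      " region(s) on chromosomes absent from the gene models; intergenic"
    )
  }
  g_chr <- as.character(GenomicRanges::seqnames(genes))
  g_strand <- as.character(GenomicRanges::strand(genes))
  g_tss <- mcols(genes)$tss
  g_start <- GenomicRanges::start(genes) - 1
  g_end <- GenomicRanges::end(genes)
  for (i in seq_len(n)) {
    if (missing_chr[i]) next
    m <- mid[i]
    cand <- which(g_chr == chrom[i])
    best <- NULL # (precedence rank, gene index, extras)
    for (gi in cand) {
      tss <- g_tss[gi]
      plus <- g_strand[gi] == "+"
      prom <- if (plus) {
        c(tss - promoter_up, tss + promoter_down)
      } else {
        c(tss - promoter_down, tss + promoter_up)
      }
      in_prom <- m >= prom[1] && m < prom[2]
      in_body <- m >= g_start[gi] && m < g_end[gi]
      if (!in_prom && !in_body) next
      rank <- NA_integer_
      intr <- NA_integer_
      if (in_prom) {
        rank <- 1L
      } else {
        ex <- gene_exons(genes, gi)
        in_exon <- any(m >= ex$start & m < ex$end)
        if (in_exon) {
          rank <- 2L
        } else {
          rank <- 3L
          # introns between consecutive exons in genomic order
          o <- order(ex$start)
          intr_start <- ex$end[o][-nrow(ex)]
          intr_end <- ex$start[o][-1]
          gidx <- which(m >= intr_start & m < intr_end)
          if (length(gidx) == 1) {
            intr <- if (plus) gidx else (nrow(ex) - gidx)
          } else {
            rank <- 3L
            intr <- NA_integer_
          }
        }
      }
      if (is.null(best) || rank < best$rank) {
        best <- list(rank = rank, gi = gi, intron = intr)
      }
    }
    if (!is.null(best)) {
      gi <- best$gi
      len <- g_end[gi] - g_start[gi]
      rel <- (m - g_tss[gi]) / len
      if (g_strand[gi] == "-") rel <- -rel
      out$category[i] <- c("promoter", "exon", "intron")[best$rank]
      out$gene[i] <- mcols(genes)$name[gi]
      out$intron_index[i] <- best$intron
      out$relative_position[i] <- min(max(rel, 0), 1)
    }
  }
  out
}

#' Enhancer overlap enrichment of specific LMRs
#'
#' For each enhancer set (cell type), computes the fraction of RA- and
#' OA-specific LMRs overlapping at least 1 bp of an enhancer, their ratio,
#' and the p-value of a Pearson chi-squared test (1 df, no continuity
#' correction) on the 2x2 overlap-by-group table.
#'
#' @param ra_regions,oa_regions `GRanges` of specific LMRs.
#' @param enhancers_by_celltype Named list of enhancer `GRanges`.
#' @return data.frame: celltype, p_ra, p_oa, ratio (Inf when p_oa = 0),
#'   chi2_p.
#' @export
enhancer_overlap_ratio <- function(ra_regions, oa_regions,
                                   enhancers_by_celltype) {
  stopifnot(length(ra_regions) > 0, length(oa_regions) > 0)
  res <- lapply(names(enhancers_by_celltype), function(ct) {
    enh <- enhancers_by_celltype[[ct]]
    ra_hit <- sum(GenomicRanges::countOverlaps(ra_regions, enh) > 0)
    oa_hit <- sum(GenomicRanges::countOverlaps(oa_regions, enh) > 0)
    n_ra <- length(ra_regions)
    n_oa <- length(oa_regions)
    p_ra <- ra_hit / n_ra
    p_oa <- oa_hit / n_oa
    tab <- matrix(
      c(ra_hit, n_ra - ra_hit, oa_hit, n_oa - oa_hit), 2, 2
    )
    chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(
      celltype = ct, p_ra = p_ra, p_oa = p_oa,
      ratio = if (p_oa == 0) Inf else p_ra / p_oa,
      chi2_p = chi$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
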