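# Synthetic two-group WGBS cohort generator with full ground truth.
#
# The simulated genome is one synthetic chromosome with CpG spacing drawn
# i.i.d. geometric (mean `mean_spacing` bp), which reproduces a realistic CpG
# density without a reference sequence. Methylation emission is locus-driven:
# each background CpG is assigned once (per locus, shared by all samples) to
# a high- or low-methylation component, and every sample then draws its own
# beta from that component, so between-sample variability exists but the
# methylation landscape is conserved across individuals, as in real
# methylomes. Planted structure (PMDs, UMRs, LMRs, group-specific LMRs,
# variably methylated miRNA promoters, DMC/DVC sites) overrides the
# background emission at its loci.

#' Configuration for a synthetic cohort
#'
#' Defaults emulate the WGBS arm of a two-group synoviocyte study: 12 RA and
#' 8 OA methylomes at ~22x mean coverage, a bimodal background with ~20% of
#' CpGs in the low-to-intermediate component, megabase-scale PMDs, and
#' CpG-dense hypomethylated regions (UMRs >= 30 CpGs, LMRs < 30 CpGs), some
#' shared and some private to one group.
#'
#' @param n_ra,n_oa Samples per group.
#' @param n_cpg Number of CpGs on the simulated chromosome.
#' @param mean_cov Target mean read coverage (Poisson, truncated at >= 1).
#' @param mean_spacing Mean CpG spacing in bp.
#' @param n_pmd,pmd_cpgs Number and CpG size of planted PMDs (shared).
#' @param n_umr,umr_cpgs Number and CpG size of shared UMRs.
#' @param n_lmr,lmr_cpgs Number and CpG size of shared LMRs.
#' @param n_lmr_ra,n_lmr_oa Number of RA-/OA-specific LMRs.
#' @param penetrance Fraction of target-group samples hypomethylated at a
#'   group-specific LMR.
#' @param n_dmc Planted differentially methylated CpGs (half hyper in RA,
#'   half hypo).
#' @param dmc_delta Methylation difference at planted DMCs.
#' @param dmc_base Methylation of the low group at planted DMCs (the high
#'   group sits symmetrically at 1 - dmc_base).
#' @param n_dvc Planted differentially variable CpGs (half hypervariable in
#'   RA, half hypovariable).
#' @param n_genes,n_coupled_genes Total genes and genes whose expression is
#'   coupled to an RA-specific LMR.
#' @param gene_coupling_strength Slope (log2 units per unit methylation) of
#'   the expression coupling; positive values give negative
#'   methylation-expression dependence.
#' @param expr_noise_sd Residual log2 expression noise.
#' @param n_mirna,n_coupled_mirna Total miRNA genes and miRNAs whose
#'   expression is negatively coupled to promoter methylation. Coupled
#'   miRNAs sit on a planted variably methylated region (VMR) whose
#'   per-sample methylation level varies continuously across the cohort.
#' @param vmr_cpgs CpGs per planted VMR.
#' @param mirna_coupling_strength Log-scale slope of the miRNA coupling.
#' @param mirna_dispersion Negative-binomial dispersion of miRNA counts.
#' @param mirna_base_mean Baseline miRNA mean count.
#' @param mirna_group_fc Multiplicative RA/OA fold change planted on
#'   coupled miRNAs (1 = none).
#' @param n_mut_genes Genes in the exome layer.
#' @param mu_range Range of per-gene per-copy mutation probabilities.
#' @param n_excess_genes Genes with planted RA-specific mutation excess.
#' @param excess_factor Rate inflation of excess genes in RA samples.
#' @param rng_seed Master seed; all randomness flows from it.
#' @return A `cohort_config` list, validated.
#' @export
cohort_config <- function(n_ra = 12, n_oa = 8,
                          n_cpg = 1e5, mean_cov = 22, mean_spacing = 100,
                          n_pmd = 2, pmd_cpgs = 2000,
                          n_umr = 20, umr_cpgs = 40,
                          n_lmr = 40, lmr_cpgs = 15,
                          n_lmr_ra = 8, n_lmr_oa = 4,
                          penetrance = 1.0,
                          n_dmc = 200, dmc_delta = 0.3, dmc_base = 0.02,
                          n_dvc = 200,
                          n_genes = 200, n_coupled_genes = 10,
                          gene_coupling_strength = 4, expr_noise_sd = 0.25,
                          n_mirna = 110, n_coupled_mirna = 10, vmr_cpgs = 8,
                          mirna_coupling_strength = 3,
                          mirna_dispersion = 0.05, mirna_base_mean = 500,
                          mirna_group_fc = 1,
                          n_mut_genes = 200, mu_range = c(1e-5, 1e-4),
                          n_excess_genes = 2, excess_factor = 1e4,
                          rng_seed = 1) {
  cfg <- as.list(environment())
  with(cfg, {
    stopifnot(
      n_ra >= 1, n_oa >= 1, n_cpg >= 100, mean_cov > 0,
      dmc_delta > 0, dmc_delta < 1,
      penetrance >= 0, penetrance <= 1,
      all(mu_range >= 0), n_excess_genes <= n_mut_genes,
      n_coupled_mirna <= n_mirna, n_coupled_genes <= n_genes
    )
  })
  class(cfg) <- "cohort_config"
  cfg
}

# Allocate planted elements along the CpG index axis without overlap.
# PMDs are placed first at even quantiles; everything else fills the
# remaining space on an even grid with guard gaps.
plant_layout <- function(config) {
  n <- config$n_cpg
  gap <- 25L
  regions <- list()
  pmd_slots <- integer(0)
  if (config$n_pmd > 0) {
    centers <- round(seq(0.2, 0.8, length.out = config$n_pmd) * n)
    for (i in seq_len(config$n_pmd)) {
      s <- centers[i] - config$pmd_cpgs %/% 2
      regions[[length(regions) + 1]] <- data.frame(
        klass = "PMD", group = "shared",
        start_idx = s, end_idx = s + config$pmd_cpgs - 1L,
        penetrance = 1
      )
    }
  }
  pmd_df <- if (length(regions)) do.call(rbind, regions) else NULL
  in_pmd <- rep(FALSE, n)
  if (!is.null(pmd_df)) {
    for (i in seq_len(nrow(pmd_df))) {
      lo <- max(1L, pmd_df$start_idx[i] - gap)
      hi <- min(n, pmd_df$end_idx[i] + gap)
      in_pmd[lo:hi] <- TRUE
    }
  }
  free <- which(!in_pmd)
  # block requests: (klass, group, size, count)
  req <- rbind(
    data.frame(klass = "UMR", group = "shared", size = config$umr_cpgs,
      count = config$n_umr),
    data.frame(klass = "LMR", group = "shared", size = config$lmr_cpgs,
      count = config$n_lmr),
    data.frame(klass = "LMR", group = "RA", size = config$lmr_cpgs,
      count = config$n_lmr_ra),
    data.frame(klass = "LMR", group = "OA", size = config$lmr_cpgs,
      count = config$n_lmr_oa),
    data.frame(klass = "VMR", group = "shared", size = config$vmr_cpgs,
      count = config$n_coupled_mirna),
    data.frame(klass = "DMC", group = "site", size = 1,
      count = config$n_dmc),
    data.frame(klass = "DVC", group = "site", size = 1,
      count = config$n_dvc)
  )
  n_blocks <- sum(req$count)
  if (n_blocks > 0) {
    need <- sum(req$count * (req$size + gap))
    if (need > length(free)) {
      stop("planted elements exceed genome capacity; increase n_cpg")
    }
    # spread block anchors evenly over the free index positions
    anchors <- free[round(seq(1, length(free) - max(req$size) - 1,
      length.out = n_blocks
    ))]
    bi <- 1L
    for (r in seq_len(nrow(req))) {
      for (k in seq_len(req$count[r])) {
        s <- anchors[bi]
        bi <- bi + 1L
        regions[[length(regions) + 1]] <- data.frame(
          klass = req$klass[r], group = req$group[r],
          start_idx = s, end_idx = s + req$size[r] - 1L,
          penetrance = if (req$group[r] %in% c("RA", "OA")) {
            config$penetrance
          } else {
            1
          }
        )
      }
    }
  }
  out <- do.call(rbind, regions)
  if (is.null(out)) {
    out <- data.frame(
      klass = character(), group = character(),
      start_idx = integer(), end_idx = integer(), penetrance = numeric()
    )
  }
  out <- out[order(out$start_idx), , drop = FALSE]
  # overlap check: UMR/LMR/VMR/sites must not fall inside PMDs, and planted
  # blocks must not overlap each other
  if (nrow(out) > 1) {
    if (any(out$start_idx[-1] <= out$end_idx[-nrow(out)])) {
      stop("planted regions overlap inconsistently")
    }
  }
  if (any(out$start_idx < 1 | out$end_idx > n)) {
    stop("planted region outside the simulated genome")
  }
  rownames(out) <- NULL
  out$region_id <- sprintf(
    "%s_%s_%03d", out$klass, out$group, seq_len(nrow(out))
  )
  out
}

#' Simulate a two-group methylome cohort with ground truth
#'
#' Background CpGs follow a polarized locus-level mixture
#' (0.8 Beta(20, 2) high + 0.2 Beta(2, 20) low); PMD CpGs a dispersed
#' symmetric Beta(1.5, 1.5); UMR CpGs Beta(2, 38) (mean 0.05); LMR CpGs
#' Beta(6, 34) (mean 0.15). Group-specific LMRs are hypomethylated only in
#' penetrant samples of the target group. Coverage is Poisson(mean_cov)
#' truncated at >= 1 and methylated counts are Binomial(cov, beta). The run
#' is fully reproducible from `config$rng_seed`.
#'
#' @param config A [cohort_config()].
#' @return A list with `samples` (list of [methylome_sample()]) and `truth`
#'   (a `cohort_truth` list: CpG positions, planted region table with
#'   genomic coordinates and realized per-group support, DMC/DVC tables,
#'   per-sample VMR methylation levels, sample sheet).
#' @export
simulate_methylome_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(derive_seed(config$rng_seed, "methylome"))
  n <- config$n_cpg
  chrom <- "chrS"
  spacing <- stats::rgeom(n, 1 / config$mean_spacing) + 1L
  pos <- cumsum(spacing)
  layout <- plant_layout(config)

  # locus-level background component (shared by all samples)
  bg_low <- stats::runif(n) < 0.2

  klass_at <- rep("background", n)
  region_rows <- which(layout$group != "site")
  for (i in region_rows) {
    klass_at[layout$start_idx[i]:layout$end_idx[i]] <- layout$region_id[i]
  }
  dmc_rows <- which(layout$klass == "DMC")
  dvc_rows <- which(layout$klass == "DVC")
  dmc_idx <- layout$start_idx[dmc_rows]
  dvc_idx <- layout$start_idx[dvc_rows]

  # planted site directions: first half hyper (RA high), second half hypo
  dmc_dir <- rep(c("hyper", "hypo"), length.out = length(dmc_idx))
  dvc_dir <- rep(c("hyper", "hypo"), length.out = length(dvc_idx))
  dmc_lo <- config$dmc_base
  dmc_hi <- config$dmc_base + config$dmc_delta

  sample_info <- data.frame(
    sample_id = c(
      sprintf("RA_%02d", seq_len(config$n_ra)),
      sprintf("OA_%02d", seq_len(config$n_oa))
    ),
    group = c(rep("RA", config$n_ra), rep("OA", config$n_oa)),
    stringsAsFactors = FALSE
  )
  n_samp <- nrow(sample_info)

  # penetrance draws for group-specific regions (one Bernoulli per
  # region x target-group sample), before the per-sample emission loop
  spec_rows <- which(layout$group %in% c("RA", "OA"))
  penetrant <- matrix(FALSE, nrow(layout), n_samp,
    dimnames = list(layout$region_id, sample_info$sample_id)
  )
  for (i in spec_rows) {
    tgt <- which(sample_info$group == layout$group[i])
    penetrant[i, tgt] <- stats::runif(length(tgt)) < layout$penetrance[i]
  }

  # per-sample methylation level of each VMR (continuous across the cohort)
  vmr_rows <- which(layout$klass == "VMR")
  vmr_level <- matrix(NA_real_, length(vmr_rows), n_samp,
    dimnames = list(layout$region_id[vmr_rows], sample_info$sample_id)
  )
  if (length(vmr_rows) > 0) {
    vmr_level[, ] <- matrix(
      stats::runif(length(vmr_rows) * n_samp, 0.05, 0.95),
      length(vmr_rows), n_samp
    )
  }

  # locus-level true methylation, shared across samples: the methylation
  # landscape is conserved between individuals, who differ through
  # sampling noise and the planted group effects
  locus_beta <- numeric(n)
  bgh <- which(klass_at == "background" & !bg_low)
  bgl <- which(klass_at == "background" & bg_low)
  locus_beta[bgh] <- stats::rbeta(length(bgh), 20, 2)
  locus_beta[bgl] <- stats::rbeta(length(bgl), 2, 20)
  spec_high <- list() # background-level draws for non-penetrant samples
  for (i in region_rows) {
    ii <- layout$start_idx[i]:layout$end_idx[i]
    kl <- layout$klass[i]
    if (kl == "PMD") {
      locus_beta[ii] <- stats::rbeta(length(ii), 1.5, 1.5)
    } else if (kl == "UMR") {
      locus_beta[ii] <- stats::rbeta(length(ii), 2, 38)
    } else if (kl == "LMR") {
      locus_beta[ii] <- stats::rbeta(length(ii), 6, 34)
      if (layout$group[i] %in% c("RA", "OA")) {
        spec_high[[layout$region_id[i]]] <- stats::rbeta(length(ii), 20, 2)
      }
    }
    # VMR loci are drawn per sample below
  }
  # DVC loci: both groups share the same mean (0.5) so variability, not
  # level, separates them; the stable group sits tightly at the locus
  # value while the variable group is redrawn per sample from a strongly
  # bimodal distribution
  dvc_stable <- stats::rbeta(length(dvc_idx), 100, 100)
  samples <- vector("list", n_samp)
  for (s in seq_len(n_samp)) {
    grp <- sample_info$group[s]
    beta_true <- locus_beta
    for (i in spec_rows) {
      if (layout$klass[i] != "LMR") next
      if (!penetrant[i, s]) {
        ii <- layout$start_idx[i]:layout$end_idx[i]
        beta_true[ii] <- spec_high[[layout$region_id[i]]]
      }
    }
    for (vi in seq_along(vmr_rows)) {
      i <- vmr_rows[vi]
      ii <- layout$start_idx[i]:layout$end_idx[i]
      lev <- vmr_level[vi, s]
      beta_true[ii] <- stats::rbeta(length(ii), lev * 30, (1 - lev) * 30)
    }
    if (length(dmc_idx) > 0) {
      ra_val <- ifelse(dmc_dir == "hyper", dmc_hi, 1 - dmc_lo - config$dmc_delta)
      oa_val <- ifelse(dmc_dir == "hyper", dmc_lo, 1 - dmc_lo)
      beta_true[dmc_idx] <- if (grp == "RA") ra_val else oa_val
    }
    if (length(dvc_idx) > 0) {
      variable <- (grp == "RA") == (dvc_dir == "hyper")
      bv <- dvc_stable
      bv[variable] <- stats::rbeta(sum(variable), 0.2, 0.2)
      beta_true[dvc_idx] <- bv
    }
    u <- stats::runif(n)
    p0 <- stats::dpois(0, config$mean_cov)
    cov <- stats::qpois(p0 + u * (1 - p0), config$mean_cov)
    meth <- stats::rbinom(n, cov, beta_true)
    samples[[s]] <- methylome_sample(
      sample_info$sample_id[s], grp,
      data.frame(
        chrom = chrom, pos = pos, cov = as.integer(cov),
        meth = as.integer(meth), stringsAsFactors = FALSE
      )
    )
  }

  regions <- layout[layout$group != "site", , drop = FALSE]
  regions$start <- pos[regions$start_idx]
  regions$end <- pos[regions$end_idx] + 1L
  regions$n_ra_detected <- rep(NA_integer_, nrow(regions))
  regions$n_oa_detected <- rep(NA_integer_, nrow(regions))
  for (i in seq_len(nrow(regions))) {
    rid <- match(regions$region_id[i], layout$region_id)
    if (regions$group[i] %in% c("RA", "OA")) {
      regions$n_ra_detected[i] <-
        sum(penetrant[rid, sample_info$group == "RA"])
      regions$n_oa_detected[i] <-
        sum(penetrant[rid, sample_info$group == "OA"])
    } else {
      regions$n_ra_detected[i] <- config$n_ra
      regions$n_oa_detected[i] <- config$n_oa
    }
  }
  truth <- structure(list(
    chrom = chrom,
    positions = pos,
    regions = regions,
    dmc = if (length(dmc_idx)) {
      data.frame(
        idx = dmc_idx, pos = pos[dmc_idx], direction = dmc_dir,
        beta_ra = ifelse(dmc_dir == "hyper", dmc_hi, 1 - dmc_hi),
        beta_oa = ifelse(dmc_dir == "hyper", dmc_lo, 1 - dmc_lo)
      )
    } else {
      data.frame()
    },
    dvc = if (length(dvc_idx)) {
      data.frame(idx = dvc_idx, pos = pos[dvc_idx], direction = dvc_dir)
    } else {
      data.frame()
    },
    vmr_level = vmr_level,
    penetrant = penetrant,
    sample_info = sample_info
  ), class = "cohort_truth")
  list(samples = samples, truth = truth)
}

# mean beta of a sample over an index range
region_mean_beta <- function(sample, idx) {
  s <- sample$sites[idx, , drop = FALSE]
  sum(s$meth) / sum(s$cov)
}

#' Simulate gene models and an expression matrix coupled to LMR methylation
#'
#' Gene models (strand-alternating, three exons each) are laid out along the
#' simulated chromosome; the first `n_coupled_genes` are placed with their
#' TSS ~2 kb downstream of an RA-specific LMR and their log2 intensity
#' depends linearly (negatively for positive coupling strength) on that
#' LMR's per-sample mean methylation, plus Gaussian noise. Remaining genes
#' are log-normal background.
#'
#' @param config A [cohort_config()].
#' @param truth `cohort_truth` from [simulate_methylome_cohort()].
#' @param samples The simulated methylome samples.
#' @return List with `expr` (genes x samples matrix), `genes` (a `GRanges`
#'   of gene models with mcols name, tss, exon_starts, exon_ends), and
#'   `couplings` (data.frame gene, region_id, strength).
#' @export
simulate_expression_profiles <- function(config, truth, samples) {
  set.seed(derive_seed(config$rng_seed, "expression"))
  n_g <- config$n_genes
  n_c <- config$n_coupled_genes
  ra_lmrs <- truth$regions[
    truth$regions$klass == "LMR" & truth$regions$group == "RA", ,
    drop = FALSE
  ]
  if (n_c > 0 && nrow(ra_lmrs) == 0) {
    stop("coupled genes requested but no RA-specific LMR planted")
  }
  genome_end <- max(truth$positions) + 1e4
  gene_len <- 3000
  strands <- rep(c("+", "-"), length.out = n_g)
  starts <- numeric(n_g)
  # coupled genes adjacent to RA-specific LMRs (recycled if fewer LMRs)
  coupled_region <- character(0)
  if (n_c > 0) {
    lmr_pick <- ra_lmrs[rep(seq_len(nrow(ra_lmrs)), length.out = n_c), ]
    coupled_region <- lmr_pick$region_id
    for (i in seq_len(n_c)) {
      if (strands[i] == "+") {
        starts[i] <- lmr_pick$end[i] + 2000
      } else {
        starts[i] <- lmr_pick$start[i] - 2000 - gene_len
      }
    }
  }
  if (n_g > n_c) {
    free_starts <- round(seq(1e4, genome_end - gene_len - 1e4,
      length.out = n_g - n_c
    ))
    starts[(n_c + 1):n_g] <- free_starts
  }
  starts <- pmax(starts, 1)
  name <- sprintf("gene_%03d", seq_len(n_g))
  tss <- ifelse(strands == "+", starts, starts + gene_len)
  exon_w <- round(gene_len / 6)
  exon_starts <- lapply(starts, function(s) {
    c(s, s + 2 * exon_w, s + 4 * exon_w)
  })
  exon_ends <- lapply(seq_len(n_g), function(i) {
    exon_starts[[i]] + exon_w
  })
  genes <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = starts + gene_len),
    strand = strands,
    name = name,
    tss = tss,
    exon_starts = vapply(exon_starts, paste, character(1), collapse = ","),
    exon_ends = vapply(exon_ends, paste, character(1), collapse = ",")
  )
  n_samp <- length(samples)
  expr <- matrix(0, n_g, n_samp,
    dimnames = list(name, vapply(samples, `[[`, character(1), "sample_id"))
  )
  base <- stats::rnorm(n_g, mean = 8, sd = 1.5)
  noise <- matrix(stats::rnorm(n_g * n_samp, 0, config$expr_noise_sd),
    n_g, n_samp
  )
  expr[] <- base + noise
  if (n_c > 0) {
    for (i in seq_len(n_c)) {
      r <- truth$regions[truth$regions$region_id == coupled_region[i], ]
      idx <- r$start_idx:r$end_idx
      m <- vapply(samples, region_mean_beta, numeric(1), idx = idx)
      expr[i, ] <- expr[i, ] -
        config$gene_coupling_strength * (m - 0.5)
    }
  }
  list(
    expr = 2^expr, genes = genes,
    couplings = data.frame(
      gene = name[seq_len(n_c)],
      region_id = coupled_region,
      strength = rep(config$gene_coupling_strength, n_c)
    )
  )
}

#' Simulate miRNA counts negatively coupled to promoter methylation
#'
#' miRNA genes are small (~200 bp) intervals; coupled miRNAs sit immediately
#' downstream of a planted variably methylated region (VMR) so that the
#' CpGs in their gene body + 5 kb upstream window carry a methylation level
#' that varies continuously across samples, and their negative-binomial mean
#' decreases monotonically (log-linearly) with that level. Library sizes
#' vary at most two-fold.
#'
#' @param config A [cohort_config()].
#' @param truth `cohort_truth`.
#' @param samples Simulated methylome samples.
#' @return List with `counts` (miRNA x samples integer matrix),
#'   `mirna_genes` (a `GRanges` with mcols name), and `couplings`
#'   (data.frame mirna, region_id).
#' @export
simulate_mirna_counts <- function(config, truth, samples) {
  set.seed(derive_seed(config$rng_seed, "mirna"))
  n_m <- config$n_mirna
  n_c <- config$n_coupled_mirna
  vmrs <- truth$regions[truth$regions$klass == "VMR", , drop = FALSE]
  if (n_c > nrow(vmrs)) stop("not enough planted VMRs for coupled miRNAs")
  name <- sprintf("mir_%03d", seq_len(n_m))
  width <- 200
  starts <- numeric(n_m)
  strands <- rep("+", n_m)
  if (n_c > 0) {
    # gene body right at the VMR end: the VMR lies in the upstream window
    starts[seq_len(n_c)] <- vmrs$end[seq_len(n_c)] + 50
  }
  if (n_m > n_c) {
    genome_end <- max(truth$positions)
    # decoys offset from the even grid used for planted elements
    starts[(n_c + 1):n_m] <- round(seq(2e4, genome_end - 2e4,
      length.out = n_m - n_c
    )) + 37
  }
  mirna_genes <- GenomicRanges::GRanges(
    seqnames = truth$chrom,
    ranges = IRanges::IRanges(start = starts + 1, end = starts + width),
    strand = strands,
    name = name
  )
  n_samp <- length(samples)
  sample_ids <- vapply(samples, `[[`, character(1), "sample_id")
  libfac <- stats::runif(n_samp, 0.7, 1.4)
  mu0 <- config$mirna_base_mean *
    exp(stats::rnorm(n_m, 0, 0.6))
  counts <- matrix(0L, n_m, n_samp, dimnames = list(name, sample_ids))
  lev <- matrix(0.5, n_m, n_samp)
  if (n_c > 0) {
    lev[seq_len(n_c), ] <- truth$vmr_level[
      vmrs$region_id[seq_len(n_c)], , drop = FALSE
    ]
  }
  groups <- vapply(samples, `[[`, character(1), "group")
  coupled_mask <- c(rep(1, n_c), rep(0, n_m - n_c))
  for (j in seq_len(n_samp)) {
    mu <- mu0 * libfac[j] *
      exp(-config$mirna_coupling_strength * (lev[, j] - 0.5) * coupled_mask)
    if (groups[j] == "RA" && config$mirna_group_fc != 1) {
      mu <- mu * config$mirna_group_fc^coupled_mask
    }
    if (config$mirna_dispersion > 0) {
      counts[, j] <- stats::rnbinom(n_m,
        mu = mu, size = 1 / config$mirna_dispersion
      )
    } else {
      counts[, j] <- stats::rpois(n_m, mu)
    }
  }
  list(
    counts = counts, mirna_genes = mirna_genes,
    couplings = data.frame(
      mirna = name[seq_len(n_c)],
      region_id = vmrs$region_id[seq_len(n_c)]
    )
  )
}

#' Simulate per-sample variant tables and per-gene mutation probabilities
#'
#' Baseline per-gene, per-sample variant counts are Poisson(2 mu_g) (two
#' copies per individual); planted excess genes have their rate inflated by
#' `excess_factor` in RA samples only.
#'
#' @param config A [cohort_config()].
#' @param sample_info Optional data.frame (sample_id, group); defaults to
#'   the cohort layout implied by `config`.
#' @return List with `variants` (data.frame gene, sample, consequence),
#'   `mu_table` (data.frame gene, mu), and `excess_genes` (character).
#' @export
simulate_variant_tables <- function(config, sample_info = NULL) {
  set.seed(derive_seed(config$rng_seed, "variants"))
  if (is.null(sample_info)) {
    sample_info <- data.frame(
      sample_id = c(
        sprintf("RA_%02d", seq_len(config$n_ra)),
        sprintf("OA_%02d", seq_len(config$n_oa))
      ),
      group = c(rep("RA", config$n_ra), rep("OA", config$n_oa))
    )
  }
  n_g <- config$n_mut_genes
  gene <- sprintf("mutgene_%03d", seq_len(n_g))
  if (any(config$mu_range < 0)) stop("negative mutation probability")
  mu <- stats::runif(n_g, config$mu_range[1], config$mu_range[2])
  if (identical(config$mu_range[1], 0) && identical(config$mu_range[2], 0)) {
    mu <- rep(0, n_g)
  }
  excess <- gene[seq_len(config$n_excess_genes)]
  conseq <- c("missense", "nonsense", "splice_site", "frameshift")
  rows <- list()
  for (s in seq_len(nrow(sample_info))) {
    rate <- 2 * mu
    if (sample_info$group[s] == "RA") {
      rate[seq_len(config$n_excess_genes)] <-
        rate[seq_len(config$n_excess_genes)] * config$excess_factor
    }
    k <- stats::rpois(n_g, rate)
    hit <- which(k > 0)
    for (g in hit) {
      rows[[length(rows) + 1]] <- data.frame(
        gene = rep(gene[g], k[g]),
        sample = rep(sample_info$sample_id[s], k[g]),
        consequence = sample(conseq, k[g], replace = TRUE,
          prob = c(0.7, 0.1, 0.1, 0.1)
        ),
        stringsAsFactors = FALSE
      )
    }
  }
  variants <- if (length(rows)) {
    do.call(rbind, rows)
  } else {
    data.frame(
      gene = character(), sample = character(), consequence = character()
    )
  }
  list(
    variants = variants,
    mu_table = data.frame(gene = gene, mu = mu),
    excess_genes = excess
  )
}

#' Simulate the full multi-layer cohort
#'
#' Convenience wrapper running all four generators from one config.
#'
#' @param config A [cohort_config()].
#' @return List: samples, truth, expr, genes, gene_couplings, mirna_counts,
#'   mirna_genes, mirna_couplings, variants, mu_table, excess_genes.
#' @export
simulate_cohort <- function(config) {
  mc <- simulate_methylome_cohort(config)
  ex <- simulate_expression_profiles(config, mc$truth, mc$samples)
  mi <- simulate_mirna_counts(config, mc$truth, mc$samples)
  va <- simulate_variant_tables(config)
  list(
    samples = mc$samples, truth = mc$truth,
    expr = ex$expr, genes = ex$genes, gene_couplings = ex$couplings,
    mirna_counts = mi$counts, mirna_genes = mi$mirna_genes,
    mirna_couplings = mi$couplings,
    variants = va$variants, mu_table = va$mu_table,
    excess_genes = va$excess_genes
  )
}
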