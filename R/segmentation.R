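# Methylome segmentation: polarization (alpha) track, PMD detection with a
# two-state Gaussian HMM on log alpha, FDR-calibrated hypomethylation cutoff
# selection against a permuted methylome, and UMR/LMR calling.

# moving mean over +/- k neighbours with partial windows at the edges
smooth_runmean <- function(x, k = 1L) {
  n <- length(x)
  if (n == 0 || k == 0) {
    return(x)
  }
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Maximum-likelihood shape of a symmetric Beta(alpha, alpha) given
# sbar = mean(log(b) + log(1 - b)). The score equation is
# 2 psi(2a) - 2 psi(a) = -sbar, whose left side decreases from +Inf (a -> 0)
# to 2 log 2 (a -> Inf); solved by Newton iteration on log(a), vectorized.
symmetric_beta_mle <- function(sbar, max_alpha = 1000) {
  target <- -sbar
  a <- rep(1, length(sbar))
  sat <- target <= 2 * log(2) + 1e-10
  a[sat] <- max_alpha
  act <- which(!sat)
  if (length(act) > 0) {
    x <- rep(0, length(act)) # log alpha
    tg <- target[act]
    for (it in 1:60) {
      al <- exp(x)
      g <- 2 * digamma(2 * al) - 2 * digamma(al)
      gp <- (4 * trigamma(2 * al) - 2 * trigamma(al)) * al
      step <- (g - tg) / gp
      step[!is.finite(step)] <- 0
      step <- pmax(pmin(step, 2), -2)
      x <- x - step
      x <- pmax(pmin(x, log(max_alpha)), log(1e-4))
      if (max(abs(step)) < 1e-12) break
    }
    a[act] <- exp(x)
  }
  pmin(a, max_alpha)
}

#' Compute the polarization (alpha) track of a methylome
#'
#' For each sliding window of `window_cpgs` consecutive CpGs, the shape
#' parameter of a symmetric Beta(alpha, alpha) distribution is fitted by
#' maximum likelihood to the window's posterior-smoothed beta values
#' (meth + 0.5)/(cov + 1). Alpha below 1 indicates a polarized (bimodal)
#' methylation landscape, alpha at or above 1 a dispersed one, as inside
#' partially methylated domains.
#'
#' @param sample A [methylome_sample()].
#' @param window_cpgs Odd window size in CpGs (default 101).
#' @return An `alpha_track` data.frame: chrom, center_idx (CpG index in the
#'   sample), pos (of the center CpG), alpha, log_alpha; window size kept as
#'   attribute `window`.
#' @export
compute_alpha_track <- function(sample, window_cpgs = 101L) {
  stopifnot(window_cpgs >= 3, window_cpgs %% 2 == 1)
  s <- sample$sites
  n <- nrow(s)
  if (n < window_cpgs) {
    warning("sample has fewer CpGs than the window; empty alpha track")
    out <- data.frame(
      chrom = character(), center_idx = integer(),
      pos = integer(), alpha = numeric(), log_alpha = numeric()
    )
    attr(out, "window") <- window_cpgs
    class(out) <- c("alpha_track", "data.frame")
    return(out)
  }
  b <- (s$meth + 0.5) / (s$cov + 1)
  t <- log(b) + log1p(-b)
  hw <- window_cpgs %/% 2
  cs <- cumsum(c(0, t))
  centers <- (hw + 1):(n - hw)
  sbar <- (cs[centers + hw + 1] - cs[centers - hw]) / window_cpgs
  alpha <- symmetric_beta_mle(sbar)
  out <- data.frame(
    chrom = s$chrom[centers],
    center_idx = centers,
    pos = s$pos[centers],
    alpha = alpha,
    log_alpha = log(alpha)
  )
  attr(out, "window") <- window_cpgs
  class(out) <- c("alpha_track", "data.frame")
  out
}

# build a GRanges of segments from CpG index ranges of one sample
segments_from_index_runs <- function(sample, from_idx, to_idx, klass) {
  s <- sample$sites
  if (length(from_idx) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$klass <- character(0)
    mcols(gr)$n_cpg <- integer(0)
    mcols(gr)$mean_meth <- numeric(0)
    return(gr)
  }
  mean_meth <- mapply(function(a, b) {
    mean(s$meth[a:b] / s$cov[a:b])
  }, from_idx, to_idx)
  GenomicRanges::GRanges(
    seqnames = s$chrom[from_idx],
    ranges = IRanges::IRanges(
      start = s$pos[from_idx] + 1,
      end = s$pos[to_idx] + 1
    ),
    klass = klass,
    n_cpg = to_idx - from_idx + 1L,
    mean_meth = mean_meth
  )
}

#' Detect partially methylated domains from an alpha track
#'
#' A two-state hidden Markov model with Gaussian emissions on log alpha is
#' trained by expectation-maximization (deterministic initialization by a
#' median split of log alpha) and decoded by posterior state probability
#' > 0.5. The state with the larger mean log alpha is the PMD state,
#' provided it is dispersed in absolute terms (mean alpha >= `min_alpha`);
#' if both states are dispersed the whole tracked region is PMD, if
#' neither is, no PMD is called. Consecutive PMD windows are merged;
#' merged segments whose mean window alpha falls below `min_alpha` (runs
#' of upper-tail background absorbed by the broader state) and segments
#' with fewer than `min_pmd_cpgs` CpGs are dropped.
#'
#' @param track An `alpha_track` from [compute_alpha_track()].
#' @param sample The corresponding [methylome_sample()].
#' @param min_pmd_cpgs Minimum CpGs per PMD (default: the track's window).
#' @param min_alpha Dispersion threshold defining a PMD-like state.
#' @param max_iter,tol EM iteration cap and relative log-likelihood
#'   tolerance.
#' @return A `GRanges` of PMD segments (mcols klass, n_cpg, mean_meth).
#' @export
detect_pmds <- function(track, sample, min_pmd_cpgs = NULL, min_alpha = 1,
                        max_iter = 100L, tol = 1e-6) {
  if (nrow(track) == 0) stop("empty alpha track")
  if (is.null(min_pmd_cpgs)) min_pmd_cpgs <- attr(track, "window")
  hw <- attr(track, "window") %/% 2
  x <- track$log_alpha
  med <- stats::median(x)
  lo <- x[x <= med]
  hi <- x[x > med]
  if (length(hi) == 0) hi <- lo
  mu0 <- c(mean(lo), mean(hi))
  sd0 <- pmax(c(stats::sd(lo), stats::sd(hi)), 0.05)
  sd0[is.na(sd0)] <- 0.05
  fit <- .hmm2_em(x, mu0, sd0, c(0.5, 0.5),
    matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE),
    as.integer(max_iter), tol
  )
  if (!fit$converged && length(x) > 1) {
    stop(
      "HMM expectation-maximization did not converge in ", max_iter,
      " iterations; log-likelihood trace: ",
      paste(utils::tail(signif(fit$loglik_trace, 8), 5), collapse = ", ")
    )
  }
  dispersed <- fit$mu >= log(min_alpha)
  if (!any(dispersed)) {
    return(segments_from_index_runs(sample, integer(0), integer(0), "PMD"))
  }
  if (all(dispersed) || abs(diff(fit$mu)) < 1e-3) {
    is_pmd <- rep(TRUE, length(x))
  } else {
    pmd_state <- which.max(fit$mu)
    p2 <- fit$posterior_state2
    is_pmd <- if (pmd_state == 2) p2 > 0.5 else (1 - p2) > 0.5
  }
  r <- rle(is_pmd)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values)
  if (length(keep) == 0) {
    return(segments_from_index_runs(sample, integer(0), integer(0), "PMD"))
  }
  # a called segment must itself be dispersed: the HMM's larger-mean state
  # can absorb stretches of upper-tail background windows, which a
  # segment-level mean-alpha filter removes
  seg_alpha <- vapply(keep, function(r) {
    mean(track$alpha[starts[r]:ends[r]])
  }, numeric(1))
  keep <- keep[seg_alpha >= min_alpha]
  if (length(keep) == 0) {
    return(segments_from_index_runs(sample, integer(0), integer(0), "PMD"))
  }
  # window centers back to CpG index ranges (windows span center +/- hw)
  from_idx <- pmax(track$center_idx[starts[keep]] - hw, 1L)
  to_idx <- pmin(track$center_idx[ends[keep]] + hw, nrow(sample$sites))
  w <- (to_idx - from_idx + 1L) >= min_pmd_cpgs
  segments_from_index_runs(sample, from_idx[w], to_idx[w], "PMD")
}

#' Classify PMD sharing between groups
#'
#' A PMD overlapping (>= 1 bp) any PMD of the other group is `shared`; a
#' PMD found in exactly one sample overall (no overlap with any other
#' sample's PMDs) is `specific`; PMDs private to several samples of one
#' group are labelled `private_multi`.
#'
#' @param pmds_by_sample Named list of PMD `GRanges`, one per sample.
#' @param groups Named character vector mapping sample id to group.
#' @return A data.frame: sample, chrom, start (0-based), end, label.
#' @export
classify_pmd_sharing <- function(pmds_by_sample, groups) {
  check_groups(groups)
  empty <- data.frame(
    sample = character(), chrom = character(), start = integer(),
    end = integer(), label = character()
  )
  if (length(pmds_by_sample) == 0) {
    return(empty)
  }
  ids <- names(pmds_by_sample)
  stopifnot(!is.null(ids), all(ids %in% names(groups)))
  pool <- function(which_ids) {
    gs <- pmds_by_sample[which_ids]
    gs <- gs[vapply(gs, length, 1L) > 0]
    if (length(gs) == 0) {
      return(GenomicRanges::GRanges())
    }
    # combining per-sample calls with disjoint seqlevels is expected here
    suppressWarnings(do.call(c, unname(gs)))
  }
  rows <- list()
  for (id in ids) {
    g <- pmds_by_sample[[id]]
    if (length(g) == 0) next
    other_group <- pool(ids[groups[ids] != groups[id]])
    any_other <- pool(ids[ids != id])
    # per-sample calls may live on disjoint seqlevels; that is expected
    shared <- suppressWarnings(
      GenomicRanges::countOverlaps(g, other_group, minoverlap = 1) > 0
    )
    alone <- suppressWarnings(
      GenomicRanges::countOverlaps(g, any_other, minoverlap = 1) == 0
    )
    label <- ifelse(shared, "shared",
      ifelse(alone, "specific", "private_multi")
    )
    rows[[id]] <- data.frame(
      sample = id,
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g) - 1,
      end = GenomicRanges::end(g),
      label = label,
      stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# count hypomethylated runs (>= n consecutive CpGs with smoothed beta < m)
# within unmasked stretches; returns run count, or the runs themselves
hypo_runs <- function(smoothed, unmasked, m, n, return_runs = FALSE) {
  low <- smoothed < m & unmasked
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= n)
  if (!return_runs) {
    return(length(keep))
  }
  list(from = starts[keep], to = ends[keep])
}

#' Select the hypomethylation cutoff by permutation-based FDR
#'
#' After masking PMDs, hypomethylated regions (maximal runs of at least `n`
#' consecutive CpGs whose 3-CpG-smoothed beta is below `m`) are counted in
#' the observed methylome and in a methylome whose beta values are permuted
#' genome-wide (fixed seed). FDR(m, n) is the permuted/observed call ratio
#' (capped at 1). The chosen cutoff is the smallest `n` for which any `m`
#' achieves FDR at or below the bound, with the largest such `m`.
#'
#' @param sample A [methylome_sample()].
#' @param pmds PMD `GRanges` to mask (may be empty).
#' @param m_grid Candidate methylation cutoffs.
#' @param n_grid Candidate minimum CpG counts.
#' @param fdr_bound FDR bound (default 0.05).
#' @param seed Seed for the genome-wide permutation.
#' @return A `cutoff_selection` list: m_grid, n_grid, fdr_table (matrix m x
#'   n), counts, chosen m and n, fdr at the chosen pair.
#' @export
select_fdr_cutoff <- function(sample, pmds,
                              m_grid = seq(0.30, 0.70, by = 0.05),
                              n_grid = 4:10,
                              fdr_bound = 0.05, seed = 1L) {
  s <- sample$sites
  beta <- s$meth / s$cov
  unmasked <- rep(TRUE, nrow(s))
  if (length(pmds) > 0) {
    cg <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1, s$pos + 1))
    unmasked <- GenomicRanges::countOverlaps(cg, pmds) == 0
  }
  sm_obs <- smooth_runmean(beta, 1L)
  set.seed(seed)
  beta_perm <- beta
  beta_perm[unmasked] <- sample(beta[unmasked])
  sm_perm <- smooth_runmean(beta_perm, 1L)
  obs <- matrix(0, length(m_grid), length(n_grid),
    dimnames = list(m_grid, n_grid)
  )
  perm <- obs
  for (i in seq_along(m_grid)) {
    for (j in seq_along(n_grid)) {
      obs[i, j] <- hypo_runs(sm_obs, unmasked, m_grid[i], n_grid[j])
      perm[i, j] <- hypo_runs(sm_perm, unmasked, m_grid[i], n_grid[j])
    }
  }
  if (all(obs == 0)) stop("no callable regions at any grid point")
  fdr <- ifelse(obs > 0, pmin(perm / obs, 1), NA_real_)
  ok <- !is.na(fdr) & fdr <= fdr_bound
  if (!any(ok)) {
    stop(
      "no cutoff achieves FDR <= ", fdr_bound,
      " (methylome indistinguishable from its permutation)"
    )
  }
  j_sel <- which(apply(ok, 2, any))[1]
  i_sel <- max(which(ok[, j_sel]))
  structure(list(
    m_grid = m_grid, n_grid = n_grid,
    fdr_table = fdr, observed = obs, permuted = perm,
    m = m_grid[i_sel], n = n_grid[j_sel],
    fdr = fdr[i_sel, j_sel], fdr_bound = fdr_bound, seed = seed
  ), class = "cutoff_selection")
}

#' @export
print.cutoff_selection <- function(x, ...) {
  cat(sprintf(
    "<cutoff_selection> m = %.2f, n = %d (FDR %.3f <= %.2f)\n",
    x$m, x$n, x$fdr, x$fdr_bound
  ))
  invisible(x)
}

#' Call UMRs and LMRs outside PMDs
#'
#' Beta values are smoothed over 3 consecutive CpGs; maximal runs of at
#' least `cutoff$n` CpGs with smoothed beta below `cutoff$m`, outside PMDs,
#' become segments spanning their first to last CpG. Because smoothing
#' pulls boundary CpGs toward the flanking background, run boundaries are
#' then refined on the raw beta values: each run is extended outward while
#' the adjacent CpG's raw beta stays below the cutoff (without crossing
#' masked CpGs or a neighbouring run). Segments with at least 30 CpGs are
#' UMRs, smaller ones LMRs.
#'
#' @param sample A [methylome_sample()].
#' @param pmds PMD `GRanges` to mask.
#' @param cutoff A `cutoff_selection` (or any list with elements m and n).
#' @param umr_min_cpgs UMR/LMR class boundary (default 30 CpGs).
#' @return A `GRanges` of segments with mcols klass ("UMR"/"LMR"), n_cpg,
#'   mean_meth.
#' @export
call_umr_lmr <- function(sample, pmds, cutoff, umr_min_cpgs = 30L) {
  s <- sample$sites
  beta <- s$meth / s$cov
  unmasked <- rep(TRUE, nrow(s))
  if (length(pmds) > 0) {
    cg <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos + 1, s$pos + 1))
    unmasked <- GenomicRanges::countOverlaps(cg, pmds) == 0
  }
  sm <- smooth_runmean(beta, 1L)
  runs <- hypo_runs(sm, unmasked, cutoff$m, cutoff$n, return_runs = TRUE)
  # refine boundaries on raw betas
  nr <- length(runs$from)
  if (nr > 0) {
    for (i in seq_len(nr)) {
      lo_bound <- if (i > 1) runs$to[i - 1] + 1L else 1L
      hi_bound <- if (i < nr) runs$from[i + 1] - 1L else length(beta)
      while (runs$from[i] > lo_bound &&
        unmasked[runs$from[i] - 1L] &&
        beta[runs$from[i] - 1L] < cutoff$m) {
        runs$from[i] <- runs$from[i] - 1L
      }
      while (runs$to[i] < hi_bound &&
        unmasked[runs$to[i] + 1L] &&
        beta[runs$to[i] + 1L] < cutoff$m) {
        runs$to[i] <- runs$to[i] + 1L
      }
    }
  }
  seg <- segments_from_index_runs(sample, runs$from, runs$to, "LMR")
  if (length(seg) > 0) {
    mcols(seg)$klass <- ifelse(
      mcols(seg)$n_cpg >= umr_min_cpgs, "UMR", "LMR"
    )
  }
  seg
}

#' Segment one sample end to end
#'
#' Convenience wrapper: alpha track, PMD detection, FDR cutoff selection and
#' UMR/LMR calling in one call.
#'
#' @param sample A [methylome_sample()].
#' @param window_cpgs Alpha window (default 101).
#' @param fdr_bound FDR bound for cutoff selection.
#' @param seed Seed for the cutoff permutation.
#' @return List: track, pmds, cutoff, segments (UMR/LMR `GRanges`),
#'   all_segments (PMDs + UMRs/LMRs combined).
#' @export
segment_methylome <- function(sample, window_cpgs = 101L, fdr_bound = 0.05,
                              seed = 1L) {
  track <- compute_alpha_track(sample, window_cpgs)
  pmds <- if (nrow(track) > 0) {
    detect_pmds(track, sample)
  } else {
    segments_from_index_runs(sample, integer(0), integer(0), "PMD")
  }
  cutoff <- select_fdr_cutoff(sample, pmds, fdr_bound = fdr_bound, seed = seed)
  segs <- call_umr_lmr(sample, pmds, cutoff)
  all <- c(pmds, segs)
  all <- all[order(GenomicRanges::start(all))]
  list(
    track = track, pmds = pmds, cutoff = cutoff,
    segments = segs, all_segments = all
  )
}
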