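# Shared fixtures: tiny methylomes and gene models built in code.

# a methylome sample from explicit beta values at fixed coverage
sample_from_betas <- function(betas, cov = 10L, sample_id = "S1",
                              group = "RA", spacing = 100L,
                              chrom = "chrS") {
  pos <- seq(0L, by = spacing, length.out = length(betas))
  methylome_sample(sample_id, group, data.frame(
    chrom = chrom, pos = pos,
    cov = rep(cov, length(betas)),
    meth = as.integer(round(betas * cov))
  ))
}

# cohort of samples from a beta matrix (sites x samples)
cohort_from_beta_matrix <- function(B, groups, cov = 10L, spacing = 100L) {
  lapply(seq_len(ncol(B)), function(i) {
    sample_from_betas(B[, i],
      cov = cov,
      sample_id = sprintf("%s_%02d", groups[i], i), group = groups[i],
      spacing = spacing
    )
  })
}

# a one-gene toy gene model; default exons are three blocks derived from
# the gene span
toy_gene <- function(chrom = "chrS", start = 10000, end = 13000,
                     strand = "+", name = "g1",
                     exon_starts = start + c(0, 1000, 2000),
                     exon_ends = c(start + 400, start + 1400, end)) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = strand,
    name = name,
    tss = if (strand == "-") end else start,
    exon_starts = paste(exon_starts, collapse = ","),
    exon_ends = paste(exon_ends, collapse = ",")
  )
}

gr_interval <- function(chrom, start, end, ...) {
  GenomicRanges::GRanges(
    seqnames = chrom, ranges = IRanges::IRanges(start + 1, end), ...
  )
}

# independent grid-search oracle for the symmetric Beta ML fit
alpha_grid_oracle <- function(b, grid = 10^seq(-3, 3, length.out = 20000)) {
  s <- sum(log(b) + log1p(-b))
  n <- length(b)
  ll <- n * (lgamma(2 * grid) - 2 * lgamma(grid)) + (grid - 1) * s
  grid[which.max(ll)]
}
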