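# Recovery evaluation against the synthetic ground truth.

#' Ground-truth intervals of one segment class for one sample
#'
#' Returns the planted regions of class `klass` that are present in the
#' given sample: shared regions always, group-specific regions only when
#' the sample is penetrant for them.
#'
#' @param truth A `cohort_truth`.
#' @param klass "PMD", "UMR" or "LMR".
#' @param sample_id Sample identifier (used for penetrance lookup).
#' @return A `GRanges` of truth intervals.
#' @export
truth_region_ranges <- function(truth, klass, sample_id) {
  r <- truth$regions[truth$regions$klass == klass, , drop = FALSE]
  if (nrow(r) == 0) {
    return(GenomicRanges::GRanges())
  }
  keep <- r$group == "shared" |
    truth$penetrant[match(r$region_id, rownames(truth$penetrant)), sample_id]
  r <- r[keep, , drop = FALSE]
  if (nrow(r) == 0) {
    return(GenomicRanges::GRanges())
  }
  GenomicRanges::GRanges(
    truth$chrom, IRanges::IRanges(start = r$start + 1, end = r$end)
  )
}

#' Base-level precision, recall and F1 of called intervals
#'
#' All quantities are computed on base pairs after reducing both sets.
#'
#' @param called,truth `GRanges`.
#' @return Named numeric: precision, recall, f1, jaccard.
#' @export
interval_f1 <- function(called, truth) {
  a <- GenomicRanges::reduce(GenomicRanges::granges(called))
  b <- GenomicRanges::reduce(GenomicRanges::granges(truth))
  wa <- sum(IRanges::width(a))
  wb <- sum(IRanges::width(b))
  inter <- if (length(a) && length(b)) {
    sum(IRanges::width(GenomicRanges::intersect(a, b)))
  } else {
    0
  }
  uni <- wa + wb - inter
  prec <- if (wa > 0) inter / wa else NA_real_
  rec <- if (wb > 0) inter / wb else NA_real_
  f1 <- if (isTRUE(prec + rec > 0)) 2 * prec * rec / (prec + rec) else 0
  c(
    precision = prec, recall = rec, f1 = f1,
    jaccard = if (uni > 0) inter / uni else NA_real_
  )
}
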