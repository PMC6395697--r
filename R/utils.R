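#' Derive a reproducible sub-seed from a master seed
#'
#' Stage-level analyses draw their randomness from sub-streams derived
#' deterministically from one master seed, so that re-running a single stage
#' reproduces its part of a full pipeline run.
#'
#' @param seed Integer master seed.
#' @param stream Character label of the consuming stage.
#' @return A single integer seed, strictly below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # fold the stream label into the seed with a small polynomial hash
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629)
}

#' Format a count as a percentage of a total
#'
#' Used throughout result summaries, e.g. the share of intronic regions
#' falling in first introns. Rounds to one decimal place.
#'
#' @param x Numerator count.
#' @param n Denominator count.
#' @param digits Decimal places (default 1).
#' @return Numeric percentage.
#' @export
pct <- function(x, n, digits = 1) {
  stopifnot(n > 0)
  round(100 * x / n, digits)
}

#' Bonferroni-corrected per-test significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests in the family.
#' @param signif_digits If non-NULL, truncate (not round) the threshold to
#'   this many significant digits, as thresholds are conventionally printed.
#' @return Per-test threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests, signif_digits = NULL) {
  stopifnot(n_tests >= 1)
  thr <- alpha / n_tests
  if (!is.null(signif_digits)) {
    e <- floor(log10(thr))
    f <- 10^(signif_digits - 1 - e)
    thr <- floor(thr * f) / f
  }
  thr
}

# internal: add-one permutation p-value
perm_pvalue <- function(n_as_extreme, n_perm) {
  (1 + n_as_extreme) / (n_perm + 1)
}

# internal: check a group label vector against the two cohort labels
check_groups <- function(groups, allowed = c("RA", "OA")) {
  bad <- setdiff(unique(groups), allowed)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
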