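#' @useDynLib methylscape, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import IRanges
#' @import GenomicRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom stats aggregate
NULL

# All internal coordinates are 0-based half-open. Bismark coverage files are
# 1-based and shifted on read; BED files are used verbatim. Chromosome names
# are taken as-is (no "chr" normalization).

#' Construct a methylome sample
#'
#' A methylome sample holds one subject's per-CpG counts and a group label.
#' Sites are stored sorted by (chrom, pos) with duplicates collapsed.
#'
#' @param sample_id Sample identifier.
#' @param group Group label, one of "RA" or "OA".
#' @param sites data.frame with columns chrom, pos (0-based), cov, meth.
#' @return An object of class `methylome_sample`.
#' @export
methylome_sample <- function(sample_id, group, sites) {
  check_groups(group)
  stopifnot(all(c("chrom", "pos", "cov", "meth") %in% names(sites)))
  if (nrow(sites) > 0) {
    if (any(sites$pos < 0)) stop("negative CpG position")
    if (any(sites$cov < 0) || any(sites$meth < 0)) {
      stop("negative count in methylation calls")
    }
    if (any(sites$meth > sites$cov)) stop("meth count exceeds coverage")
    o <- order(sites$chrom, sites$pos)
    sites <- sites[o, , drop = FALSE]
    dup <- duplicated(paste(sites$chrom, sites$pos))
    sites <- sites[!dup, , drop = FALSE]
    rownames(sites) <- NULL
  }
  structure(
    list(sample_id = sample_id, group = group, sites = sites),
    class = "methylome_sample"
  )
}

#' @export
print.methylome_sample <- function(x, ...) {
  cat(sprintf(
    "<methylome_sample> %s (%s): %d CpGs, mean coverage %.1f\n",
    x$sample_id, x$group, nrow(x$sites),
    if (nrow(x$sites)) mean(x$sites$cov) else NA_real_
  ))
  invisible(x)
}

#' Per-CpG methylation levels (beta values) of a sample
#'
#' @param sample A `methylome_sample`.
#' @param smoothed Use posterior-mean smoothing (meth + 0.5)/(cov + 1)?
#'   Default FALSE (raw meth/cov).
#' @return Numeric vector of beta values, one per site.
#' @export
beta_values <- function(sample, smoothed = FALSE) {
  s <- sample$sites
  if (smoothed) (s$meth + 0.5) / (s$cov + 1) else s$meth / s$cov
}

#' Read a Bismark-style coverage file
#'
#' Expects six tab-separated columns: chrom, start (1-based), end,
#' methylation percentage, methylated count, unmethylated count. Positions
#' are shifted to the internal 0-based convention; coverage is the sum of
#' the two counts. If the percentage column disagrees with the counts by
#' more than one percentage unit a warning is raised and the counts win.
#'
#' @param path Path to the coverage file.
#' @param sample_id Sample identifier to attach.
#' @param group Group label ("RA" or "OA").
#' @return A `methylome_sample`.
#' @export
read_bismark_coverage <- function(path, sample_id, group) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(methylome_sample(sample_id, group, data.frame(
      chrom = character(), pos = integer(), cov = integer(), meth = integer()
    )))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 6)) {
    stop("malformed coverage line ", which(nf < 6)[1], ": expected 6 fields")
  }
  m <- do.call(rbind, parts)
  pos1 <- suppressWarnings(as.numeric(m[, 2]))
  pmeth <- suppressWarnings(as.numeric(m[, 4]))
  cm <- suppressWarnings(as.numeric(m[, 5]))
  cu <- suppressWarnings(as.numeric(m[, 6]))
  bad <- which(is.na(pos1) | is.na(cm) | is.na(cu))
  if (length(bad) > 0) {
    stop("malformed coverage line ", bad[1], ": non-numeric field")
  }
  if (any(cm < 0) || any(cu < 0)) {
    stop(
      "malformed coverage line ", which(cm < 0 | cu < 0)[1],
      ": negative count"
    )
  }
  cov <- cm + cu
  implied <- ifelse(cov > 0, 100 * cm / cov, 0)
  off <- which(!is.na(pmeth) & abs(pmeth - implied) > 1)
  if (length(off) > 0) {
    warning(
      length(off), " line(s) with methylation% inconsistent with counts; ",
      "counts used"
    )
  }
  methylome_sample(sample_id, group, data.frame(
    chrom = m[, 1],
    pos = as.integer(pos1 - 1),
    cov = as.integer(cov),
    meth = as.integer(cm),
    stringsAsFactors = FALSE
  ))
}

#' Write a sample's beta values as bedGraph
#'
#' @param sample A `methylome_sample`.
#' @param path Output path.
#' @export
write_bedgraph <- function(sample, path) {
  s <- sample$sites
  df <- data.frame(s$chrom, s$pos, s$pos + 1,
    format(s$meth / s$cov, digits = 6, trim = TRUE)
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' Read a BED file into a GRanges
#'
#' BED3 or better; coordinates are 0-based half-open and kept that way in
#' the returned `GRanges` (ranges are stored shifted to 1-based closed as
#' GRanges requires, i.e. start = BED start + 1). A name column (4th) and
#' strand (6th) are captured when present.
#'
#' @param path Path to BED file.
#' @return A `GRanges`, in file order, with an mcols column `name` if present.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
    !startsWith(lines, "track")]
  if (length(lines) == 0) {
    return(GenomicRanges::GRanges())
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) stop("malformed BED line ", which(nf < 3)[1])
  m <- do.call(rbind, lapply(parts, function(p) p[1:3]))
  start0 <- as.numeric(m[, 2])
  end0 <- as.numeric(m[, 3])
  if (any(is.na(start0)) || any(is.na(end0))) stop("non-numeric BED coordinate")
  if (any(start0 >= end0)) {
    stop("BED interval with start >= end at line ", which(start0 >= end0)[1])
  }
  strand <- rep("*", length(lines))
  has6 <- nf >= 6
  if (any(has6)) {
    s6 <- vapply(parts[has6], `[`, character(1), 6)
    s6[!s6 %in% c("+", "-")] <- "*"
    strand[has6] <- s6
  }
  gr <- GenomicRanges::GRanges(
    seqnames = m[, 1],
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand
  )
  if (any(nf >= 4)) {
    nm <- rep(NA_character_, length(lines))
    nm[nf >= 4] <- vapply(parts[nf >= 4], `[`, character(1), 4)
    mcols(gr)$name <- nm
  }
  gr
}

#' Write intervals or segments as BED
#'
#' Segments (see [call_umr_lmr()]) are written with their class (PMD, UMR,
#' LMR) in the name column; a plain `GRanges` uses its `name` column or ".".
#' Round-trips through [read_bed()] losslessly on (chrom, start, end, name).
#'
#' @param x A `GRanges` (possibly with mcols `klass` or `name`) or a
#'   segment data.frame with columns chrom, start, end and optionally klass.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  if (methods::is(x, "GRanges")) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1,
      end = GenomicRanges::end(x),
      stringsAsFactors = FALSE
    )
    if (!is.null(mcols(x)$klass)) {
      df$name <- as.character(mcols(x)$klass)
    } else if (!is.null(mcols(x)$name)) {
      df$name <- as.character(mcols(x)$name)
    } else {
      df$name <- rep(".", nrow(df))
    }
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    df <- data.frame(
      chrom = x$chrom, start = x$start, end = x$end,
      name = if (!is.null(x$klass)) as.character(x$klass) else ".",
      stringsAsFactors = FALSE
    )
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(df) > 0) {
    writeLines(paste(df$chrom, df$start, df$end, df$name, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' First row holds sample ids, first column row ids. Non-numeric cells
#' (e.g. "NA") become missing values.
#'
#' @param path Path to the TSV file.
#' @return A numeric matrix with dimnames (rows x samples).
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) stop("empty matrix file")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  body <- parts[-1]
  ncol_expected <- length(header)
  # tolerate an R-style header that omits the row-id column name
  widths <- unique(lengths(body))
  if (length(body) > 0 && length(widths) > 1) {
    stop("ragged rows in matrix file")
  }
  if (length(body) > 0 && widths != ncol_expected) {
    if (widths == ncol_expected + 1) {
      header <- c("", header)
    } else {
      stop("ragged rows in matrix file")
    }
  }
  ids <- vapply(body, `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate row id: ", ids[duplicated(ids)][1])
  }
  vals <- lapply(body, function(p) suppressWarnings(as.numeric(p[-1])))
  m <- do.call(rbind, vals)
  if (is.null(m)) m <- matrix(numeric(), 0, length(header) - 1)
  rownames(m) <- ids
  colnames(m) <- header[-1]
  m
}

#' Write a labeled matrix as TSV
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Write a methylome sample as a Bismark-style coverage file
#'
#' Inverse of [read_bismark_coverage()]: positions are written 1-based.
#'
#' @param sample A `methylome_sample`.
#' @param path Output path.
#' @export
write_bismark_coverage <- function(sample, path) {
  s <- sample$sites
  pctm <- ifelse(s$cov > 0, round(100 * s$meth / s$cov, 4), 0)
  lines <- paste(s$chrom, s$pos + 1, s$pos + 1, pctm, s$meth, s$cov - s$meth,
    sep = "\t"
  )
  writeLines(lines, path)
  invisible(path)
}
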