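# Per-CpG beta-values and region-level methylation. Region means are
# unweighted across CpGs: the region value is the mean of the per-CpG
# beta-values, not a coverage-weighted pool.

#' CpG beta-value
#'
#' Methylated-read count divided by total coverage at one CpG.
#'
#' @param n_meth Methylated read count(s), `0 <= n_meth <= n_total`.
#' @param n_total Total coverage, `>= 1`.
#' @return Fraction(s) in `[0, 1]`.
#' @examples
#' cpg_beta(7, 28)  # 0.25
#' @export
cpg_beta <- function(n_meth, n_total) {
  if (any(n_total < 1)) stop("beta-value undefined at zero coverage")
  if (any(n_meth < 0 | n_meth > n_total)) stop("need 0 <= n_meth <= n_total")
  n_meth / n_total
}

#' Region methylation level
#'
#' Unweighted mean of CpG beta-values over CpGs falling inside the region
#' (1-based inclusive bounds: CpGs at `region$start` and `region$end` are
#' inside). Returns `NA` when fewer than `min_cpgs` CpGs contribute; missing
#' is a value, not an error.
#'
#' @param region One-row interval data frame.
#' @param calls CpG call data frame (`chrom, pos, n_meth, n_total`).
#' @param min_cpgs Minimum contributing CpGs for a reportable value
#'   (default 3).
#' @return Fraction in `[0, 1]`, or `NA`.
#' @export
region_methylation <- function(region, calls, min_cpgs = 3L) {
  validate_intervals(region, "region")
  stopifnot(nrow(region) == 1L)
  inside <- calls$chrom == region$chrom &
    calls$pos >= region$start & calls$pos <= region$end
  k <- sum(inside)
  if (k < min_cpgs) return(NA_real_)
  mean(cpg_beta(calls$n_meth[inside], calls$n_total[inside]))
}

#' Region-by-sample methylation matrix
#'
#' For every region and sample, the unweighted mean beta-value of the CpGs
#' inside the region; `NA` where fewer than `min_cpgs` CpGs have calls.
#'
#' @param regions Interval data frame.
#' @param cohort Named list of per-sample CpG call data frames; names are the
#'   sample ids and fix the column order.
#' @param min_cpgs Minimum contributing CpGs per (region, sample).
#' @return Numeric matrix, rows named by [region_id()], columns by sample id.
#'   The per-cell CpG counts are attached as attribute `"n_cpgs"`.
#' @export
region_meth_matrix <- function(regions, cohort, min_cpgs = 3L) {
  validate_intervals(regions, "regions")
  stopifnot(length(cohort) >= 1, !is.null(names(cohort)))
  ids <- region_id(regions)
  m <- matrix(NA_real_, nrow(regions), length(cohort),
              dimnames = list(ids, names(cohort)))
  ncpg <- matrix(0L, nrow(regions), length(cohort),
                 dimnames = list(ids, names(cohort)))
  rgr <- as_granges(regions)
  for (s in names(cohort)) {
    calls <- cohort[[s]]
    if (nrow(calls) == 0) next
    cgr <- GenomicRanges::GRanges(calls$chrom,
                                  IRanges::IRanges(calls$pos, width = 1L))
    hits <- GenomicRanges::findOverlaps(cgr, rgr)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi) == 0) next
    beta <- calls$n_meth[qi] / calls$n_total[qi]
    sums <- rowsum(beta, si)
    cnts <- rowsum(rep(1L, length(si)), si)
    rows <- as.integer(rownames(sums))
    vals <- sums[, 1] / cnts[, 1]
    vals[cnts[, 1] < min_cpgs] <- NA_real_
    m[rows, s] <- vals
    ncpg[rows, s] <- as.integer(cnts[, 1])
  }
  attr(m, "n_cpgs") <- ncpg
  m
}

#' Coverage-per-base histogram
#'
#' Histogram of per-CpG total coverage, the QC view used to judge PCR
#' duplication bias (a duplication-biased library shows a secondary peak at
#' high coverage). Coverages above `max_bin` are pooled into the open-ended
#' last bin, so the counts always sum to the number of records.
#'
#' @param calls CpG call data frame.
#' @param max_bin Last closed bin (default 100).
#' @return Named integer vector of counts for coverages `1..max_bin` plus a
#'   final `">max_bin"` bin.
#' @export
coverage_histogram <- function(calls, max_bin = 100L) {
  max_bin <- as.integer(max_bin)
  stopifnot(max_bin >= 1)
  counts <- integer(max_bin + 1L)
  names(counts) <- c(as.character(seq_len(max_bin)), paste0(">", max_bin))
  if (nrow(calls) > 0) {
    cov <- pmin(as.integer(calls$n_total), max_bin + 1L)
    tab <- tabulate(cov, nbins = max_bin + 1L)
    counts[] <- tab
  }
  counts
}
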