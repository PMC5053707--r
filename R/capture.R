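# Validation stage for an independent capture-seq cohort: methylation is
# quantified as region rpkm (reads per kilobase per million mapped reads)
# from aligned read intervals, and nominated enhancer-partner pairs are
# re-tested with the same Pearson machinery as the discovery screen. No |r|
# threshold is applied at validation; r, p and the strength label are
# reported.

#' Region rpkm from read intervals
#'
#' `rpkm = c / ((region length in bp / 1000) * (total_reads / 1e6))`, where
#' `c` counts reads overlapping the region by at least `min_overlap` bp
#' (default 1). Reads are not extended or shifted.
#'
#' @param reads Read interval data frame (`chrom, start, end`, 1-based
#'   inclusive).
#' @param region One-row interval data frame.
#' @param total_reads Library size (total mapped reads, >= 1).
#' @param min_overlap Minimum overlap in bp for a read to count.
#' @return Scalar rpkm (>= 0; 0 iff no reads overlap the region).
#' @examples
#' # 10 reads over a 1 kb region in a 1e6-read library -> rpkm = 10
#' @export
region_rpkm <- function(reads, region, total_reads, min_overlap = 1L) {
  if (length(total_reads) != 1 || total_reads < 1)
    stop("total_reads must be a single count >= 1")
  validate_intervals(region, "region")
  stopifnot(nrow(region) == 1L)
  ov <- reads$chrom == region$chrom &
    (pmin(reads$end, region$end) - pmax(reads$start, region$start) + 1) >= min_overlap
  cnt <- sum(ov)
  cnt / ((interval_length(region) / 1000) * (total_reads / 1e6))
}

#' Region-by-sample rpkm profiles for a capture cohort
#'
#' @param reads Named list of per-sample read interval data frames.
#' @param total_reads Named vector of per-sample library sizes (defaults to
#'   the read counts of `reads`, i.e. the full BED line count).
#' @param regions Interval data frame of regions to quantify.
#' @param min_overlap Minimum read-region overlap in bp.
#' @return Numeric matrix, rows named by [region_id()], columns by sample.
#' @export
capture_profiles <- function(reads, regions, total_reads = NULL,
                             min_overlap = 1L) {
  stopifnot(length(reads) >= 1, !is.null(names(reads)))
  validate_intervals(regions, "regions")
  if (is.null(total_reads))
    total_reads <- vapply(reads, nrow, 0L)
  stopifnot(all(total_reads >= 1))
  rgr <- as_granges(regions)
  m <- matrix(NA_real_, nrow(regions), length(reads),
              dimnames = list(region_id(regions), names(reads)))
  for (s in names(reads)) {
    gr <- as_granges(reads[[s]])
    cnt <- GenomicRanges::countOverlaps(rgr, gr,
                                        minoverlap = as.integer(min_overlap))
    m[, s] <- cnt / ((interval_length(regions) / 1000) *
                       (total_reads[[s]] / 1e6))
  }
  m
}

#' Re-test nominated pairs in an independent capture cohort
#'
#' For each (enhancer, partner) pair, Pearson r and the two-tailed p across
#' the capture samples' rpkm values, with the strength label. Shares the
#' [pearson_r()]/[pearson_pvalue()] code path with the discovery screen; no
#' magnitude threshold is applied.
#'
#' @param pairs Pair table with `enhancer_chrom/start/end` and
#'   `partner_chrom/start/end` columns (e.g. [screen_pairs()] output).
#' @param rpkm Region-by-sample rpkm matrix from [capture_profiles()],
#'   covering every region in `pairs` (>= 3 samples).
#' @return `pairs` with validation columns `val_n`, `val_r`, `val_p_value`,
#'   `val_strength` appended.
#' @export
validate_pairs <- function(pairs, rpkm) {
  if (ncol(rpkm) < 3) stop("validation cohort needs >= 3 samples")
  out <- pairs
  out$val_n <- NA_integer_; out$val_r <- NA_real_
  out$val_p_value <- NA_real_; out$val_strength <- NA_character_
  if (nrow(pairs) == 0) return(out)
  eid <- sprintf("%s:%d-%d", pairs$enhancer_chrom, pairs$enhancer_start,
                 pairs$enhancer_end)
  did <- sprintf("%s:%d-%d", pairs$partner_chrom, pairs$partner_start,
                 pairs$partner_end)
  missing <- setdiff(unique(c(eid, did)), rownames(rpkm))
  if (length(missing))
    stop("region(s) absent from capture profiles: ",
         paste(missing, collapse = ", "))
  for (i in seq_len(nrow(pairs))) {
    r <- pearson_r(rpkm[eid[i], ], rpkm[did[i], ])
    out$val_n[i] <- attr(r, "n")
    if (is.na(r)) next
    out$val_r[i] <- as.numeric(r)
    out$val_p_value[i] <- pearson_pvalue(as.numeric(r), attr(r, "n"))
    out$val_strength[i] <- classify_strength(as.numeric(r))
  }
  out
}
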