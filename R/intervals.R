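# Genomic intervals are plain data frames with columns chrom, start, end and
# optionally name, strand. Coordinates are uniformly 1-based inclusive
# (UCSC-browser style); BED's 0-based half-open convention is converted at the
# I/O boundary only (see read_intervals).

#' Construct a genomic interval table
#'
#' Builds a validated data frame of 1-based inclusive genomic intervals,
#' the container used throughout the package for enhancers, tiling windows,
#' DMRs and sequencing reads.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 1-based inclusive; `end >= start >= 1`.
#' @param name Optional labels (recycled `NA` if omitted).
#' @param strand Optional strand, one of `"+"`, `"-"` or `NA`.
#' @return A data frame with columns `chrom`, `start`, `end`, `name`,
#'   `strand`, sorted by (chrom, start, end).
#' @examples
#' genomic_intervals("chr1", 18958671, 18960284, name = "1702")
#' @export
genomic_intervals <- function(chrom, start, end, name = NA_character_,
                              strand = NA_character_) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.integer(round(start)),
                  end = as.integer(round(end)),
                  name = as.character(name),
                  strand = as.character(strand),
                  stringsAsFactors = FALSE)
  validate_intervals(x)
  sort_intervals(x)
}

validate_intervals <- function(x, where = "interval table") {
  stopifnot(is.data.frame(x))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(x)))
    stop(where, ": missing column(s) ", paste(setdiff(need, names(x)), collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (anyNA(x$start) || anyNA(x$end))
    stop(where, ": NA coordinates")
  if (any(x$start < 1))
    stop(where, ": start must be >= 1 (1-based inclusive coordinates)")
  bad <- which(x$end < x$start)
  if (length(bad))
    stop(where, ": end < start at row ", bad[1])
  invisible(x)
}

# Total, stable ordering: chrom lexicographic, then start, then end.
sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end, method = "radix"), , drop = FALSE]
}

interval_length <- function(x) x$end - x$start + 1L

#' Region identifier string
#'
#' `"chrom:start-end"` keys used as row names of region-by-sample matrices.
#'
#' @param x Interval data frame.
#' @return Character vector of identifiers.
#' @export
region_id <- function(x) sprintf("%s:%d-%d", x$chrom, x$start, x$end)

as_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
}

#' Tile a chromosome into fixed-width windows
#'
#' Partitions positions 1..`chrom_length` into consecutive windows
#' `[k*w + 1, (k+1)*w]`; the last window is truncated at `chrom_length`.
#' Every position is covered exactly once.
#'
#' @param chrom Chromosome name.
#' @param chrom_length Chromosome length in bp (>= 1).
#' @param window Window width in bp (default 1000, the DMR window size).
#' @return Interval data frame of the tiles.
#' @examples
#' tile_windows("chr1", 2500, 1000)  # 1-1000, 1001-2000, 2001-2500
#' @export
tile_windows <- function(chrom, chrom_length, window = 1000L) {
  if (length(window) != 1L || is.na(window) || window < 1)
    stop("window width must be a positive integer")
  if (chrom_length < 1) stop("chrom_length must be >= 1")
  window <- as.integer(window)
  chrom_length <- as.numeric(chrom_length)
  n <- ceiling(chrom_length / window)
  start <- as.integer((seq_len(n) - 1L) * window + 1L)
  end <- as.integer(pmin(seq_len(n) * window, chrom_length))
  data.frame(chrom = chrom, start = start, end = end,
             name = sprintf("%s:%d-%d", chrom, start, end),
             strand = NA_character_, stringsAsFactors = FALSE)
}

#' Interval containment test
#'
#' `TRUE` iff `inner` lies completely within `outer`: same chromosome,
#' `outer$start <= inner$start` and `inner$end <= outer$end`. Vectorised with
#' the usual recycling.
#'
#' @param outer,inner One-row (or recycled) interval data frames.
#' @return Logical vector.
#' @export
interval_contains <- function(outer, inner) {
  outer$chrom == inner$chrom &
    outer$start <= inner$start &
    inner$end <= outer$end
}

#' Containment pairs between DMRs and an enhancer catalog
#'
#' Reports every (enhancer, passing DMR) pair in which the DMR window lies
#' completely within the enhancer ("within" mode, the default) or overlaps it
#' by at least one bp (`mode = "any"`). A DMR sitting in several overlapping
#' enhancers yields one pair per enhancer. If `dmrs` carries a logical
#' `passes` column only passing records are paired.
#'
#' @param dmrs DMR table (interval columns, optionally `passes`).
#' @param enhancers Enhancer interval table.
#' @param mode `"within"` (containment) or `"any"` (>= 1 bp overlap).
#' @return Data frame with enhancer columns (prefix `enhancer_`) and DMR
#'   columns (prefix `dmr_`), one row per pair, sorted by enhancer then DMR.
#' @export
dmrs_in_enhancers <- function(dmrs, enhancers, mode = c("within", "any")) {
  mode <- match.arg(mode)
  validate_intervals(enhancers, "enhancers")
  validate_intervals(dmrs, "dmrs")
  if (!is.null(dmrs$passes)) dmrs <- dmrs[which(dmrs$passes), , drop = FALSE]
  empty <- data.frame(enhancer_chrom = character(), enhancer_start = integer(),
                      enhancer_end = integer(), enhancer_name = character(),
                      dmr_chrom = character(), dmr_start = integer(),
                      dmr_end = integer(), stringsAsFactors = FALSE)
  if (nrow(dmrs) == 0 || nrow(enhancers) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(
    as_granges(dmrs), as_granges(enhancers),
    type = if (mode == "within") "within" else "any",
    minoverlap = 1L)
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  out <- data.frame(
    enhancer_chrom = enhancers$chrom[si],
    enhancer_start = enhancers$start[si],
    enhancer_end = enhancers$end[si],
    enhancer_name = if (is.null(enhancers$name)) NA_character_ else enhancers$name[si],
    dmr_chrom = dmrs$chrom[qi],
    dmr_start = dmrs$start[qi],
    dmr_end = dmrs$end[qi],
    stringsAsFactors = FALSE)
  out <- out[order(out$enhancer_chrom, out$enhancer_start, out$enhancer_end,
                   out$dmr_start, out$dmr_end, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
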