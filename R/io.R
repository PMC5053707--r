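# Readers and writers for the external file dialects. All parsing is
# column-level (tab-delimited tables); every reader documents its coordinate
# convention and converts to the internal 1-based inclusive form on entry.

check_fields <- function(path, sep = "\t") {
  cf <- utils::count.fields(path, sep = sep, comment.char = "")
  if (length(cf) == 0) stop("empty file: ", path)
  bad <- which(cf != cf[1])
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1] + 0L,
         ": expected ", cf[1], " fields, found ", cf[bad[1]])
  invisible(cf[1])
}

#' Read per-CpG methylation calls
#'
#' Reads a tab-delimited CpG call file with a header line. Two dialects are
#' accepted: explicit counts (`chrom, pos, strand, n_meth, n_total`) or a
#' coverage/percent form (`chrom, pos, strand, coverage, freqC`), converted
#' via `n_meth = round(coverage * freqC / 100)`, `n_total = coverage`.
#'
#' @param path File path.
#' @param min_coverage Records with `n_total < min_coverage` are dropped
#'   (default 10).
#' @return Data frame `chrom, pos, strand, n_meth, n_total`, sorted by
#'   (chrom, pos). Duplicate (chrom, pos, strand) records are an error, as is
#'   any record with `n_meth > n_total`.
#' @export
read_cpg_calls <- function(path, min_coverage = 10L) {
  check_fields(path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  names(x) <- tolower(names(x))
  alias <- c(chr = "chrom", chromosome = "chrom", base = "pos",
             position = "pos", coverage = "n_total")
  for (a in names(alias))
    if (a %in% names(x) && !(alias[[a]] %in% names(x)))
      names(x)[names(x) == a] <- alias[[a]]
  if (!all(c("chrom", "pos", "strand") %in% names(x)))
    stop("CpG call file ", path, " lacks chrom/pos/strand columns")
  if (!("n_meth" %in% names(x))) {
    if (!all(c("n_total", "freqc") %in% names(x)))
      stop("CpG call file ", path,
           " must carry n_meth/n_total or coverage/freqC columns")
    x$n_meth <- as.integer(round(x$n_total * x$freqc / 100))
  }
  if (!("n_total" %in% names(x)))
    stop("CpG call file ", path, " lacks an n_total/coverage column")
  x <- x[, c("chrom", "pos", "strand", "n_meth", "n_total")]
  x$pos <- as.integer(x$pos)
  x$n_meth <- as.integer(x$n_meth)
  x$n_total <- as.integer(x$n_total)
  bad <- which(x$n_meth < 0 | x$n_total < 1 | x$n_meth > x$n_total)
  if (length(bad))
    stop("invalid counts in ", path, " at data row ", bad[1],
         ": need 0 <= n_meth <= n_total, n_total >= 1")
  key <- paste(x$chrom, x$pos, x$strand)
  if (anyDuplicated(key))
    stop("duplicate CpG record in ", path, ": ", key[which(duplicated(key))[1]])
  x <- x[x$n_total >= min_coverage, , drop = FALSE]
  x <- x[order(x$chrom, x$pos, method = "radix"), , drop = FALSE]
  rownames(x) <- NULL
  x
}

#' Read genomic intervals from BED or a 1-based coordinate table
#'
#' BED input (`format = "bed"`, no header, 0-based half-open) is converted to
#' the internal 1-based inclusive convention (`start + 1, end`). `"table1"`
#' input is a headered tab-delimited table with 1-based inclusive
#' `chrom, start, end` (and optional `name`) passed through unchanged.
#'
#' @param path File path.
#' @param format `"bed"` or `"table1"`.
#' @return Sorted interval data frame (`chrom, start, end, name, strand`).
#' @export
read_intervals <- function(path, format = c("bed", "table1")) {
  format <- match.arg(format)
  check_fields(path)
  if (format == "bed") {
    x <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
    if (ncol(x) < 3) stop("BED file ", path, " needs at least 3 columns")
    out <- data.frame(chrom = as.character(x[[1]]),
                      start = as.integer(x[[2]]) + 1L,
                      end = as.integer(x[[3]]),
                      name = if (ncol(x) >= 4) as.character(x[[4]]) else NA_character_,
                      strand = if (ncol(x) >= 6) as.character(x[[6]]) else NA_character_,
                      stringsAsFactors = FALSE)
  } else {
    x <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
    names(x) <- tolower(names(x))
    if (!all(c("chrom", "start", "end") %in% names(x)))
      stop("table1-format file ", path, " lacks chrom/start/end columns")
    out <- data.frame(chrom = as.character(x$chrom),
                      start = as.integer(x$start),
                      end = as.integer(x$end),
                      name = if ("name" %in% names(x)) as.character(x$name) else NA_character_,
                      strand = if ("strand" %in% names(x)) as.character(x$strand) else NA_character_,
                      stringsAsFactors = FALSE)
  }
  validate_intervals(out, path)
  sort_intervals(out)
}

#' Write intervals as BED
#'
#' Converts from the internal 1-based inclusive convention back to BED's
#' 0-based half-open (`start - 1, end`); the exact inverse of
#' [read_intervals()] with `format = "bed"`.
#'
#' @param x Interval data frame.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  bed <- data.frame(x$chrom, x$start - 1L, x$end)
  if (!is.null(x$name) && any(!is.na(x$name))) bed$name <- x$name
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a refFlat-like table
#'
#' Expects a headered tab-delimited table with columns `symbol, accession,
#' chrom, strand, tx_start, tx_end` and optional comma-separated
#' `exon_starts`/`exon_ends` (1-based inclusive). The transcription start
#' site is `tx_start` for `+` strand genes and `tx_end` for `-` strand genes.
#'
#' @param path File path.
#' @return Data frame of gene models with a derived `tss` column; exon
#'   coordinates are retained as comma-separated strings (see
#'   [gene_exons()]).
#' @export
read_gene_models <- function(path) {
  check_fields(path)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "")
  names(x) <- tolower(names(x))
  need <- c("symbol", "accession", "chrom", "strand", "tx_start", "tx_end")
  if (!all(need %in% names(x)))
    stop("gene model file ", path, " lacks column(s): ",
         paste(setdiff(need, names(x)), collapse = ", "))
  if (!all(x$strand %in% c("+", "-")))
    stop("gene model strand must be '+' or '-' in ", path)
  x$tx_start <- as.integer(x$tx_start)
  x$tx_end <- as.integer(x$tx_end)
  if (any(x$tx_start > x$tx_end)) stop("tx_start > tx_end in ", path)
  if (!("exon_starts" %in% names(x))) x$exon_starts <- NA_character_
  if (!("exon_ends" %in% names(x))) x$exon_ends <- NA_character_
  x$exon_starts <- as.character(x$exon_starts)
  x$exon_ends <- as.character(x$exon_ends)
  x$tss <- ifelse(x$strand == "+", x$tx_start, x$tx_end)
  out <- x[, c("symbol", "accession", "chrom", "strand", "tx_start", "tx_end",
               "tss", "exon_starts", "exon_ends")]
  for (i in seq_len(nrow(out))) {
    ex <- gene_exons(out[i, ])
    if (!is.null(ex)) {
      if (any(ex$start > ex$end) || is.unsorted(ex$start, strictly = TRUE) ||
          any(ex$start[-1] <= ex$end[-nrow(ex)]) ||
          ex$start[1] < out$tx_start[i] || ex$end[nrow(ex)] > out$tx_end[i])
        stop("exon blocks of ", out$accession[i],
             " must be sorted, non-overlapping and inside the transcript")
    }
  }
  out <- out[order(out$chrom, out$tx_start, out$tx_end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exon table of one gene model
#'
#' @param gene One row of a gene model table.
#' @return Data frame `start, end` in genomic order, or `NULL` when the model
#'   carries no exon structure. A single-exon model spanning the transcript is
#'   representable as `exon_starts = tx_start`, `exon_ends = tx_end`.
#' @export
gene_exons <- function(gene) {
  if (is.na(gene$exon_starts) || !nzchar(as.character(gene$exon_starts)))
    return(NULL)
  gene$exon_starts <- as.character(gene$exon_starts)
  gene$exon_ends <- as.character(gene$exon_ends)
  s <- as.integer(strsplit(gene$exon_starts, ",", fixed = TRUE)[[1]])
  e <- as.integer(strsplit(gene$exon_ends, ",", fixed = TRUE)[[1]])
  if (length(s) != length(e)) stop("exon_starts/exon_ends length mismatch")
  data.frame(start = s, end = e)
}

#' Write a result table
#'
#' Deterministic tab-delimited output: fixed column order (as given), header
#' line, 1-based inclusive coordinates, doubles at six significant digits.
#'
#' @param records Homogeneous data frame (any pipeline record type).
#' @param path Output path.
#' @export
write_records <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- records
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- formatC(out[[j]], digits = 6, format = "g")
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a table written by [write_records()]
#' @param path File path.
#' @return Data frame.
#' @export
read_records <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Write a simulated cohort to disk in the dialects the readers accept
#'
#' Emits one CpG call file per sample plus a sample sheet
#' (`sample_id, group, path`).
#'
#' @param cohort Named list of per-sample CpG call data frames.
#' @param sheet Sample sheet data frame (`sample_id, group`).
#' @param dir Output directory (created if needed).
#' @return The sample sheet with populated `path` column, invisibly; also
#'   written to `dir/samplesheet.tsv`.
#' @export
write_cohort <- function(cohort, sheet, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sheet$path <- file.path(dir, paste0(sheet$sample_id, ".cpg.tsv"))
  for (i in seq_len(nrow(sheet)))
    write_records(cohort[[sheet$sample_id[i]]], sheet$path[i])
  # the written sheet carries paths relative to its own directory, so a
  # cohort directory is relocatable and reruns are byte-identical
  rel <- sheet
  rel$path <- basename(rel$path)
  write_records(rel, file.path(dir, "samplesheet.tsv"))
  invisible(sheet)
}
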