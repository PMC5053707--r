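# Classifies partner regions against gene models (promoter / gene body /
# intergenic) and computes the distance conventions used for reporting:
# strand-aware boundary gaps and TSS distances under explicit anchors. The
# TSS-distance anchor is a parameter because reported conventions mix the
# region's start, its end, and the nearest edge.

#' Promoter interval of a gene
#'
#' The `length` bp immediately upstream of the transcription start site in
#' gene orientation: `[TSS - length, TSS - 1]` for `+` strand genes and
#' `[TSS + 1, TSS + length]` for `-` strand genes, clipped at position 1.
#' The promoter never overlaps the gene body on the TSS side.
#'
#' @param gene One row of a gene model table (needs `chrom, strand, tss`).
#' @param length Promoter length in bp (default 1500).
#' @return One-row interval data frame, or `NULL` for a `+` strand gene whose
#'   TSS is at position 1 (no upstream sequence exists).
#' @export
promoter_of <- function(gene, length = 1500L) {
  stopifnot(nrow(gene) == 1L, gene$strand %in% c("+", "-"))
  if (gene$strand == "+") {
    if (gene$tss <= 1L) return(NULL)
    s <- max(1L, gene$tss - as.integer(length)); e <- gene$tss - 1L
  } else {
    s <- gene$tss + 1L; e <- gene$tss + as.integer(length)
  }
  data.frame(chrom = gene$chrom, start = as.integer(s), end = as.integer(e),
             name = paste0(gene$accession, "_promoter"),
             strand = gene$strand, stringsAsFactors = FALSE)
}

overlaps1 <- function(a, b) {
  a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
}

#' Strand-aware gap between a region and a gene
#'
#' For non-overlapping inputs on the same chromosome, the boundary gap in bp
#' (1-based inclusive arithmetic, always >= 1) and whether the region lies
#' upstream or downstream of the gene in its orientation. For a `+` strand
#' gene, a region beyond `tx_end` is downstream with gap
#' `region$start - tx_end`; the conventions mirror for `-` strand.
#'
#' @param region One-row interval data frame.
#' @param gene One row of a gene model table.
#' @return List `gap_bp`, `relative_position` (`"upstream"`/`"downstream"`).
#' @export
gene_gap_distance <- function(region, gene) {
  stopifnot(nrow(region) == 1L, nrow(gene) == 1L)
  if (region$chrom != gene$chrom)
    stop("region and gene must share a chromosome")
  g <- data.frame(chrom = gene$chrom, start = gene$tx_start, end = gene$tx_end)
  if (overlaps1(region, g))
    stop("gene_gap_distance requires non-overlapping inputs")
  right_of_gene <- region$start > gene$tx_end
  gap <- if (right_of_gene) region$start - gene$tx_end
         else gene$tx_start - region$end
  rel <- if (gene$strand == "+") {
    if (right_of_gene) "downstream" else "upstream"
  } else {
    if (right_of_gene) "upstream" else "downstream"
  }
  list(gap_bp = as.integer(gap), relative_position = rel)
}

#' Distance from a region anchor to a gene's TSS
#'
#' Absolute distance in bp between the TSS (strand rule: `tx_start` for `+`,
#' `tx_end` for `-`) and the chosen anchor of the region. `"nearest_edge"`
#' uses whichever region boundary is closer; for a region containing the TSS
#' this is the distance to the closer boundary.
#'
#' @param region One-row interval data frame.
#' @param gene One row of a gene model table.
#' @param anchor `"nearest_edge"` (default), `"region_start"` or
#'   `"region_end"`.
#' @return Distance in bp (non-negative integer).
#' @export
tss_distance <- function(region, gene,
                         anchor = c("nearest_edge", "region_start", "region_end")) {
  anchor <- match.arg(anchor)
  stopifnot(nrow(region) == 1L, nrow(gene) == 1L)
  if (region$chrom != gene$chrom)
    stop("region and gene must share a chromosome")
  d <- switch(anchor,
              region_start = abs(gene$tss - region$start),
              region_end = abs(gene$tss - region$end),
              nearest_edge = min(abs(gene$tss - region$start),
                                 abs(gene$tss - region$end)))
  as.integer(d)
}

# Exon/intron labels of the gene features a region overlaps, numbered in
# transcription order (exon 1 nearest the TSS). Returns "" when the model
# has no exon structure.
sub_features_of <- function(region, gene) {
  ex <- gene_exons(gene)
  if (is.null(ex)) return("")
  n <- nrow(ex)
  feats <- list()
  for (i in seq_len(n)) {
    tnum <- if (gene$strand == "+") i else n - i + 1L
    feats[[length(feats) + 1L]] <- list(start = ex$start[i], end = ex$end[i],
                                        label = paste("exon", tnum),
                                        rank = 2L * tnum - 1L)
  }
  if (n > 1) for (i in seq_len(n - 1L)) {
    inum <- if (gene$strand == "+") i else n - i
    feats[[length(feats) + 1L]] <- list(start = ex$end[i] + 1L,
                                        end = ex$start[i + 1L] - 1L,
                                        label = paste("intron", inum),
                                        rank = 2L * inum)
  }
  hit <- Filter(function(f) f$start <= region$end && region$start <= f$end, feats)
  if (length(hit) == 0) return("")
  hit <- hit[order(vapply(hit, `[[`, 0L, "rank"))]
  paste(vapply(hit, `[[`, "", "label"), collapse = "; ")
}

#' Classify a region against gene models
#'
#' Priority: promoter > gene body > intergenic. A region overlapping any
#' gene's promoter (see [promoter_of()]) is a promoter region; otherwise a
#' region overlapping a transcript span is gene body, with exon/intron
#' sub-features reported when the model carries exon structure; otherwise the
#' region is intergenic and annotated with the nearest gene by boundary gap
#' and its orientation-aware relative position. Ties (several overlapping
#' genes, or equidistant nearest genes) break to the smaller accession
#' string.
#'
#' @param region One-row interval data frame.
#' @param genes Gene model table (from [read_gene_models()] or equivalent).
#' @param promoter_bp Promoter length upstream of the TSS (default 1500).
#' @param tss_anchor Anchor for the reported TSS distance (see
#'   [tss_distance()]); all three anchor values are also reported.
#' @return List `region`, `category`, `gene` (accession or `NA`), `symbol`,
#'   `sub_features`, `gap_bp` (intergenic only, else `NA`),
#'   `relative_position`, `tss_distance`, and `tss_distances` (named vector,
#'   all three anchors).
#' @export
classify_location <- function(region, genes, promoter_bp = 1500L,
                              tss_anchor = c("nearest_edge", "region_start",
                                             "region_end")) {
  tss_anchor <- match.arg(tss_anchor)
  validate_intervals(region, "region")
  stopifnot(nrow(region) == 1L)
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  g <- g[order(g$accession), , drop = FALSE]
  res <- list(region = region, category = "intergenic", gene = NA_character_,
              symbol = NA_character_, sub_features = "", gap_bp = NA_integer_,
              relative_position = NA_character_, tss_distance = NA_integer_,
              tss_distances = c(nearest_edge = NA_integer_,
                                region_start = NA_integer_,
                                region_end = NA_integer_))
  if (nrow(g) == 0) return(res)

  fill_tss <- function(res, gene) {
    res$tss_distances <- c(
      nearest_edge = tss_distance(region, gene, "nearest_edge"),
      region_start = tss_distance(region, gene, "region_start"),
      region_end = tss_distance(region, gene, "region_end"))
    res$tss_distance <- res$tss_distances[[tss_anchor]]
    res$gene <- gene$accession
    res$symbol <- gene$symbol
    res
  }

  for (i in seq_len(nrow(g))) {
    pr <- promoter_of(g[i, ], promoter_bp)
    if (!is.null(pr) && overlaps1(region, pr)) {
      res$category <- "promoter"
      return(fill_tss(res, g[i, ]))
    }
  }
  for (i in seq_len(nrow(g))) {
    body <- data.frame(chrom = g$chrom[i], start = g$tx_start[i],
                       end = g$tx_end[i])
    if (overlaps1(region, body)) {
      res$category <- "gene_body"
      res$sub_features <- sub_features_of(region, g[i, ])
      return(fill_tss(res, g[i, ]))
    }
  }
  gaps <- vapply(seq_len(nrow(g)), function(i)
    gene_gap_distance(region, g[i, ])$gap_bp, 0L)
  best <- which.min(gaps)  # g is accession-sorted, so ties break to smaller
  gd <- gene_gap_distance(region, g[best, ])
  res$gap_bp <- gd$gap_bp
  res$relative_position <- gd$relative_position
  fill_tss(res, g[best, ])
}

#' Annotate a table of regions
#'
#' Row-wise [classify_location()] flattened to a data frame.
#'
#' @inheritParams classify_location
#' @param regions Interval data frame.
#' @return Data frame with one row per region: coordinates, `category`,
#'   `gene`, `symbol`, `sub_features`, `gap_bp`, `relative_position`, and the
#'   three TSS distances (`tss_nearest_edge`, `tss_region_start`,
#'   `tss_region_end`).
#' @export
annotate_regions <- function(regions, genes, promoter_bp = 1500L,
                             tss_anchor = "nearest_edge") {
  validate_intervals(regions, "regions")
  rows <- lapply(seq_len(nrow(regions)), function(i) {
    a <- classify_location(regions[i, ], genes, promoter_bp, tss_anchor)
    data.frame(chrom = regions$chrom[i], start = regions$start[i],
               end = regions$end[i], category = a$category, gene = a$gene,
               symbol = a$symbol, sub_features = a$sub_features,
               gap_bp = a$gap_bp, relative_position = a$relative_position,
               tss_nearest_edge = a$tss_distances[["nearest_edge"]],
               tss_region_start = a$tss_distances[["region_start"]],
               tss_region_end = a$tss_distances[["region_end"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
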