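# Shared fixtures (hg19 coordinates of the study loci) and independent
# oracles used across the test files. The IGDCC3 exon structure below is
# SYNTHETIC: invented block coordinates inside the real transcript span,
# used only to exercise transcription-order exon/intron numbering.

study_genes <- function() data.frame(
  symbol = c("WNT3A", "CHRM3", "IGDCC3"),
  accession = c("NM_033131", "NM_000740", "NM_004884"),
  chrom = c("chr1", "chr1", "chr15"),
  strand = c("+", "+", "-"),
  tx_start = c(228194722L, 239549876L, 65619464L),
  tx_end = c(228248972L, 240078750L, 65670378L),
  tss = c(228194722L, 239549876L, 65670378L),
  exon_starts = NA_character_, exon_ends = NA_character_,
  stringsAsFactors = FALSE)

igdcc3_synthetic_exons <- function() {
  g <- study_genes()[3, ]
  g$exon_starts <- "65619464,65622001,65628301,65632001,65640001,65670001"
  g$exon_ends <- "65620000,65623000,65628600,65633000,65641000,65670378"
  g
}

study_enhancers <- function() data.frame(
  chrom = c("chr1", "chr10", "chr15"),
  start = c(18958671L, 102414915L, 65377669L),
  end = c(18960284L, 102415578L, 65381418L),
  name = c("1702", "285", "1944"),
  strand = NA_character_, stringsAsFactors = FALSE)

study_dmrs <- function() data.frame(
  chrom = c("chr1", "chr1", "chr15"),
  start = c(228194001L, 240118001L, 65628001L),
  end = c(228195000L, 240119000L, 65629000L),
  name = c("DC1A", "DC1B", "DC15A"),
  stringsAsFactors = FALSE)

make_calls <- function(pos, n_meth, n_total, chrom = "chr1", strand = "+") {
  data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
             n_meth = as.integer(n_meth), n_total = as.integer(n_total),
             stringsAsFactors = FALSE)
}

one_region <- function(chrom, start, end, name = NA_character_) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             name = name, strand = NA_character_, stringsAsFactors = FALSE)
}

# a small, fast synthetic configuration for structural tests
small_config <- function(seed = 7L, ...) {
  sim_config(chrom_length = 4e5, n_cpgs = 4000L, n_planted_dmrs = 10L,
             n_enhancers = 6L, n_diff_enhancers = 2L, n_coupled_pairs = 4L,
             seed = seed, ...)
}

# ---- independent oracles ----

# two-proportion G-statistic on the pooled 2x2 table
g_test_2x2 <- function(m1, t1, m2, t2) {
  obs <- c(m1, t1 - m1, m2, t2 - m2)
  p <- (m1 + m2) / (t1 + t2)
  expc <- c(t1 * p, t1 * (1 - p), t2 * p, t2 * (1 - p))
  terms <- ifelse(obs == 0, 0, obs * log(obs / expc))
  2 * sum(terms)
}

# hand Benjamini-Hochberg step-up with monotonicity enforcement
bh_hand <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# all-pairs containment check
brute_contained <- function(dmrs, enhancers) {
  rows <- list()
  for (i in seq_len(nrow(enhancers))) for (j in seq_len(nrow(dmrs))) {
    if (enhancers$chrom[i] == dmrs$chrom[j] &&
        enhancers$start[i] <= dmrs$start[j] &&
        dmrs$end[j] <= enhancers$end[i])
      rows[[length(rows) + 1L]] <- c(i, j)
  }
  if (length(rows) == 0) return(matrix(integer(0), 0, 2))
  do.call(rbind, rows)
}

# brute-force nearest gene by boundary gap (non-overlapping inputs),
# ties to smaller accession
brute_nearest <- function(region, genes) {
  g <- genes[genes$chrom == region$chrom, , drop = FALSE]
  gaps <- vapply(seq_len(nrow(g)), function(i) {
    if (region$start > g$tx_end[i]) region$start - g$tx_end[i]
    else g$tx_start[i] - region$end
  }, 0L)
  g <- g[order(gaps, g$accession), , drop = FALSE]
  g$accession[1]
}
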