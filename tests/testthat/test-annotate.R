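# Promoter geometry, gap/TSS distance conventions, and region classification.

test_that("promoter is the 1500 bp upstream of the TSS, strand-aware", {
  wnt3a <- study_genes()[1, ]
  pr <- promoter_of(wnt3a)
  expect_equal(pr$start, 228193222L)
  expect_equal(pr$end, 228194721L)
  # the promoter never reaches the TSS side of the gene body
  expect_lt(pr$end, wnt3a$tss)
  minus <- data.frame(symbol = "M", accession = "NM_M", chrom = "chr5",
                      strand = "-", tx_start = 10000L, tx_end = 20000L,
                      tss = 20000L, exon_starts = NA, exon_ends = NA)
  prm <- promoter_of(minus)
  expect_equal(c(prm$start, prm$end), c(20001L, 21500L))
  expect_gt(prm$start, minus$tss)
  clip <- data.frame(symbol = "C", accession = "NM_C", chrom = "chr5",
                     strand = "+", tx_start = 1000L, tx_end = 5000L,
                     tss = 1000L, exon_starts = NA, exon_ends = NA)
  prc <- promoter_of(clip)
  expect_equal(c(prc$start, prc$end), c(1L, 999L))
})

test_that("boundary gaps reproduce the reported distances", {
  genes <- study_genes()
  dc1b <- one_region("chr1", 240118001, 240119000)
  gd <- gene_gap_distance(dc1b, genes[genes$symbol == "CHRM3", ])
  expect_equal(gd$gap_bp, 39251L)
  expect_equal(gd$relative_position, "downstream")
  e1944 <- one_region("chr15", 65377669, 65381418)
  gd2 <- gene_gap_distance(e1944, genes[genes$symbol == "IGDCC3", ])
  expect_equal(gd2$gap_bp, 238046L)
  expect_equal(gd2$relative_position, "downstream")
  # adjacency unit and upstream mirror
  plus <- data.frame(symbol = "P", accession = "NM_P", chrom = "chr7",
                     strand = "+", tx_start = 5000L, tx_end = 6000L,
                     tss = 5000L, exon_starts = NA, exon_ends = NA)
  adj <- gene_gap_distance(one_region("chr7", 6001, 6500), plus)
  expect_equal(adj$gap_bp, 1L)
  expect_equal(adj$relative_position, "downstream")
  up <- gene_gap_distance(one_region("chr7", 1000, 1999), plus)
  expect_equal(up$gap_bp, 3001L)
  expect_equal(up$relative_position, "upstream")
  expect_error(gene_gap_distance(one_region("chr7", 5500, 5600), plus),
               "non-overlapping")
})

test_that("TSS distances reproduce the reported anchor conventions", {
  genes <- study_genes()
  e1702 <- one_region("chr1", 18958671, 18960284)
  expect_equal(tss_distance(e1702, genes[1, ], "region_start"), 209236051L)
  dc1b <- one_region("chr1", 240118001, 240119000)
  expect_equal(tss_distance(dc1b, genes[2, ], "region_start"), 568125L)
  e1944 <- one_region("chr15", 65377669, 65381418)
  expect_equal(tss_distance(e1944, genes[3, ], "region_end"), 288960L)
  # region containing the TSS: nearest edge is the closer boundary
  span <- one_region("chr1", 228194000, 228195000)
  expect_equal(tss_distance(span, genes[1, ], "nearest_edge"),
               min(abs(228194722 - 228194000), abs(228194722 - 228195000)))
  expect_error(tss_distance(one_region("chr9", 1, 2), genes[1, ]),
               "chromosome")
})

test_that("classification priority and study-locus categories hold", {
  genes <- rbind(study_genes()[1:2, ], igdcc3_synthetic_exons())
  # DC1A overlaps the WNT3A promoter (and its gene body): promoter wins
  a <- classify_location(one_region("chr1", 228194001, 228195000), genes)
  expect_equal(a$category, "promoter")
  expect_equal(a$symbol, "WNT3A")
  # DC15A sits in the IGDCC3 gene body
  b <- classify_location(one_region("chr15", 65628001, 65629000), genes)
  expect_equal(b$category, "gene_body")
  expect_equal(b$symbol, "IGDCC3")
  # transcription-order numbering on the minus strand (synthetic exons)
  expect_equal(b$sub_features, "intron 3; exon 4; intron 4")
  # DC1B is intergenic, downstream of CHRM3
  c3 <- classify_location(one_region("chr1", 240118001, 240119000), genes)
  expect_equal(c3$category, "intergenic")
  expect_equal(c3$symbol, "CHRM3")
  expect_equal(c3$gap_bp, 39251L)
  expect_equal(c3$relative_position, "downstream")
  # no genes on the chromosome: intergenic with absent gene
  d <- classify_location(one_region("chrX", 1, 1000), genes)
  expect_equal(d$category, "intergenic")
  expect_true(is.na(d$gene))
})

test_that("a region in one gene's promoter and another's body is a promoter", {
  genes <- data.frame(
    symbol = c("A", "B"), accession = c("NM_A", "NM_B"), chrom = "chr1",
    strand = "+", tx_start = c(10000L, 1000L), tx_end = c(20000L, 30000L),
    tss = c(10000L, 1000L), exon_starts = NA_character_,
    exon_ends = NA_character_, stringsAsFactors = FALSE)
  r <- classify_location(one_region("chr1", 9000, 9500), genes)
  expect_equal(r$category, "promoter")
  expect_equal(r$symbol, "A")
})

test_that("nearest-gene choice equals the brute-force oracle", {
  for (seed in 1:100) {
    set.seed(seed + 500)
    n_g <- sample(2:8, 1)
    tx_start <- sort(sample(seq(1e4, 9e5, by = 1e4), n_g))
    genes <- data.frame(symbol = paste0("G", 1:n_g),
                        accession = paste0("NM_", sample(100:999, n_g)),
                        chrom = "chr1", strand = sample(c("+", "-"), n_g, TRUE),
                        tx_start = as.integer(tx_start),
                        tx_end = as.integer(tx_start + 5000L),
                        exon_starts = NA_character_, exon_ends = NA_character_,
                        stringsAsFactors = FALSE)
    genes$tss <- ifelse(genes$strand == "+", genes$tx_start, genes$tx_end)
    # drop a region into a gap between genes
    i <- sample(n_g - 1, 1)
    lo <- genes$tx_end[i] + 2L
    hi <- genes$tx_start[i + 1] - 2L
    if (hi - lo < 10) next
    s <- sample(seq(lo, hi - 5L), 1)
    region <- one_region("chr1", s, min(s + 4L, hi))
    got <- classify_location(region, genes, promoter_bp = 1)
    if (got$category != "intergenic") next  # landed in a 1 bp promoter
    expect_equal(got$gene, brute_nearest(region, genes))
  }
})

test_that("annotate_regions flattens classifications row-wise", {
  genes <- rbind(study_genes()[1:2, ], igdcc3_synthetic_exons())
  out <- annotate_regions(study_dmrs()[, c("chrom", "start", "end")], genes)
  expect_equal(nrow(out), 3L)
  expect_equal(out$category[out$start == 228194001], "promoter")
  expect_equal(out$category[out$start == 65628001], "gene_body")
  expect_equal(out$gap_bp[out$start == 240118001], 39251L)
  expect_true(all(c("tss_nearest_edge", "tss_region_start",
                    "tss_region_end") %in% names(out)))
})
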