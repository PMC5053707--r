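# Pearson machinery and the intrachromosomal correlation screen.

test_that("Pearson r handles exact, hand-computed and degenerate cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(as.numeric(pearson_r(x, x)), 1)
  expect_equal(as.numeric(pearson_r(x, -2 * x + 7)), -1)
  expect_equal(as.numeric(pearson_r(x, c(1, 3, 2, 4))), 0.8)
  z <- pearson_r(x, rep(2, 4))
  expect_true(is.na(z))
  expect_equal(attr(z, "reason"), "zero variance")
  s <- pearson_r(c(1, 2, NA, NA), c(1, 2, 3, 4))
  expect_true(is.na(s))
  expect_equal(attr(s, "reason"), "n < 3")
})

test_that("r is symmetric and affine-equivariant", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- as.numeric(pearson_r(x, y))
    expect_equal(as.numeric(pearson_r(y, x)), r)
    expect_equal(as.numeric(pearson_r(3 * x + 2, y)), r)
    expect_equal(as.numeric(pearson_r(-3 * x + 2, y)), -r)
  }
})

test_that("correlation p-values reproduce the printed validation values", {
  expect_equal(signif(pearson_pvalue(0.634, 24), 2), 0.00088)
  expect_equal(signif(pearson_pvalue(0.493, 24), 2), 0.014)
  expect_equal(signif(pearson_pvalue(0.089, 24), 3), 0.679)
  expect_equal(pearson_pvalue(0, 10), 1)
  expect_equal(pearson_pvalue(1, 10), 0)
  expect_error(pearson_pvalue(0.5, 2), "n >= 3")
})

test_that("p is monotone in |r| at fixed n and in n at fixed |r|", {
  rs <- seq(0.05, 0.95, by = 0.05)
  p_at_n10 <- pearson_pvalue(rs, 10)
  expect_true(all(diff(p_at_n10) < 0))
  ns <- c(5, 8, 11, 24, 50)
  p_at_r6 <- vapply(ns, function(n) pearson_pvalue(0.6, n), 0)
  expect_true(all(diff(p_at_r6) < 0))
})

test_that("strength labels follow the |r| >= 0.5 scale", {
  expect_equal(classify_strength(0.634), "good to excellent")
  expect_equal(classify_strength(0.493), "moderate to nil")
  expect_equal(classify_strength(-1), "good to excellent")
  expect_equal(classify_strength(c(0.5, -0.5, 0.49)),
               c("good to excellent", "good to excellent", "moderate to nil"))
})

make_screen_fixture <- function() {
  # two DMEs (chr1, chr2), three DMRs; values crafted so dmr_a tracks the
  # chr1 enhancer exactly, dmr_b anti-tracks it, dmr_c is contained in it
  samples <- paste0("s", 1:8)
  enh <- data.frame(chrom = c("chr1", "chr2"), start = c(1000L, 1000L),
                    end = c(5000L, 5000L), name = c("E1", "E2"),
                    selected = TRUE, stringsAsFactors = FALSE)
  dmr <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr3"),
                    start = c(10001L, 20001L, 2001L, 1L),
                    end = c(11000L, 21000L, 3000L, 1000L),
                    passes = TRUE, stringsAsFactors = FALSE)
  v <- seq(0.1, 0.8, length.out = 8)
  m <- rbind("chr1:1000-5000" = v,
             "chr2:1000-5000" = rev(v),
             "chr1:10001-11000" = v + 0.02,
             "chr1:20001-21000" = 0.9 - v,
             "chr1:2001-3000" = v,
             "chr3:1-1000" = v)
  colnames(m) <- samples
  list(enh = enh, dmr = dmr, m = m)
}

test_that("screen applies intrachromosomal, containment and threshold rules", {
  fx <- make_screen_fixture()
  out <- screen_pairs(fx$enh, fx$dmr, fx$m)
  # E2 (chr2) has no same-chromosome DMRs; E1 excludes its contained DMR
  expect_equal(nrow(out), 2L)
  expect_false(any(out$partner_start == 2001))
  expect_false(any(out$enhancer_chrom == "chr2"))
  expect_true(all(out$passes))
  expect_equal(sort(sign(out$r)), c(-1, 1))
  expect_true(all(abs(out$r) >= 0.85 & out$q_value <= 0.05 & out$n >= 3))
  expect_equal(out$strength, rep("good to excellent", 2))
})

test_that("screen equals a brute-force recomputation on its fixture", {
  fx <- make_screen_fixture()
  out <- screen_pairs(fx$enh, fx$dmr, fx$m)
  for (i in seq_len(nrow(out))) {
    eid <- sprintf("%s:%d-%d", out$enhancer_chrom[i], out$enhancer_start[i],
                   out$enhancer_end[i])
    did <- sprintf("%s:%d-%d", out$partner_chrom[i], out$partner_start[i],
                   out$partner_end[i])
    r <- cor(fx$m[eid, ], fx$m[did, ])
    expect_equal(out$r[i], r)
    tstat <- r * sqrt(8 - 2) / sqrt(1 - r^2)
    expect_equal(out$p_value[i], 2 * pt(-abs(tstat), 6))
  }
  # per-enhancer BH on the candidate family
  fam <- out$p_value[out$enhancer_name == "E1"]
  expect_equal(out$q_value[out$enhancer_name == "E1"], bh_hand(fam))
})

test_that("pooled FDR family and empty candidate sets behave", {
  fx <- make_screen_fixture()
  pooled <- screen_pairs(fx$enh, fx$dmr, fx$m, fdr_family = "pooled")
  expect_equal(pooled$q_value, bh_hand(pooled$p_value))
  none <- screen_pairs(fx$enh[fx$enh$name == "E2", ], fx$dmr, fx$m)
  expect_equal(nrow(none), 0L)
  no_dme <- fx$enh; no_dme$selected <- FALSE
  expect_equal(nrow(screen_pairs(no_dme, fx$dmr, fx$m)), 0L)
})

test_that("an anti-coupled planted pair passes with negative r", {
  cfg <- small_config(seed = 29)
  truth <- plant_truth(cfg)
  neg <- truth$coupled_pairs[truth$coupled_pairs$sign == -1L, ]
  expect_gt(nrow(neg), 0)  # seed chosen arbitrarily; config plants 4 pairs
  sim <- simulate_cohort_counts(truth, cfg)
  d <- call_dmrs(sim$calls, sim$sheet,
                 chrom_lengths = c(chrS1 = cfg$chrom_length))
  pairs <- dmrs_in_enhancers(d, truth$enhancers[, c("chrom", "start", "end", "name")])
  regions <- unique(rbind(
    data.frame(chrom = pairs$enhancer_chrom, start = pairs$enhancer_start,
               end = pairs$enhancer_end),
    d[d$passes, c("chrom", "start", "end")]))
  m <- region_meth_matrix(regions, sim$calls)
  dmes <- select_dmes(pairs, m, sim$sheet)
  scr <- screen_pairs(dmes, d, m)
  pd <- truth$dmr_windows[match(neg$partner, truth$dmr_windows$name), ]
  hit <- merge(scr, data.frame(enhancer_name = neg$enhancer,
                               partner_start = pd$start))
  expect_gt(nrow(hit), 0)
  expect_true(all(hit$r <= -0.85 & hit$passes))
})
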