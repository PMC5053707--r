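# Generator structure, determinism, and the planted statistical signal.

test_that("config validation enforces the stated invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(dmr_delta = 0))
  expect_error(sim_config(dmr_delta = 1.5))
  expect_error(sim_config(n_group1 = 0))
  expect_error(sim_config(n_coupled_pairs = 25, n_enhancers = 20))
  expect_error(sim_config(n_coupled_pairs = 5, n_diff_enhancers = 0),
               "differential enhancer")
  expect_error(sim_config(n_planted_dmrs = 5, n_coupled_pairs = 5),
               "partners")
})

test_that("planted truth matches the configuration counts and grid", {
  cfg <- sim_config(seed = 41)
  truth <- plant_truth(cfg)
  expect_equal(nrow(truth$dmr_windows), cfg$n_planted_dmrs)
  expect_equal(nrow(truth$enhancers), cfg$n_enhancers)
  expect_equal(nrow(truth$coupled_pairs), cfg$n_coupled_pairs)
  expect_equal(sum(truth$enhancers$differential), cfg$n_diff_enhancers)
  # DMR windows are 1000 bp and grid-aligned
  expect_true(all(truth$dmr_windows$end - truth$dmr_windows$start + 1 == 1000))
  expect_true(all((truth$dmr_windows$start - 1) %% 1000 == 0))
  # true group means differ by exactly dmr_delta
  expect_equal(abs(truth$dmr_windows$mean_g1 - truth$dmr_windows$mean_g2),
               rep(cfg$dmr_delta, nrow(truth$dmr_windows)))
  # elements do not overlap
  all_el <- rbind(truth$dmr_windows[, c("chrom", "start", "end")],
                  truth$enhancers[, c("chrom", "start", "end")])
  all_el <- all_el[order(all_el$start), ]
  solo_enh <- rbind(
    truth$dmr_windows[truth$dmr_windows$role != "contained",
                      c("chrom", "start", "end")],
    truth$enhancers[, c("chrom", "start", "end")])
  solo_enh <- solo_enh[order(solo_enh$start), ]
  expect_true(all(solo_enh$start[-1] > solo_enh$end[-nrow(solo_enh)]))
  # contained DMRs sit inside their differential enhancer
  cont <- truth$dmr_windows[truth$dmr_windows$role == "contained", ]
  for (i in seq_len(nrow(cont))) {
    e <- truth$enhancers[cont$family[i], ]
    expect_true(interval_contains(e[, c("chrom", "start", "end")],
                                  cont[i, c("chrom", "start", "end")]))
  }
  # coupled partners share the enhancer's chromosome
  for (i in seq_len(nrow(truth$coupled_pairs))) {
    p <- truth$coupled_pairs[i, ]
    expect_equal(
      truth$dmr_windows$chrom[truth$dmr_windows$name == p$partner],
      truth$enhancers$chrom[truth$enhancers$name == p$enhancer])
  }
  # zero planted elements gives an empty truth
  empty <- plant_truth(sim_config(n_planted_dmrs = 0, n_diff_enhancers = 0,
                                  n_coupled_pairs = 0, seed = 1))
  expect_equal(nrow(empty$dmr_windows), 0L)
  # infeasible placement is a configuration error
  expect_error(plant_truth(sim_config(chrom_length = 3e4, seed = 1)),
               "without overlap")
})

test_that("identical seed and config give byte-identical outputs", {
  cfg <- small_config(seed = 33)
  t1 <- plant_truth(cfg); t2 <- plant_truth(cfg)
  expect_identical(t1, t2)
  s1 <- simulate_cohort_counts(t1, cfg)
  s2 <- simulate_cohort_counts(t2, cfg)
  expect_identical(s1, s2)
  c1 <- simulate_capture_cohort(t1, cfg, n_samples = 4, reads_per_sample = 1e4)
  c2 <- simulate_capture_cohort(t2, cfg, n_samples = 4, reads_per_sample = 1e4)
  expect_identical(c1, c2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(s1$calls, s1$sheet, d1)
  write_cohort(s2$calls, s2$sheet, d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # and a different seed changes the draw
  s3 <- simulate_cohort_counts(plant_truth(small_config(seed = 34)),
                               small_config(seed = 34))
  expect_false(identical(s1$calls, s3$calls))
})

test_that("counts respect the generative envelope", {
  cfg <- small_config(seed = 35)
  truth <- plant_truth(cfg)
  sim <- simulate_cohort_counts(truth, cfg)
  expect_equal(length(sim$calls), cfg$n_group1 + cfg$n_group2)
  expect_equal(as.vector(table(sim$sheet$group)[c("group1", "group2")]),
               c(cfg$n_group1, cfg$n_group2))
  for (s in sim$calls[c(1, 11)]) {
    expect_equal(nrow(s), cfg$n_cpgs)
    expect_true(all(s$n_total >= 1))
    expect_true(all(s$n_meth >= 0 & s$n_meth <= s$n_total))
    expect_false(is.unsorted(s$pos))
  }
  # written files are readable by the package's own reader
  d <- withr::local_tempdir()
  sheet <- write_cohort(sim$calls, sim$sheet, d)
  back <- read_cpg_calls(sheet$path[1], min_coverage = 1)
  expect_equal(back$n_meth, sim$calls[[1]]$n_meth)
})

test_that("a planted 0.2-vs-0.8 window shows a ~60 point pooled difference", {
  # Monte-Carlo mean of the realised pooled difference over planted windows,
  # aggregated across replicate cohorts, against the analytic 0.6
  diffs <- c()
  for (seed in 1:3) {
    cfg <- small_config(seed = 100 + seed, sample_sd = 0)
    truth <- plant_truth(cfg)
    sim <- simulate_cohort_counts(truth, cfg)
    g1 <- truth$sample_ids[truth$groups == "group1"]
    solo <- truth$dmr_windows[truth$dmr_windows$role == "solo", ]
    for (i in seq_len(nrow(solo))) {
      cnt <- aggregate_window_counts(solo[i, c("chrom", "start", "end")],
                                     sim$calls)
      p1 <- sum(cnt$n_meth[cnt$sample_id %in% g1]) /
        sum(cnt$n_total[cnt$sample_id %in% g1])
      p2 <- sum(cnt$n_meth[!cnt$sample_id %in% g1]) /
        sum(cnt$n_total[!cnt$sample_id %in% g1])
      diffs <- c(diffs, abs(p1 - p2))
    }
  }
  expect_equal(mean(diffs), 0.6, tolerance = 0.05)
})

test_that("coupled enhancer-partner region means correlate strongly", {
  # expectation of sample-level r under the generative model, averaged over
  # replicate cohorts at the documented coupling defaults
  rs <- c()
  for (seed in 1:3) {
    cfg <- small_config(seed = 200 + seed)
    truth <- plant_truth(cfg)
    sim <- simulate_cohort_counts(truth, cfg)
    regions <- rbind(truth$enhancers[, c("chrom", "start", "end")],
                     truth$dmr_windows[, c("chrom", "start", "end")])
    m <- region_meth_matrix(regions, sim$calls)
    for (i in seq_len(nrow(truth$coupled_pairs))) {
      p <- truth$coupled_pairs[i, ]
      e <- truth$enhancers[truth$enhancers$name == p$enhancer, ]
      d <- truth$dmr_windows[truth$dmr_windows$name == p$partner, ]
      r <- pearson_r(m[region_id(e[, c("chrom", "start", "end")]), ],
                     m[region_id(d[, c("chrom", "start", "end")]), ])
      rs <- c(rs, p$sign * as.numeric(r))
    }
  }
  expect_gt(mean(rs), 0.85)
})

test_that("a null cohort produces no passing DMRs", {
  cfg <- sim_config(n_planted_dmrs = 0, n_diff_enhancers = 0,
                    n_coupled_pairs = 0, chrom_length = 1e6, n_cpgs = 10000,
                    seed = 55)
  truth <- plant_truth(cfg)
  sim <- simulate_cohort_counts(truth, cfg)
  d <- call_dmrs(sim$calls, sim$sheet,
                 chrom_lengths = c(chrS1 = cfg$chrom_length))
  expect_lte(mean(d$passes), 0.001)
})

test_that("capture rpkm of a positively coupled pair correlates positively", {
  # Monte-Carlo over replicate capture cohorts
  rs <- c()
  for (seed in 1:3) {
    cfg <- small_config(seed = 300 + seed)
    truth <- plant_truth(cfg)
    pos <- truth$coupled_pairs[truth$coupled_pairs$sign == 1L, ]
    if (nrow(pos) == 0) next
    cap <- simulate_capture_cohort(truth, cfg, n_samples = 12,
                                   reads_per_sample = 3e4)
    prof <- capture_profiles(cap$reads, cap$regions,
                             total_reads = cap$total_reads)
    for (i in seq_len(nrow(pos))) {
      eid <- region_id(truth$enhancers[truth$enhancers$name == pos$enhancer[i],
                                       c("chrom", "start", "end")])
      did <- region_id(truth$dmr_windows[
        truth$dmr_windows$name == pos$partner[i], c("chrom", "start", "end")])
      rs <- c(rs, as.numeric(pearson_r(prof[eid, ], prof[did, ])))
    }
  }
  expect_gt(length(rs), 0)
  expect_gt(mean(rs), 0.5)
  expect_true(all(rs > 0))
})
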