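# Seeded generator for (i) a two-group beta-binomial bisulfite-count cohort
# with planted 1000-bp DMR windows, differential enhancers and latent-factor
# coupled enhancer-partner pairs, and (ii) a capture-seq read-interval cohort
# whose region rpkm tracks the same latent structure. All planted elements
# are placed in disjoint blocks of the window grid, so recovery by the
# window test is unambiguous; the full ground truth is returned for
# parameter-recovery testing.

#' Simulation configuration
#'
#' Defaults encode the emulated study design: 6 vs 5 samples, one 2-Mb
#' chromosome carrying 20,000 CpGs, negative-binomial coverage around 30x,
#' beta-binomial methylation with precision 50, 50 planted 1000-bp DMR
#' windows at a 60-percentage-point group difference, 20 enhancers
#' (1-4 kb) of which 3 carry group effects, and 10 latent-factor coupled
#' enhancer-partner pairs.
#'
#' @param n_group1,n_group2 Samples per group (defaults 6 and 5).
#' @param chrom,chrom_length Simulated chromosome name and length in bp.
#' @param n_cpgs Number of CpG sites.
#' @param coverage_mean,coverage_dispersion Negative-binomial coverage mean
#'   and size parameter (coverage is floored at 1 read).
#' @param beta_precision Beta-binomial precision (shape1 + shape2) of the
#'   per-CpG per-sample methylation level.
#' @param n_planted_dmrs Planted 1000-bp DMR windows (grid-aligned).
#' @param dmr_delta True group methylation difference on `[0, 1]`
#'   (default 0.6, i.e. group means 0.2 vs 0.8).
#' @param n_enhancers Enhancers in the catalog.
#' @param enhancer_length_range Enhancer lengths in bp (uniform draw).
#' @param n_diff_enhancers Enhancers carrying a group effect, each containing
#'   one planted DMR window (default 3).
#' @param n_coupled_pairs Coupled (enhancer, partner DMR) pairs, distributed
#'   round-robin over the differential enhancers (default 10).
#' @param coupling_strengths Slopes `(a, b)` of the enhancer and partner
#'   means on the shared standard-normal latent factor.
#' @param sample_sd Within-group per-sample sd of uncoupled planted element
#'   means (biological variability; default 0.08).
#' @param window Grid/window width in bp.
#' @param mean_clamp Planted per-sample means are clamped to this interval
#'   to keep Pearson correlations defined.
#' @param island_mean,open_mean Background CpG means inside/outside the
#'   simulated CpG-dense segments (identical in both groups).
#' @param n_islands,island_length Number and length of the CpG-dense
#'   low-methylation background segments.
#' @param seed Integer seed; identical seed and config give byte-identical
#'   output.
#' @return A validated config list of class `"sim_config"`.
#' @export
sim_config <- function(n_group1 = 6L, n_group2 = 5L, chrom = "chrS1",
                       chrom_length = 2e6, n_cpgs = 20000L,
                       coverage_mean = 30, coverage_dispersion = 8,
                       beta_precision = 50, n_planted_dmrs = 50L,
                       dmr_delta = 0.6, n_enhancers = 20L,
                       enhancer_length_range = c(1000L, 4000L),
                       n_diff_enhancers = 3L, n_coupled_pairs = 10L,
                       coupling_strengths = c(0.08, 0.08), sample_sd = 0.08,
                       window = 1000L, mean_clamp = c(0.02, 0.98),
                       island_mean = 0.1, open_mean = 0.8, n_islands = 300L,
                       island_length = 1000L, seed = 1L) {
  cfg <- list(n_group1 = as.integer(n_group1), n_group2 = as.integer(n_group2),
              chrom = chrom, chrom_length = chrom_length,
              n_cpgs = as.integer(n_cpgs), coverage_mean = coverage_mean,
              coverage_dispersion = coverage_dispersion,
              beta_precision = beta_precision,
              n_planted_dmrs = as.integer(n_planted_dmrs),
              dmr_delta = dmr_delta, n_enhancers = as.integer(n_enhancers),
              enhancer_length_range = as.integer(enhancer_length_range),
              n_diff_enhancers = as.integer(n_diff_enhancers),
              n_coupled_pairs = as.integer(n_coupled_pairs),
              coupling_strengths = coupling_strengths,
              sample_sd = sample_sd, window = as.integer(window),
              mean_clamp = mean_clamp, island_mean = island_mean,
              open_mean = open_mean, n_islands = as.integer(n_islands),
              island_length = as.integer(island_length),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_group1 >= 1, n_group2 >= 1, chrom_length >= window,
              n_cpgs >= 1, coverage_mean > 0, coverage_dispersion > 0,
              beta_precision > 0, dmr_delta > 0, dmr_delta <= 1,
              n_planted_dmrs >= 0, n_enhancers >= 0, n_diff_enhancers >= 0,
              n_coupled_pairs >= 0,
              n_coupled_pairs <= n_enhancers,
              n_diff_enhancers <= n_enhancers,
              n_diff_enhancers <= n_planted_dmrs || n_diff_enhancers == 0,
              length(enhancer_length_range) == 2,
              enhancer_length_range[1] >= window,
              length(coupling_strengths) == 2,
              mean_clamp[1] > 0, mean_clamp[2] < 1)
  })
  if (cfg$n_coupled_pairs > 0 && cfg$n_diff_enhancers == 0)
    stop("coupled pairs require at least one differential enhancer")
  if (cfg$n_coupled_pairs > max(0, cfg$n_planted_dmrs - cfg$n_diff_enhancers))
    stop("not enough planted DMR windows to serve as coupled partners")
  structure(cfg, class = "sim_config")
}

clamp <- function(x, lim) pmin(pmax(x, lim[1]), lim[2])

#' Plant the simulation ground truth
#'
#' Places non-overlapping enhancers and grid-aligned 1000-bp DMR windows in
#' disjoint blocks of the window grid, assigns true group means differing by
#' exactly `dmr_delta`, designates differential enhancers (each containing
#' one planted DMR, hypermethylated in group 1), selects coupled partner
#' DMRs with signs, and draws the per-sample latent factors (one standard
#' normal factor per differential-enhancer family). Under a `sign = -1`
#' coupling, partner means decrease as enhancer means increase across
#' samples by construction.
#'
#' @param config A [sim_config()] object.
#' @return List of class `"truth_set"`: `dmr_windows` (with per-group true
#'   means, role, coupling sign and family), `enhancers`, `coupled_pairs`,
#'   `latent_factors` (samples x families matrix), `islands`, `sample_ids`,
#'   `groups`, and the config.
#' @export
plant_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  w <- config$window
  n_windows <- floor(config$chrom_length / w)
  block_w <- ceiling(max(config$enhancer_length_range) / w) + 2L  # windows/block
  n_blocks <- floor(n_windows / block_w)
  n_solo <- config$n_planted_dmrs - config$n_diff_enhancers
  need <- config$n_enhancers + n_solo
  if (need > n_blocks)
    stop("cannot place ", need, " elements without overlap: only ", n_blocks,
         " placement blocks available; enlarge chrom_length")
  blocks <- sort(sample.int(n_blocks, need))
  enh_blocks <- blocks[seq_len(config$n_enhancers)]
  solo_blocks <- if (n_solo > 0) blocks[config$n_enhancers + seq_len(n_solo)]
                 else integer(0)

  samples <- c(paste0("g1_s", seq_len(config$n_group1)),
               paste0("g2_s", seq_len(config$n_group2)))
  groups <- c(rep("group1", config$n_group1), rep("group2", config$n_group2))

  lo <- 0.5 - config$dmr_delta / 2
  hi <- 0.5 + config$dmr_delta / 2

  # enhancers: block b spans windows (b-1)*block_w + 1 .. b*block_w; the
  # element anchors on the block's second grid window
  enh <- data.frame(chrom = config$chrom, start = integer(config$n_enhancers),
                    end = integer(config$n_enhancers),
                    name = paste0("ENH", seq_len(config$n_enhancers)),
                    differential = FALSE, family = NA_integer_,
                    mean_g1 = NA_real_, mean_g2 = NA_real_,
                    stringsAsFactors = FALSE)
  dmr <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                    name = character(0), mean_g1 = numeric(0),
                    mean_g2 = numeric(0), role = character(0),
                    family = integer(0), sign = integer(0),
                    stringsAsFactors = FALSE)
  if (config$n_enhancers > 0) for (i in seq_len(config$n_enhancers)) {
    anchor_start <- (enh_blocks[i] - 1L) * block_w * w + w + 1L  # 2nd window
    len <- sample(seq(config$enhancer_length_range[1],
                      config$enhancer_length_range[2]), 1L)
    left <- sample.int(min(len - w, w - 1L) + 1L, 1L) - 1L  # 0..min(len-w, w-1)
    enh$start[i] <- anchor_start - left
    enh$end[i] <- enh$start[i] + len - 1L
    if (i <= config$n_diff_enhancers) {
      enh$differential[i] <- TRUE
      enh$family[i] <- i
      enh$mean_g1[i] <- hi  # hypermethylated in group 1 (the CIMP-like group)
      enh$mean_g2[i] <- lo
      dmr <- rbind(dmr, data.frame(
        chrom = config$chrom, start = anchor_start, end = anchor_start + w - 1L,
        name = paste0("DMR", nrow(dmr) + 1L), mean_g1 = hi, mean_g2 = lo,
        role = "contained", family = i, sign = 1L, stringsAsFactors = FALSE))
    }
  }
  if (n_solo > 0) for (b in solo_blocks) {
    s <- (b - 1L) * block_w * w + w + 1L
    dmr <- rbind(dmr, data.frame(
      chrom = config$chrom, start = s, end = s + w - 1L,
      name = paste0("DMR", nrow(dmr) + 1L), mean_g1 = NA_real_,
      mean_g2 = NA_real_, role = "solo", family = NA_integer_, sign = 0L,
      stringsAsFactors = FALSE))
  }

  # coupled partners: drawn from the solo pool, round-robin over families
  pairs <- data.frame(enhancer = character(0), partner = character(0),
                      family = integer(0), sign = integer(0), a = numeric(0),
                      b = numeric(0), stringsAsFactors = FALSE)
  if (config$n_coupled_pairs > 0) {
    solo_idx <- which(dmr$role == "solo")
    partner_idx <- sort(sample(solo_idx, config$n_coupled_pairs))
    fam <- rep(seq_len(config$n_diff_enhancers),
               length.out = config$n_coupled_pairs)
    sgn <- ifelse(stats::runif(config$n_coupled_pairs) < 0.5, 1L, -1L)
    for (k in seq_len(config$n_coupled_pairs)) {
      i <- partner_idx[k]
      dmr$role[i] <- "partner"
      dmr$family[i] <- fam[k]
      dmr$sign[i] <- sgn[k]
      pairs <- rbind(pairs, data.frame(
        enhancer = enh$name[fam[k]], partner = dmr$name[i], family = fam[k],
        sign = sgn[k], a = config$coupling_strengths[1],
        b = config$coupling_strengths[2], stringsAsFactors = FALSE))
    }
  }
  # orientation of planted DMR means: contained follow the enhancer (hyper in
  # group 1); partners follow sign; solo DMRs get a random direction
  for (i in seq_len(nrow(dmr))) {
    if (dmr$role[i] == "partner") {
      if (dmr$sign[i] == 1L) { dmr$mean_g1[i] <- hi; dmr$mean_g2[i] <- lo }
      else { dmr$mean_g1[i] <- lo; dmr$mean_g2[i] <- hi }
    } else if (dmr$role[i] == "solo") {
      if (stats::runif(1) < 0.5) { dmr$mean_g1[i] <- hi; dmr$mean_g2[i] <- lo }
      else { dmr$mean_g1[i] <- lo; dmr$mean_g2[i] <- hi }
    }
  }

  latent <- matrix(stats::rnorm(length(samples) *
                                  max(1L, config$n_diff_enhancers)),
                   nrow = length(samples),
                   dimnames = list(samples, NULL))

  # background CpG-dense segments (low methylation, identical across groups)
  isl_start <- sort(sample.int(max(1L, config$chrom_length -
                                     config$island_length),
                               config$n_islands))
  islands <- data.frame(chrom = config$chrom, start = isl_start,
                        end = isl_start + config$island_length - 1L,
                        stringsAsFactors = FALSE)

  structure(list(dmr_windows = dmr, enhancers = enh, coupled_pairs = pairs,
                 latent_factors = latent, islands = islands,
                 sample_ids = samples, groups = groups, config = config),
            class = "truth_set")
}

# Per-sample planted mean for element row `el` (needs mean_g1/mean_g2 and,
# when coupled, slope*latent). groups/latent align with `samples`.
planted_means <- function(el, slope, truth) {
  cfg <- truth$config
  base <- ifelse(truth$groups == "group1", el$mean_g1, el$mean_g2)
  if (!is.na(el$family) && slope != 0) {
    u <- truth$latent_factors[, el$family]
    sgn <- if (!is.null(el$sign) && el$sign != 0L) el$sign else 1L
    base <- base + sgn * slope * u
  } else if (cfg$sample_sd > 0) {
    base <- base + stats::rnorm(length(base), 0, cfg$sample_sd)
  }
  clamp(base, cfg$mean_clamp)
}

#' Simulate the two-group bisulfite-count cohort
#'
#' Per CpG and sample: coverage ~ negative binomial (floored at one read),
#' methylation level theta ~ Beta with mean given by the planted/background
#' truth and precision `beta_precision`, methylated count ~
#' Binomial(coverage, theta). Background CpG means follow a bimodal pattern
#' (low inside the CpG-dense segments, high elsewhere) identical in both
#' groups; planted elements override the background with their per-sample
#' means: group base plus the shared latent term for coupled elements, group
#' base plus independent within-group noise for uncoupled planted elements.
#'
#' @param truth A [plant_truth()] result.
#' @param config The same [sim_config()] used to plant the truth.
#' @return List `calls` (named list of per-sample CpG call data frames) and
#'   `sheet` (sample sheet `sample_id, group, path`).
#' @export
simulate_cohort_counts <- function(truth, config) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n_s <- length(truth$sample_ids)
  pos <- sort(sample.int(config$chrom_length, config$n_cpgs))

  in_island <- rep(FALSE, config$n_cpgs)
  if (nrow(truth$islands) > 0) {
    o <- GenomicRanges::findOverlaps(
      GenomicRanges::GRanges(config$chrom, IRanges::IRanges(pos, width = 1L)),
      as_granges(truth$islands))
    in_island[unique(S4Vectors::queryHits(o))] <- TRUE
  }
  base <- ifelse(in_island, config$island_mean, config$open_mean)
  M <- matrix(rep(base, n_s), ncol = n_s,
              dimnames = list(NULL, truth$sample_ids))

  apply_element <- function(M, el, slope) {
    rows <- which(pos >= el$start & pos <= el$end)
    if (length(rows))
      M[rows, ] <- matrix(rep(planted_means(el, slope, truth),
                              each = length(rows)), nrow = length(rows))
    M
  }
  # uncoupled planted DMRs first, then differential enhancers (whole span),
  # then coupled partners, so the contained window reflects its enhancer's
  # per-sample mean and partners keep their own coupling sign
  dmr <- truth$dmr_windows
  for (i in which(dmr$role == "solo"))
    M <- apply_element(M, dmr[i, ], 0)
  a <- config$coupling_strengths[1]
  for (i in which(truth$enhancers$differential))
    M <- apply_element(M, cbind(truth$enhancers[i, ], sign = 1L), a)
  b <- config$coupling_strengths[2]
  for (i in which(dmr$role == "partner"))
    M <- apply_element(M, dmr[i, ], b)
  M <- clamp(M, config$mean_clamp)

  n <- length(M)
  coverage <- matrix(pmax(1L, stats::rnbinom(n, size = config$coverage_dispersion,
                                             mu = config$coverage_mean)),
                     ncol = n_s)
  theta <- matrix(stats::rbeta(n, shape1 = M * config$beta_precision,
                               shape2 = (1 - M) * config$beta_precision),
                  ncol = n_s)
  meth <- matrix(stats::rbinom(n, size = coverage, prob = theta), ncol = n_s)

  calls <- lapply(seq_len(n_s), function(j)
    data.frame(chrom = config$chrom, pos = pos, strand = "+",
               n_meth = meth[, j], n_total = coverage[, j],
               stringsAsFactors = FALSE))
  names(calls) <- truth$sample_ids
  sheet <- data.frame(sample_id = truth$sample_ids, group = truth$groups,
                      path = NA_character_, stringsAsFactors = FALSE)
  list(calls = calls, sheet = sheet)
}

#' Simulate the capture-seq validation cohort
#'
#' Emulates an MBD-capture cohort quantified by region rpkm: each sample
#' gets fixed-length (36 bp) read intervals. Reads are placed in the planted
#' truth regions (enhancers and DMR windows) with Poisson counts whose rate
#' is proportional to the region's per-sample methylation level — driven by
#' the same group-plus-latent-factor structure as the bisulfite cohort, with
#' phenotype labels and fresh latent factors drawn for the capture samples —
#' so coupled pairs exhibit correlated rpkm across samples. Background reads
#' are placed uniformly outside the truth regions; a region with zero
#' intensity therefore receives zero overlapping reads.
#'
#' @param truth A [plant_truth()] result.
#' @param config The matching [sim_config()].
#' @param n_samples Capture cohort size (default 24).
#' @param reads_per_sample Target library size (default 1e5; must be >= 1).
#' @param enrich_fraction Fraction of the library allocated to truth regions
#'   (default 0.5).
#' @param read_length Read length in bp (default 36).
#' @param intensity Optional regions-by-samples matrix overriding the
#'   methylation-derived intensities (used for placement-mechanics tests).
#' @return List `reads` (named list of per-sample read interval data
#'   frames), `total_reads` (named vector, the realised library sizes),
#'   `regions` (the truth regions quantified), `phenotype`, `latent`, and
#'   `intensity` (the regions-by-samples matrix used).
#' @export
simulate_capture_cohort <- function(truth, config, n_samples = 24L,
                                    reads_per_sample = 1e5,
                                    enrich_fraction = 0.5, read_length = 36L,
                                    intensity = NULL) {
  stopifnot(inherits(truth, "truth_set"), inherits(config, "sim_config"))
  if (reads_per_sample < 1) stop("reads_per_sample must be >= 1")
  set.seed(config$seed + 2L)
  n_samples <- as.integer(n_samples)
  regions <- rbind(
    data.frame(chrom = truth$enhancers$chrom, start = truth$enhancers$start,
               end = truth$enhancers$end, name = truth$enhancers$name,
               stringsAsFactors = FALSE),
    data.frame(chrom = truth$dmr_windows$chrom, start = truth$dmr_windows$start,
               end = truth$dmr_windows$end, name = truth$dmr_windows$name,
               stringsAsFactors = FALSE))
  sample_ids <- sprintf("cap_s%02d", seq_len(n_samples))
  phenotype <- rep(c("group1", "group2"), length.out = n_samples)
  latent <- matrix(stats::rnorm(n_samples * max(1L, config$n_diff_enhancers)),
                   nrow = n_samples, dimnames = list(sample_ids, NULL))

  if (is.null(intensity)) {
    cap_truth <- truth
    cap_truth$groups <- phenotype
    cap_truth$latent_factors <- latent
    meanrow <- function(el, slope) planted_means(el, slope, cap_truth)
    rows <- list()
    for (i in seq_len(nrow(truth$enhancers))) {
      e <- truth$enhancers[i, ]
      rows[[length(rows) + 1L]] <-
        if (e$differential) meanrow(cbind(e, sign = 1L),
                                    config$coupling_strengths[1])
        else rep(0.5, n_samples)  # catalog enhancers without planted effects
    }
    for (i in seq_len(nrow(truth$dmr_windows))) {
      d <- truth$dmr_windows[i, ]
      slope <- if (d$role == "partner") config$coupling_strengths[2] else 0
      rows[[length(rows) + 1L]] <- meanrow(d, slope)
    }
    intensity <- do.call(rbind, rows)
    dimnames(intensity) <- list(region_id(regions), sample_ids)
  }
  stopifnot(nrow(intensity) == nrow(regions), ncol(intensity) == n_samples)

  # fixed normaliser (expected weight at methylation 0.5) keeps the expected
  # read count exactly linear in a region's intensity
  lens <- interval_length(regions)
  norm <- sum(0.5 * lens)
  occupied <- as_granges(regions)
  chrom_max <- config$chrom_length - read_length + 1L

  reads <- list(); totals <- integer(n_samples)
  for (j in seq_len(n_samples)) {
    lambda <- reads_per_sample * enrich_fraction * intensity[, j] * lens / norm
    cnt <- stats::rpois(length(lambda), lambda)
    starts <- integer(0)
    for (i in which(cnt > 0)) {
      lo <- regions$start[i]
      hiS <- max(lo, regions$end[i] - read_length + 1L)
      starts <- c(starts, lo + sample.int(hiS - lo + 1L, cnt[i],
                                          replace = TRUE) - 1L)
    }
    n_bg <- stats::rpois(1, reads_per_sample * (1 - enrich_fraction))
    bg <- integer(0)
    while (length(bg) < n_bg) {
      cand <- sample.int(chrom_max, n_bg - length(bg), replace = TRUE)
      gr <- GenomicRanges::GRanges(config$chrom,
                                   IRanges::IRanges(cand, width = read_length))
      keep <- GenomicRanges::countOverlaps(gr, occupied) == 0
      bg <- c(bg, cand[keep])
    }
    starts <- sort(c(starts, bg))
    reads[[j]] <- data.frame(chrom = config$chrom, start = starts,
                             end = starts + read_length - 1L,
                             stringsAsFactors = FALSE)
    totals[j] <- length(starts)
  }
  names(reads) <- sample_ids
  names(totals) <- sample_ids
  list(reads = reads, total_reads = totals, regions = regions,
       phenotype = phenotype, latent = latent, intensity = intensity)
}
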