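# End-to-end orchestration: DMR calling -> enhancer containment -> region
# methylation -> DME selection -> correlation screen -> annotation ->
# capture validation, under a single configuration with a run report.
# Execution is single-process and deterministic: identical config and inputs
# give identical outputs (and byte-identical files when out_dir is set).

#' Pipeline configuration
#'
#' Collects every threshold and method switch, with defaults reproducing the
#' study's printed settings: 1000-bp windows, methylation difference > 50
#' percentage points with q < 0.01 for DMRs, t-test alpha 0.05 for DMEs,
#' |r| >= 0.85 with BH q <= 0.05 for the screen, and a 1500-bp promoter.
#'
#' @param window DMR window width in bp.
#' @param diff DMR effect-size cutoff in percentage points.
#' @param q_dmr DMR q-value cutoff.
#' @param alpha_dme DME t-test alpha.
#' @param r_min Screen threshold on |r|.
#' @param q_corr Screen threshold on the BH-adjusted p.
#' @param promoter_bp Promoter length upstream of the TSS.
#' @param min_coverage Per-CpG coverage filter at read time.
#' @param min_cpgs Minimum CpGs per (region, sample) methylation value.
#' @param qmethod DMR q-value method (`"slim"` or `"bh"`).
#' @param ttest DME t-test variant (`"welch"` or `"student"`).
#' @param fdr_family Screen FDR family (`"per_enhancer"` or `"pooled"`).
#' @param tss_anchor Reported TSS-distance anchor.
#' @param seed Integer seed recorded with the run.
#' @param paths Optional named list of input paths (`sample_sheet`,
#'   `enhancers`, `gene_models`, ...), carried for file-driven runs.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(window = 1000L, diff = 50, q_dmr = 0.01,
                            alpha_dme = 0.05, r_min = 0.85, q_corr = 0.05,
                            promoter_bp = 1500L, min_coverage = 10L,
                            min_cpgs = 3L, qmethod = "slim", ttest = "welch",
                            fdr_family = "per_enhancer",
                            tss_anchor = "nearest_edge", seed = 1L,
                            paths = list()) {
  cfg <- list(window = as.integer(window), diff = diff, q_dmr = q_dmr,
              alpha_dme = alpha_dme, r_min = r_min, q_corr = q_corr,
              promoter_bp = as.integer(promoter_bp),
              min_coverage = as.integer(min_coverage),
              min_cpgs = as.integer(min_cpgs), qmethod = qmethod,
              ttest = ttest, fdr_family = fdr_family,
              tss_anchor = tss_anchor, seed = as.integer(seed),
              paths = paths)
  stopifnot(cfg$window >= 1, cfg$diff >= 0, cfg$diff <= 100,
            cfg$q_dmr >= 0, cfg$q_dmr <= 1, cfg$alpha_dme >= 0,
            cfg$alpha_dme <= 1, cfg$r_min >= 0, cfg$r_min <= 1,
            cfg$q_corr >= 0, cfg$q_corr <= 1, cfg$promoter_bp >= 1,
            cfg$min_coverage >= 1, cfg$min_cpgs >= 1,
            cfg$qmethod %in% c("slim", "bh"),
            cfg$ttest %in% c("welch", "student"),
            cfg$fdr_family %in% c("per_enhancer", "pooled"),
            cfg$tss_anchor %in% c("nearest_edge", "region_start", "region_end"))
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration file
#'
#' YAML round-trip: `read_pipeline_config(write_pipeline_config(cfg, path))`
#' reproduces the configuration losslessly.
#'
#' @param config A [pipeline_config()] object.
#' @param path File path.
#' @return The path (write) or the configuration (read).
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(pipeline_config, x)
}

#' Semantic hash of a pipeline configuration
#'
#' MD5 of the canonical (key-sorted) YAML text; changes iff any semantic
#' field changes.
#'
#' @param config A [pipeline_config()] object.
#' @return Character MD5 digest.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x <- x[order(names(x))]
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Run the enhancer-gene methylation-coupling pipeline
#'
#' Stages, in order: DMR calling on tiling windows; containment overlap of
#' passing DMRs with the enhancer catalog; region methylation for candidate
#' enhancers and passing DMRs; DME selection by t-test; the intrachromosomal
#' correlation screen; gene annotation of screen partners (when gene models
#' are given); capture-cohort validation (when capture inputs are given).
#' Later stages receive earlier stages' outputs; empty intermediate results
#' propagate as empty outputs, not errors.
#'
#' @param cohort Named list of per-sample CpG call data frames.
#' @param sheet Sample sheet (`sample_id, group`); first group label is
#'   "group1" for effect signs.
#' @param enhancers Enhancer catalog interval data frame.
#' @param genes Optional gene model table for the annotation stage.
#' @param capture Optional list `reads` (named list of read interval data
#'   frames) and optionally `total_reads`, for the validation stage.
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional directory; when set, every stage output is
#'   written as a TSV (deterministic bytes for identical inputs/config).
#' @param chrom_lengths Optional named chromosome lengths for tiling.
#' @return Object of class `"meth_coupling"`: stage outputs (`dmrs`,
#'   `containment`, `meth_matrix`, `dmes`, `screen`, `annotation`,
#'   `validation`), the `config`, its `config_hash`, and a `report` of
#'   per-stage counts.
#' @export
run_pipeline <- function(cohort, sheet, enhancers, genes = NULL,
                         capture = NULL, config = pipeline_config(),
                         out_dir = NULL, chrom_lengths = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  dmrs <- stage("call-dmrs", call_dmrs(
    cohort, sheet, window = config$window, diff_cutoff = config$diff,
    q_cutoff = config$q_dmr, qmethod = config$qmethod,
    chrom_lengths = chrom_lengths))

  containment <- stage("overlap", dmrs_in_enhancers(dmrs, enhancers))

  cand_enh <- unique(containment[, c("enhancer_chrom", "enhancer_start",
                                     "enhancer_end", "enhancer_name")])
  names(cand_enh) <- c("chrom", "start", "end", "name")
  passing <- dmrs[dmrs$passes, c("chrom", "start", "end"), drop = FALSE]
  regions <- unique(rbind(cand_enh[, c("chrom", "start", "end")], passing))
  mmatrix <- stage("region-meth", {
    if (nrow(regions) > 0)
      region_meth_matrix(regions, cohort, min_cpgs = config$min_cpgs)
    else matrix(NA_real_, 0, length(cohort),
                dimnames = list(NULL, names(cohort)))
  })

  dmes <- stage("select-dmes", select_dmes(
    containment, mmatrix, sheet, alpha = config$alpha_dme,
    variant = config$ttest))

  screen <- stage("screen", screen_pairs(
    dmes, dmrs, mmatrix, r_min = config$r_min, q_max = config$q_corr,
    fdr_family = config$fdr_family))

  annotation <- NULL
  if (!is.null(genes) && nrow(screen) > 0) {
    partners <- unique(data.frame(chrom = screen$partner_chrom,
                                  start = screen$partner_start,
                                  end = screen$partner_end,
                                  stringsAsFactors = FALSE))
    annotation <- stage("annotate", annotate_regions(
      partners, genes, promoter_bp = config$promoter_bp,
      tss_anchor = config$tss_anchor))
  }

  validation <- NULL
  if (!is.null(capture) && nrow(screen) > 0) {
    pass_pairs <- screen[screen$passes, , drop = FALSE]
    if (nrow(pass_pairs) > 0) {
      vregions <- unique(rbind(
        data.frame(chrom = pass_pairs$enhancer_chrom,
                   start = pass_pairs$enhancer_start,
                   end = pass_pairs$enhancer_end, stringsAsFactors = FALSE),
        data.frame(chrom = pass_pairs$partner_chrom,
                   start = pass_pairs$partner_start,
                   end = pass_pairs$partner_end, stringsAsFactors = FALSE)))
      rpkm <- stage("validate", capture_profiles(
        capture$reads, vregions, total_reads = capture$total_reads))
      validation <- stage("validate", validate_pairs(pass_pairs, rpkm))
    }
  }

  report <- list(
    samples = nrow(sheet),
    windows_tested = nrow(dmrs),
    windows_skipped = attr(dmrs, "skipped"),
    dmrs_passing = sum(dmrs$passes),
    enhancers_in_catalog = nrow(enhancers),
    enhancers_with_contained_dmrs = nrow(cand_enh),
    dmes_selected = sum(dmes$selected),
    pairs_screened = nrow(screen),
    pairs_passing = if (nrow(screen)) sum(screen$passes) else 0L,
    pairs_validated = if (is.null(validation)) 0L else nrow(validation),
    elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))

  obj <- structure(list(config = config, config_hash = config_hash(config),
                        dmrs = dmrs, containment = containment,
                        meth_matrix = mmatrix, dmes = dmes, screen = screen,
                        annotation = annotation, validation = validation,
                        report = report),
                   class = "meth_coupling")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_records(dmrs, file.path(out_dir, "dmrs.tsv"))
    write_records(containment, file.path(out_dir, "containment.tsv"))
    if (nrow(mmatrix) > 0) {
      mm <- data.frame(region = rownames(mmatrix), mmatrix, check.names = FALSE)
      write_records(mm, file.path(out_dir, "region_methylation.tsv"))
    }
    write_records(dmes, file.path(out_dir, "dmes.tsv"))
    write_records(screen, file.path(out_dir, "screen.tsv"))
    if (!is.null(annotation))
      write_records(annotation, file.path(out_dir, "annotation.tsv"))
    if (!is.null(validation))
      write_records(validation, file.path(out_dir, "validation.tsv"))
  }
  obj
}

#' @export
print.meth_coupling <- function(x, ...) {
  r <- x$report
  cat("Enhancer-gene methylation coupling run\n")
  cat(sprintf("  samples: %d   config: %s\n", r$samples,
              substr(x$config_hash, 1, 8)))
  cat(sprintf("  windows tested: %d (skipped %d)\n", r$windows_tested,
              r$windows_skipped))
  cat(sprintf("  DMRs passing |diff|>%g%%, q<%g: %d\n", x$config$diff,
              x$config$q_dmr, r$dmrs_passing))
  cat(sprintf("  enhancers with contained DMRs: %d of %d\n",
              r$enhancers_with_contained_dmrs, r$enhancers_in_catalog))
  cat(sprintf("  DMEs selected (p<%g): %d\n", x$config$alpha_dme,
              r$dmes_selected))
  cat(sprintf("  pairs screened: %d, passing |r|>=%g, q<=%g: %d\n",
              r$pairs_screened, x$config$r_min, x$config$q_corr,
              r$pairs_passing))
  if (r$pairs_validated > 0)
    cat(sprintf("  pairs validated in capture cohort: %d\n",
                r$pairs_validated))
  invisible(x)
}

#' @export
summary.meth_coupling <- function(object, n = 10L, ...) {
  print(object)
  scr <- object$screen
  if (nrow(scr) > 0) {
    cat("\nTop screened pairs (by q, then |r|):\n")
    cols <- c("enhancer_name", "partner_chrom", "partner_start", "partner_end",
              "n", "r", "p_value", "q_value", "strength", "passes")
    print(utils::head(scr[, cols], n), row.names = FALSE, digits = 3)
  }
  if (!is.null(object$validation) && nrow(object$validation) > 0) {
    cat("\nCapture-cohort validation:\n")
    cols <- c("enhancer_name", "partner_start", "partner_end", "r",
              "val_n", "val_r", "val_p_value", "val_strength")
    print(utils::head(object$validation[, cols], n), row.names = FALSE,
          digits = 3)
  }
  invisible(object)
}

#' Diagnostic plots for a pipeline run
#'
#' `which = "volcano"` shows window -log10 p against methylation difference
#' with the pass region delimited; `which = "pair"` shows the per-sample
#' methylation scatter of the i-th screened pair.
#'
#' @param x A `meth_coupling` object.
#' @param which `"volcano"` or `"pair"`.
#' @param i Pair row for `which = "pair"`.
#' @param ... Passed to the underlying plot call.
#' @export
plot.meth_coupling <- function(x, which = c("volcano", "pair"), i = 1L, ...) {
  which <- match.arg(which)
  if (which == "volcano") {
    d <- x$dmrs
    graphics::plot(d$meth_diff, -log10(pmax(d$p_value, 1e-300)),
                   xlab = "methylation difference (group1 - group2, %)",
                   ylab = "-log10 p", pch = 20,
                   col = ifelse(d$passes, "firebrick", "grey60"), ...)
    graphics::abline(v = c(-x$config$diff, x$config$diff), lty = 2)
  } else {
    stopifnot(nrow(x$screen) >= i)
    p <- x$screen[i, ]
    eid <- sprintf("%s:%d-%d", p$enhancer_chrom, p$enhancer_start, p$enhancer_end)
    did <- sprintf("%s:%d-%d", p$partner_chrom, p$partner_start, p$partner_end)
    graphics::plot(x$meth_matrix[eid, ], x$meth_matrix[did, ],
                   xlab = paste("enhancer", eid), ylab = paste("partner", did),
                   pch = 19, ...)
    graphics::abline(stats::lm(x$meth_matrix[did, ] ~ x$meth_matrix[eid, ]),
                     lty = 3)
  }
  invisible(x)
}
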