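# Windowed DMR detection: 1000-bp tiling windows, per-sample aggregated
# counts, a binomial logistic-regression test of group on the methylated
# proportion, multiple-testing correction, and the effect-size/q-value filter
# (|difference| > 50 percentage points, q < 0.01).

#' Aggregate CpG counts over a window
#'
#' Per-sample sums of methylated and total counts over the CpGs inside the
#' window (inclusive bounds). Samples with no CpGs in the window get (0, 0);
#' disjoint windows therefore partition the per-sample totals.
#'
#' @param window One-row interval data frame.
#' @param cohort Named list of per-sample CpG call data frames.
#' @return Data frame `sample_id, n_meth, n_total`, one row per sample.
#' @export
aggregate_window_counts <- function(window, cohort) {
  validate_intervals(window, "window")
  stopifnot(nrow(window) == 1L)
  res <- t(vapply(cohort, function(calls) {
    inside <- calls$chrom == window$chrom &
      calls$pos >= window$start & calls$pos <= window$end
    c(sum(calls$n_meth[inside]), sum(calls$n_total[inside]))
  }, numeric(2)))
  data.frame(sample_id = names(cohort),
             n_meth = as.integer(res[, 1]), n_total = as.integer(res[, 2]),
             stringsAsFactors = FALSE)
}

#' Binomial logistic-regression window test
#'
#' Fits a binomial GLM (logit link) of the methylated proportion on a group
#' indicator, one observation per sample weighted by its total coverage, and
#' tests the group term with the likelihood-ratio chi-square statistic (1 df)
#' against the intercept-only model. With one pooled observation per group
#' the statistic equals the two-proportion G-statistic on the 2x2 table.
#'
#' The methylation difference is reported on the pooled scale:
#' `100 * (sum(n_meth)/sum(n_total) in group1 - same in group2)`.
#'
#' @param n_meth,n_total Integer vectors of per-sample counts.
#' @param groups Vector of group labels (exactly two levels); "group1" is the
#'   first factor level, or the first label in order of appearance for a
#'   character vector.
#' @return List with `meth_diff` (percent, group1 - group2), `p_value`, and
#'   `estimable` (`FALSE` when a group has zero total coverage, in which case
#'   the window is untestable and both statistics are `NA`).
#' @export
test_window <- function(n_meth, n_total, groups) {
  stopifnot(length(n_meth) == length(n_total), length(groups) == length(n_meth))
  lev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  g <- factor(as.character(groups), levels = lev)
  keep <- n_total > 0
  tot1 <- sum(n_total[keep & g == lev[1]])
  tot2 <- sum(n_total[keep & g == lev[2]])
  if (tot1 == 0 || tot2 == 0)
    return(list(meth_diff = NA_real_, p_value = NA_real_, estimable = FALSE))
  meth_diff <- 100 * (sum(n_meth[keep & g == lev[1]]) / tot1 -
                      sum(n_meth[keep & g == lev[2]]) / tot2)
  m <- n_meth[keep]; t <- n_total[keep]; gg <- droplevels(g[keep])
  fit <- suppressWarnings(
    stats::glm(cbind(m, t - m) ~ gg, family = stats::binomial()))
  lrt <- max(0, fit$null.deviance - fit$deviance)
  p <- stats::pchisq(lrt, df = 1L, lower.tail = FALSE)
  list(meth_diff = meth_diff, p_value = p, estimable = TRUE)
}

#' Estimate the null proportion pi0 from a p-value vector
#'
#' Lambda-grid estimator in the SLIM spirit: for each lambda in 0.1..0.9,
#' `pi0(lambda) = mean(p > lambda) / (1 - lambda)`; the reported estimate is
#' taken at the flattest segment of the pi0(lambda) curve (smallest absolute
#' finite-difference slope, right endpoint), clamped to (0, 1].
#'
#' @param p P-values in `[0, 1]`.
#' @return Scalar pi0 estimate in (0, 1].
#' @export
estimate_pi0 <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p <- p[!is.na(p)]
  if (length(p) < 20) return(1)
  lambda <- seq(0.1, 0.9, by = 0.1)
  pi0l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1))
  slope <- abs(diff(pi0l) / diff(lambda))
  i <- which.min(slope)
  min(max(pi0l[i + 1L], 1e-3), 1)
}

#' FDR-adjust p-values
#'
#' `method = "bh"` is the Benjamini-Hochberg step-up (monotone by
#' construction). `method = "slim"` (alias `"slim_pi0"`) multiplies the BH
#' q-values by the estimated null proportion pi0 (see [estimate_pi0()]),
#' clipped to `[0, 1]` — the package's stand-in for the sliding-linear-model
#' q-value method, which shares the pi0-rescaled-BH structure.
#'
#' @param p P-values in `[0, 1]`.
#' @param method `"bh"`, `"slim"` or `"slim_pi0"`.
#' @return Q-values; for the slim method the pi0 estimate is attached as
#'   attribute `"pi0"`.
#' @export
adjust_qvalues <- function(p, method = c("slim", "bh", "slim_pi0")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "bh") return(q)
  pi0 <- estimate_pi0(p)
  q <- pmin(pmax(q * pi0, 0), 1)
  attr(q, "pi0") <- pi0
  q
}

#' Call differentially methylated windows between two groups
#'
#' Tiles each chromosome into fixed windows, aggregates per-sample counts,
#' runs the logistic-regression window test, adjusts p-values, and flags
#' windows passing the effect-size and q-value filters. Both passing and
#' non-passing tested windows are returned; windows with zero total coverage
#' in either group are skipped (counted in attribute `"skipped"`), not
#' assigned p = 1.
#'
#' @param cohort Named list of per-sample CpG call data frames.
#' @param sheet Sample sheet (`sample_id, group`); the first group label in
#'   sheet order is "group1" (e.g. CIMP) for the sign of `meth_diff`.
#' @param window Window width in bp (default 1000).
#' @param diff_cutoff Pass requires `|meth_diff| > diff_cutoff` percent
#'   (default 50).
#' @param q_cutoff Pass requires `q_value < q_cutoff` (default 0.01).
#' @param qmethod Q-value method, `"slim"` (default) or `"bh"`.
#' @param chrom_lengths Optional named vector of chromosome lengths; defaults
#'   to the maximum observed CpG position per chromosome.
#' @return Data frame `chrom, start, end, meth_diff, p_value, q_value,
#'   passes`, sorted by (chrom, start). Attributes: `"counts"` (list of
#'   per-window sample count matrices `n_meth`, `n_total`), `"skipped"`
#'   (number of untestable windows with coverage), `"pi0"` when applicable.
#' @export
call_dmrs <- function(cohort, sheet, window = 1000L, diff_cutoff = 50,
                      q_cutoff = 0.01, qmethod = c("slim", "bh"),
                      chrom_lengths = NULL) {
  qmethod <- match.arg(qmethod)
  if (length(cohort) == 0 || all(vapply(cohort, nrow, 0L) == 0))
    stop("empty cohort")
  stopifnot(all(sheet$sample_id %in% names(cohort)))
  groups <- sheet$group
  lev <- unique(as.character(groups))
  if (length(lev) != 2 || any(table(groups) < 1))
    stop("sample sheet must define two non-empty groups")
  samples <- sheet$sample_id
  cohort <- cohort[samples]

  chroms <- sort(unique(unlist(lapply(cohort, function(x) unique(x$chrom)))))
  res <- list(); skipped <- 0L
  meth_rows <- list(); total_rows <- list()
  for (ch in chroms) {
    len <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths))
      chrom_lengths[[ch]]
    else max(vapply(cohort, function(x) {
      p <- x$pos[x$chrom == ch]
      if (length(p)) max(p) else 0L
    }, numeric(1)))
    if (len < 1) next
    # window index per CpG; rowsum gives the aggregated count matrices
    nm <- matrix(0, 0, length(samples)); nt <- matrix(0, 0, length(samples))
    widx_all <- sort(unique(unlist(lapply(cohort, function(x)
      unique((x$pos[x$chrom == ch] - 1L) %/% window)))))
    if (length(widx_all) == 0) next
    nm <- matrix(0, length(widx_all), length(samples),
                 dimnames = list(widx_all, samples))
    nt <- nm
    for (s in samples) {
      x <- cohort[[s]]
      sel <- x$chrom == ch
      if (!any(sel)) next
      wi <- (x$pos[sel] - 1L) %/% window
      sm <- rowsum(cbind(x$n_meth[sel], x$n_total[sel]), wi)
      nm[rownames(sm), s] <- sm[, 1]
      nt[rownames(sm), s] <- sm[, 2]
    }
    for (k in seq_along(widx_all)) {
      w <- widx_all[k]
      tw <- test_window(nm[k, ], nt[k, ], groups)
      if (!tw$estimable) { skipped <- skipped + 1L; next }
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start = w * window + 1L,
        end = min((w + 1L) * window, len),
        meth_diff = tw$meth_diff, p_value = tw$p_value,
        stringsAsFactors = FALSE)
      meth_rows[[length(res)]] <- nm[k, ]
      total_rows[[length(res)]] <- nt[k, ]
    }
  }
  if (length(res) == 0) stop("no testable windows in cohort")
  out <- do.call(rbind, res)
  q <- adjust_qvalues(out$p_value, method = qmethod)
  out$q_value <- as.numeric(q)
  out$passes <- abs(out$meth_diff) > diff_cutoff & out$q_value < q_cutoff
  ord <- order(out$chrom, out$start, method = "radix")
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "counts") <- list(
    n_meth = do.call(rbind, meth_rows)[ord, , drop = FALSE],
    n_total = do.call(rbind, total_rows)[ord, , drop = FALSE])
  attr(out, "skipped") <- skipped
  if (!is.null(attr(q, "pi0"))) attr(out, "pi0") <- attr(q, "pi0")
  out
}
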