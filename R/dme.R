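# Differentially methylated enhancer (DME) selection: a two-tailed
# two-sample t-test on per-sample enhancer methylation, at raw p < 0.05 over
# the candidate enhancers (no multiple-testing correction at this stage; the
# screen mirrors the small-candidate-set selection it reproduces).

#' Two-tailed two-sample t-test on per-sample fractions
#'
#' Welch (Satterthwaite df, default) or Student (pooled variance) variant.
#' Degenerate contract: when both groups have zero variance, equal means give
#' p = 1 (t = 0) by convention and unequal means give p = 0 (infinite t).
#'
#' @param values Numeric vector of per-sample fractions (NAs allowed).
#' @param groups Group labels aligned with `values` (two levels; "group1" is
#'   the first factor level, or the first label in order of appearance).
#' @param variant `"welch"` or `"student"`.
#' @return List `t_statistic`, `p_value`, `df`, `mean1`, `mean2`, `estimable`
#'   (`FALSE` with fewer than two non-missing values in either group).
#' @export
ttest_two_group <- function(values, groups, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  lev <- if (is.factor(groups)) levels(groups) else unique(as.character(groups))
  if (length(lev) != 2) stop("exactly two groups required")
  x <- values[groups == lev[1]]; x <- x[!is.na(x)]
  y <- values[groups == lev[2]]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(t_statistic = NA_real_, p_value = NA_real_, df = NA_real_,
                mean1 = mean(x), mean2 = mean(y), estimable = FALSE))
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t_statistic = if (eq) 0 else sign(mean(x) - mean(y)) * Inf,
                p_value = if (eq) 1 else 0, df = NA_real_,
                mean1 = mean(x), mean2 = mean(y), estimable = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = (variant == "student"),
                      alternative = "two.sided")
  list(t_statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), mean1 = mean(x), mean2 = mean(y),
       estimable = TRUE)
}

#' Select differentially methylated enhancers
#'
#' One record per candidate enhancer (an enhancer with at least one contained
#' passing DMR); selected iff the two-tailed t-test on its per-sample region
#' methylation gives p < `alpha` and both group value vectors are complete.
#'
#' @param pairs Containment pairs from [dmrs_in_enhancers()].
#' @param mmatrix Region-by-sample methylation matrix covering every
#'   candidate enhancer (rows keyed by [region_id()]).
#' @param sheet Sample sheet (`sample_id, group`).
#' @param alpha Selection threshold on the raw p-value (default 0.05).
#' @param variant T-test variant, `"welch"` (default) or `"student"`.
#' @return Data frame `chrom, start, end, name, mean_group1, mean_group2,
#'   t_statistic, p_value, direction, selected`, one row per candidate
#'   enhancer.
#' @export
select_dmes <- function(pairs, mmatrix, sheet, alpha = 0.05,
                        variant = c("welch", "student")) {
  variant <- match.arg(variant)
  cols <- c("enhancer_chrom", "enhancer_start", "enhancer_end", "enhancer_name")
  stopifnot(all(cols %in% names(pairs)))
  enh <- unique(pairs[, cols])
  names(enh) <- c("chrom", "start", "end", "name")
  out <- enh[order(enh$chrom, enh$start, enh$end, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  n <- nrow(out)
  out$mean_group1 <- out$mean_group2 <- out$t_statistic <- out$p_value <-
    rep(NA_real_, n)
  out$direction <- rep(NA_character_, n)
  out$selected <- rep(FALSE, n)
  if (n == 0) return(out)
  ids <- region_id(out)
  missing <- setdiff(ids, rownames(mmatrix))
  if (length(missing))
    stop("enhancer(s) absent from methylation matrix: ",
         paste(missing, collapse = ", "))
  stopifnot(all(sheet$sample_id %in% colnames(mmatrix)))
  groups <- sheet$group[match(colnames(mmatrix)[colnames(mmatrix) %in% sheet$sample_id],
                              sheet$sample_id)]
  use <- colnames(mmatrix) %in% sheet$sample_id
  for (i in seq_len(n)) {
    vals <- mmatrix[ids[i], use]
    tt <- ttest_two_group(vals, groups, variant = variant)
    out$mean_group1[i] <- tt$mean1
    out$mean_group2[i] <- tt$mean2
    out$t_statistic[i] <- tt$t_statistic
    out$p_value[i] <- tt$p_value
    out$direction[i] <- if (!is.na(tt$mean1) && !is.na(tt$mean2) &&
                            tt$mean1 >= tt$mean2) "hyper_in_group1"
                        else "hyper_in_group2"
    complete <- !anyNA(vals)
    out$selected[i] <- isTRUE(tt$estimable) && !is.na(tt$p_value) &&
      tt$p_value < alpha && complete
  }
  out
}
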