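# Intrachromosomal correlation screen: each selected enhancer is paired with
# every passing DMR on its chromosome (excluding DMRs contained in the
# enhancer itself), Pearson r and a two-tailed p are computed across samples,
# and p-values are BH-adjusted within each enhancer's candidate family. The
# pass rule is |r| >= 0.85 with q <= 0.05 (the stated band "-0.85 >= r >=
# 0.85" read as a two-sided magnitude threshold).

#' Pearson product-moment correlation
#'
#' Pairwise-complete sample correlation. Undefined-correlation inputs (fewer
#' than 3 complete pairs, or zero variance in either vector) return `NA` with
#' the reason in attribute `"reason"` rather than an error, so screening
#' loops can skip and log them.
#'
#' @param x,y Equal-length numeric vectors.
#' @return Scalar r in `[-1, 1]`, or `NA`. Attribute `"n"` carries the number
#'   of complete pairs used.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(structure(NA_real_, n = n, reason = "n < 3"))
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    return(structure(NA_real_, n = n, reason = "zero variance"))
  structure(stats::cor(x, y), n = n)
}

#' Two-tailed p-value for a Pearson correlation
#'
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` referred to the t distribution with
#' `n - 2` degrees of freedom; `|r| = 1` gives p = 0.
#'
#' @param r Correlation coefficient in `[-1, 1]`.
#' @param n Number of paired samples (>= 3).
#' @return Two-tailed p-value.
#' @examples
#' pearson_pvalue(0.634, 24)  # ~0.00088
#' @export
pearson_pvalue <- function(r, n) {
  if (any(n < 3)) stop("Pearson p-value requires n >= 3")
  if (any(abs(r) > 1)) stop("r must lie in [-1, 1]")
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t <- r[ok] * sqrt(n - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(t), df = n - 2)
  if (length(r) == 1L) p <- as.numeric(p)
  p
}

#' Correlation-strength label
#'
#' `|r| >= 0.5` is "good to excellent"; below that, "moderate to nil".
#'
#' @param r Correlation coefficient(s) in `[-1, 1]`.
#' @return Character vector of labels.
#' @export
classify_strength <- function(r) {
  stopifnot(all(abs(r) <= 1, na.rm = TRUE))
  ifelse(abs(r) >= 0.5, "good to excellent", "moderate to nil")
}

#' Screen enhancer-DMR pairs for correlated methylation
#'
#' Candidate set: every (selected DME, passing DMR) pair on the same
#' chromosome, excluding DMRs contained in that DME (which would correlate
#' trivially with it). Pearson r and p are computed across pairwise-complete
#' samples; BH adjustment is applied per enhancer across its candidate pairs
#' (`fdr_family = "pooled"` adjusts across all pairs at once). A pair passes
#' iff `|r| >= r_min`, `q <= q_max` and `n >= 3`.
#'
#' @param dmes DME table from [select_dmes()]; only `selected` rows are used.
#' @param dmrs DMR table from [call_dmrs()]; only `passes` rows are used.
#' @param mmatrix Region-by-sample methylation matrix covering all DMEs and
#'   DMRs.
#' @param r_min Magnitude threshold on r (default 0.85).
#' @param q_max Threshold on the BH-adjusted p (default 0.05).
#' @param fdr_family `"per_enhancer"` (default) or `"pooled"`.
#' @return Data frame `enhancer_chrom, enhancer_start, enhancer_end,
#'   enhancer_name, partner_chrom, partner_start, partner_end, n, r, p_value,
#'   q_value, strength, passes`, sorted by q then decreasing `|r|`. Skipped
#'   undefined-correlation pairs are counted in attribute `"skipped"`.
#' @export
screen_pairs <- function(dmes, dmrs, mmatrix, r_min = 0.85, q_max = 0.05,
                         fdr_family = c("per_enhancer", "pooled")) {
  fdr_family <- match.arg(fdr_family)
  sel <- dmes[which(dmes$selected), , drop = FALSE]
  hit <- dmrs[which(dmrs$passes), , drop = FALSE]
  empty <- data.frame(enhancer_chrom = character(), enhancer_start = integer(),
                      enhancer_end = integer(), enhancer_name = character(),
                      partner_chrom = character(), partner_start = integer(),
                      partner_end = integer(), n = integer(), r = numeric(),
                      p_value = numeric(), q_value = numeric(),
                      strength = character(), passes = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(sel) == 0 || nrow(hit) == 0) return(structure(empty, skipped = 0L))
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(sel))) {
    e <- sel[i, ]
    eid <- region_id(e)
    if (!(eid %in% rownames(mmatrix)))
      stop("enhancer absent from methylation matrix: ", eid)
    cand <- hit[hit$chrom == e$chrom &
                  !(e$start <= hit$start & hit$end <= e$end), , drop = FALSE]
    if (nrow(cand) == 0) next
    for (j in seq_len(nrow(cand))) {
      d <- cand[j, ]
      did <- region_id(d)
      if (!(did %in% rownames(mmatrix)))
        stop("DMR absent from methylation matrix: ", did)
      r <- pearson_r(mmatrix[eid, ], mmatrix[did, ])
      n <- attr(r, "n")
      if (is.na(r)) { skipped <- skipped + 1L; next }
      rows[[length(rows) + 1L]] <- data.frame(
        enhancer_chrom = e$chrom, enhancer_start = e$start,
        enhancer_end = e$end,
        enhancer_name = if (is.null(e$name)) NA_character_ else e$name,
        partner_chrom = d$chrom, partner_start = d$start, partner_end = d$end,
        n = n, r = as.numeric(r),
        p_value = pearson_pvalue(as.numeric(r), n),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(structure(empty, skipped = skipped))
  out <- do.call(rbind, rows)
  if (fdr_family == "pooled") {
    out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  } else {
    out$q_value <- NA_real_
    fam <- region_id(data.frame(chrom = out$enhancer_chrom,
                                start = out$enhancer_start,
                                end = out$enhancer_end))
    for (f in unique(fam)) {
      idx <- fam == f
      out$q_value[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
    }
  }
  out$strength <- classify_strength(out$r)
  out$passes <- abs(out$r) >= r_min & out$q_value <= q_max & out$n >= 3
  out <- out[order(out$q_value, -abs(out$r), out$enhancer_start,
                   out$partner_start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
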