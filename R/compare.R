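# Stratified comparison of complexity scores between two sample groups.
#
# Two-sample comparisons of means use Welch t-tests; when either group shows
# strong deviation from normality (Shapiro-Wilk rejecting at alpha = 0.01)
# the Wilcoxon rank-sum test is used instead. P-values are Bonferroni
# corrected over the family of all scores tested in the mode (8 genome-wide,
# 8 x number of arms arm-wise). Scores can first be residualized on
# per-sample covariates (ploidy, aberrant cell fraction) by ordinary least
# squares.

#' Choose the two-sample test for a score
#'
#' Welch t-test unless a Shapiro-Wilk test rejects normality at
#' `shapiro_alpha` in either group (then Wilcoxon rank-sum). Degenerate
#' (near-constant) groups also fall back to Wilcoxon.
#'
#' @param a,b numeric score values of the two groups (each length >= 3).
#' @param shapiro_alpha rejection level for the normality gate (default 0.01).
#' @return "t" or "wilcoxon".
#' @export
select_test <- function(a, b, shapiro_alpha = 0.01) {
  stopifnot(length(a) >= 3, length(b) >= 3)
  non_normal <- function(x) {
    x <- x[is.finite(x)]
    if (length(unique(x)) < 3) return(TRUE)
    if (length(x) > 5000) x <- x[seq_len(5000)]
    stats::shapiro.test(x)$p.value < shapiro_alpha
  }
  if (non_normal(a) || non_normal(b)) "wilcoxon" else "t"
}

#' Residualize score columns on per-sample covariates
#'
#' Replaces each score column by the residuals of an ordinary least-squares
#' fit on the covariates plus intercept, separately within each region, so
#' group comparisons are adjusted for e.g. estimated ploidy and aberrant cell
#' fraction. Residual columns have mean 0 by construction.
#'
#' @param scores long score data.frame from [score_cohort()] (`sample`,
#'   `region`, score columns).
#' @param covariates data.frame with a `sample` column plus numeric covariate
#'   columns. Samples with missing covariates are dropped with a message;
#'   constant covariates are dropped with a warning.
#' @return scores data.frame with the same shape, score columns residualized.
#' @export
adjust_scores <- function(scores, covariates) {
  stopifnot("sample" %in% names(covariates))
  cov_cols <- setdiff(names(covariates), "sample")
  if (!length(cov_cols)) stop("no covariate columns supplied")
  keep <- cov_cols[vapply(cov_cols, function(cl) {
    v <- covariates[[cl]]
    ok <- stats::var(v, na.rm = TRUE) > 0 && !all(is.na(v))
    if (!ok) warning("dropping constant covariate: ", cl)
    ok
  }, TRUE)]
  if (!length(keep)) stop("all covariates are constant")
  cov <- covariates[, c("sample", keep), drop = FALSE]
  complete <- cov$sample[stats::complete.cases(cov[, keep, drop = FALSE])]
  dropped <- setdiff(scores$sample, complete)
  if (length(dropped)) {
    message("excluding ", length(dropped), " sample(s) with missing covariates: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  }
  out <- scores[scores$sample %in% complete, , drop = FALSE]
  idx <- match(out$sample, cov$sample)
  score_cols <- intersect(SCORE_NAMES, names(out))
  X <- as.matrix(cov[idx, keep, drop = FALSE])
  for (reg in unique(out$region)) {
    rows <- which(out$region == reg)
    for (sc in score_cols) {
      y <- out[[sc]][rows]
      ok <- is.finite(y)
      if (sum(ok) < length(keep) + 2) next
      fit <- stats::lm.fit(cbind(1, X[rows[ok], , drop = FALSE]), y[ok])
      out[[sc]][rows[ok]] <- fit$residuals
    }
  }
  rownames(out) <- NULL
  out
}

#' Compare complexity scores between two groups
#'
#' One test per (region, index) score. The Bonferroni family is every score
#' tested in the mode: m = 8 for genome-wide, m = 8 x number of regions
#' arm-wise. Samples with an NA/"unknown" group label are dropped; exactly
#' two groups must remain.
#'
#' @param scores long score data.frame (`sample`, `region`, score columns),
#'   optionally pre-adjusted with [adjust_scores()].
#' @param groups named character vector mapping sample -> group label.
#' @param alpha family-wise significance level (default 0.05).
#' @param shapiro_alpha normality-gate level for [select_test()].
#' @param min_group minimum group size per test (default 3); smaller
#'   comparisons are skipped with a warning.
#' @return data.frame with one row per (region, index): group labels/sizes,
#'   test used, means, direction (label of the higher-mean group), raw and
#'   Bonferroni-adjusted P, family size m, -log10 raw P, significance flag.
#' @export
compare_groups <- function(scores, groups, alpha = 0.05, shapiro_alpha = 0.01,
                           min_group = 3) {
  g <- groups[scores$sample]
  keep <- !is.na(g) & g != "unknown"
  scores <- scores[keep, , drop = FALSE]
  g <- g[keep]
  labs <- sort(unique(g))
  if (length(labs) != 2) {
    stop("need exactly two groups after dropping unknowns, got: ",
         paste(labs, collapse = ", "))
  }
  if (!any(g == labs[1]) || !any(g == labs[2])) stop("one group is empty")
  score_cols <- intersect(SCORE_NAMES, names(scores))
  regions <- unique(scores$region)
  m <- length(score_cols) * length(regions)
  rows <- list()
  for (reg in regions) {
    in_reg <- scores$region == reg
    for (sc in score_cols) {
      a <- scores[[sc]][in_reg & g == labs[1]]
      b <- scores[[sc]][in_reg & g == labs[2]]
      a <- a[is.finite(a)]
      b <- b[is.finite(b)]
      if (length(a) < min_group || length(b) < min_group) {
        warning("skipping ", reg, "/", sc, ": group smaller than ", min_group)
        next
      }
      test <- select_test(a, b, shapiro_alpha)
      p <- if (test == "t") {
        stats::t.test(a, b)$p.value
      } else {
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region = reg, index = sc,
        group_a = labs[1], group_b = labs[2],
        n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b),
        direction = if (mean(a) >= mean(b)) labs[1] else labs[2],
        test = test, p = p,
        p_bonferroni = min(1, m * p),
        m = m,
        neg_log10_p = -log10(p),
        significant = min(1, m * p) < alpha,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no comparable scores")
  rownames(out) <- NULL
  out
}
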