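# Multiple-comparison corrections and difference-score testing, matching
# the reporting conventions used throughout the analysis suite.

#' Bonferroni correction with an explicit test count
#'
#' The original p-value multiplied by the number of tests performed,
#' capped at 1. The count is supplied explicitly because a family may be
#' larger than the vector of p-values at hand.
#'
#' @param p_raw Raw p-value(s) in [0, 1].
#' @param n_tests Number of tests in the family (>= 1).
#' @return Adjusted p-value(s).
#' @export
bonferroni <- function(p_raw, n_tests) {
  if (n_tests < 1) stop("n_tests must be >= 1")
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  pmin(1, p_raw * n_tests)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjustment used for larger families (more than
#' five comparisons). Delegates to `stats::p.adjust(method = "BH")`.
#'
#' @param p_raw Vector of raw p-values in [0, 1] (non-empty).
#' @return Adjusted p-values, monotone in rank and capped at 1.
#' @export
benjamini_hochberg <- function(p_raw) {
  if (length(p_raw) == 0L) stop("empty p-value list")
  stopifnot(all(p_raw >= 0 & p_raw <= 1))
  stats::p.adjust(p_raw, method = "BH")
}

#' One-sample t-test of difference scores against zero
#'
#' Two-sided one-sample t-test (n - 1 degrees of freedom) of normalized
#' difference scores against a zero null.
#'
#' @param scores Numeric vector of scores (>= 2, non-degenerate).
#' @return A list: `t`, `p`, `df`, `mean`.
#' @export
diff_score_ttest <- function(scores) {
  if (length(scores) < 2L) stop("need at least 2 scores")
  if (stats::sd(scores) == 0) stop("zero variance: t undefined")
  ht <- stats::t.test(scores, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean = unname(ht$estimate))
}
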