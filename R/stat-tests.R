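# Two-group comparisons used in the descriptive analysis.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Counts enter row-wise: the table is `rbind(c(a, b), c(c, d))`. No
#' continuity correction is applied; the counts this test is used on are in
#' the thousands, where the correction is immaterial.
#'
#' @param a,b,c,d Nonnegative cell counts.
#' @return List with `statistic` (1 df Pearson chi-square) and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || anyNA(cells)) {
    stop_validation("cell counts must be nonnegative")
  }
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_degenerate("degenerate 2x2 table: a margin is zero")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value), df = 1L)
}

#' Two-sided Mann-Whitney rank-sum test
#'
#' Exact p-value by enumeration when the combined sample size is at most 12
#' and there are no ties; otherwise a normal approximation without continuity
#' correction, using midranks with the tie-corrected variance. When every
#' value in both groups is identical the comparison is vacuous: the p-value
#' is 1 by convention and the result is flagged.
#'
#' @param x,y Numeric vectors (e.g. per-center 2020/2019 ratios in two zones).
#' @param method `"auto"` (branch on size/ties), or force `"exact"` /
#'   `"normal"`.
#' @return List with `statistic` (the U statistic for `x`), `p_value`,
#'   `method` used, and logical flags `ties` and `degenerate`.
#' @export
rank_sum_test <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (length(x) == 0 || length(y) == 0) {
    stop_validation("both groups must be nonempty")
  }
  combined <- c(x, y)
  ties <- anyDuplicated(combined) > 0
  if (length(unique(combined)) == 1L) {
    rlang::warn("all values identical across both groups; p = 1 by convention")
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                method = "degenerate", ties = TRUE, degenerate = TRUE))
  }
  if (method == "auto") {
    method <- if (length(combined) <= 12 && !ties) "exact" else "normal"
  }
  ht <- if (method == "exact") {
    if (ties) stop_validation("exact branch requires untied data")
    stats::wilcox.test(x, y, exact = TRUE)
  } else {
    suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  }
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       method = method, ties = ties, degenerate = FALSE)
}
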