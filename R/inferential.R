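#' Pearson chi-square test of independence
#'
#' Cross-sample fracture-frequency comparisons use the Pearson chi-square
#' statistic on contingency tables of counts, two-sided, without Yates
#' continuity correction (the correction convention that reproduces the
#' published sample contrasts). Expected counts are
#' `row_total * col_total / grand_total`.
#'
#' @param counts Non-negative integer matrix with at least 2 rows and
#'   2 columns; every row and column margin must be positive.
#' @return An object of class `"htest"` with `statistic` (X-squared),
#'   `parameter` (df = (r-1)(c-1)), `p.value`, `observed` and `expected`.
#' @export
#' @examples
#' chi_square_independence(rbind(c(29, 48), c(53, 30)))
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) == 0 || any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("every row and column margin must be positive", call. = FALSE)
  }
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(
    statistic = res$statistic,
    parameter = res$parameter,
    p.value = res$p.value,
    method = "Pearson chi-square test of independence (no continuity correction)",
    data.name = deparse(substitute(counts)),
    observed = res$observed,
    expected = res$expected
  ), class = "htest")
}

#' Two-proportion z-test (pooled, two-sided)
#'
#' Compares two binomial proportions `k1/n1` and `k2/n2` with the pooled
#' standard-error z statistic; on a 2x2 table `z^2` equals the Pearson
#' chi-square statistic without continuity correction. Used for the
#' kill-site element-removal comparison between chronological periods.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return An object of class `"htest"` with `statistic` (z, signed as
#'   group 1 minus group 2), `p.value` and `estimate` (the two proportions).
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  ok <- function(k, n) length(k) == 1 && length(n) == 1 && !is.na(k) &&
    !is.na(n) && n > 0 && k >= 0 && k <= n
  if (!ok(k1, n1) || !ok(k2, n2)) {
    stop("need 0 <= k <= n and n > 0 in both groups", call. = FALSE)
  }
  p1 <- k1 / n1
  p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (se == 0) 0 else (p1 - p2) / se
  structure(list(
    statistic = c(z = z),
    p.value = 2 * stats::pnorm(-abs(z)),
    estimate = c(prop1 = p1, prop2 = p2),
    method = "two-proportion z-test (pooled, two-sided)",
    data.name = sprintf("%d/%d vs %d/%d", k1, n1, k2, n2)
  ), class = "htest")
}

#' Format a p-value in reporting style
#'
#' Three decimals; values below 0.001 are printed as `"<0.001"`.
#'
#' @param p Numeric p-value(s) in \[0, 1\].
#' @return Character vector.
#' @export
#' @examples
#' format_p(c(0.000927, 2e-5))  # "0.001" "<0.001"
format_p <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(round_half_up(p, 3) < 0.001, "<0.001",
         sprintf("%.3f", round_half_up(p, 3)))
}
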