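# Pooled-variance two-sample t machinery for comparing architectures'
# per-image (or per-fold) accuracies.

#' Two-tailed Student-t critical value
#'
#' Quantile of the t distribution at `1 - (1 - confidence)/2`. At 99%
#' confidence and 5 degrees of freedom this is 4.032 (3 decimals).
#'
#' @param confidence confidence level in (0, 1).
#' @param df degrees of freedom, >= 1.
#' @return the critical value \eqn{t_c}; the null hypothesis of equal
#'   means is rejected when \eqn{t \ge t_c} or \eqn{t \le -t_c}.
#' @examples
#' tCritical(0.99, 5)   # 4.032
#' tCritical(0.95, 152) # 1.976
#' @export
tCritical <- function(confidence, df) {
  if (!(confidence > 0 && confidence < 1))
    stop("confidence must lie in (0, 1)")
  if (!isCount(df) || df < 1) stop("df must be an integer >= 1")
  stats::qt(1 - (1 - confidence) / 2, df)
}

#' Pooled-variance two-sample t test
#'
#' Student's two-sample t statistic with pooled variance and
#' `df = n1 + n2 - 2`, decided two-tailed against [tCritical()] at the
#' requested confidence. With zero pooled variance the statistic is 0
#' for equal means and a flagged infinite value otherwise.
#'
#' @param a,b numeric samples, each of size >= 2.
#' @param confidence confidence level for the significance decision.
#' @return a [TTestResult-class]; `direction` reports whether `a`'s mean
#'   is significantly `"higher"` or `"lower"` than `b`'s.
#' @export
twoSampleT <- function(a, b, confidence = 0.95) {
  n1 <- length(a); n2 <- length(b)
  if (n1 < 2L || n2 < 2L) stop("each sample needs at least 2 observations")
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / df
  dm <- mean(a) - mean(b)
  tval <- if (sp2 > 0) dm / sqrt(sp2 * (1 / n1 + 1 / n2))
          else if (dm == 0) 0 else sign(dm) * Inf
  tc <- tCritical(confidence, df)
  sig <- abs(tval) >= tc
  new("TTestResult", statistic = tval, df = as.integer(df),
      confidence = confidence, tCritical = tc, significant = sig,
      direction = if (!sig) "none" else if (tval > 0) "higher" else "lower")
}

#' Compare two models' per-item metrics
#'
#' Applies the pooled-variance two-sample t test to two collections of
#' per-image (validation comparison) or per-fold (cross-validation
#' comparison) metric values and reports which model, if either, is
#' significantly higher.
#'
#' @param metricA,metricB numeric metric collections of equal length.
#' @param confidence confidence level.
#' @return a [TTestResult-class]; `direction = "higher"` means model A.
#' @export
compareModels <- function(metricA, metricB, confidence = 0.95) {
  if (length(metricA) != length(metricB))
    stop("the two metric collections must have the same length")
  twoSampleT(metricA, metricB, confidence)
}
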