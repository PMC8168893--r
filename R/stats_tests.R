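# Elementary statistics for cohort characteristics tables.

#' Two-year longitudinal change
#'
#' `followup - baseline`; a decline is negative. Missing values propagate.
#'
#' @param baseline,followup numeric (vectorised).
#' @return followup minus baseline.
#' @export
longitudinal_change <- function(baseline, followup) {
  followup - baseline
}

#' Standardized uptake value ratio
#'
#' Mean tracer uptake in cortical gray matter divided by mean uptake in the
#' composite reference region. Invariant to common rescaling of the two
#' inputs.
#'
#' @param mean_uptake_gm mean gray-matter uptake.
#' @param mean_uptake_reference mean reference-region uptake (> 0).
#' @return the ratio.
#' @export
compute_suvr <- function(mean_uptake_gm, mean_uptake_reference) {
  if (any(!is.finite(mean_uptake_reference)) ||
      any(mean_uptake_reference <= 0))
    stop_invalid("reference uptake must be positive")
  mean_uptake_gm / mean_uptake_reference
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Student's t with a pooled variance estimate and `df = n1 + n2 - 2`,
#' computed directly from group means, SDs and sizes (as printed in cohort
#' characteristics tables).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (!is_count(n1) || !is_count(n2) || n1 < 2 || n2 < 2)
    stop_invalid("both group sizes must be integers >= 2")
  if (sd1 < 0 || sd2 < 0) stop_invalid("SDs must be nonnegative")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: the sum of the
#' probabilities of all tables (with the observed margins) whose probability
#' does not exceed that of the observed table.
#'
#' @param a,b,c,d cell counts, row-wise: `rbind(c(a, b), c(c, d))`.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(x < 0) || any(x != round(x)))
    stop_invalid("cell counts must be nonnegative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop_invalid("each margin needs at least one positive count")
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, c1, c2, r1)
  p_obs <- stats::dhyper(a, c1, c2, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
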