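# Benchmark combiners: Fisher, Simes, Sidak minimum-P.

#' Fisher's combined P-value
#'
#' `T = -2 sum(log P_i)` referred to the chi-square distribution with 2L
#' degrees of freedom.
#'
#' @inheritParams truncation_product
#' @return A [combined_result()] with `statistic = T`.
#' @examples
#' fisher_pvalue(c(0.1, 0.2))
#' @export
fisher_pvalue <- function(pvals) {
  ps <- pvalue_set(pvals)
  stat <- -2 * sum(log(ps$values))
  combined_result("fisher", pchisq(stat, df = 2 * ps$L, lower.tail = FALSE),
                  k = ps$L, statistic = stat)
}

#' Simes combined P-value
#'
#' `min_i { L * P_(i) / i }`, capped at 1. Rejecting when this is below
#' `alpha` is the Simes global test (algebraically the Benjamini-Hochberg
#' step-up applied to the global null).
#'
#' @inheritParams truncation_product
#' @return A [combined_result()].
#' @examples
#' simes_pvalue(c(0.01, 0.04, 0.3, 0.5))
#' @export
simes_pvalue <- function(pvals) {
  ps <- pvalue_set(pvals)
  stat <- min(ps$L * ps$sorted / seq_len(ps$L))
  combined_result("simes", min(stat, 1), statistic = stat)
}

#' Sidak minimum-P combined P-value
#'
#' `1 - (1 - P_(1))^L`, the exact null CDF of the smallest of L
#' independent uniform P-values. Identical to [rtp_pvalue()] at `k = 1`.
#'
#' @inheritParams truncation_product
#' @return A [combined_result()].
#' @export
sidak_minp_pvalue <- function(pvals) {
  ps <- pvalue_set(pvals)
  p1 <- ps$sorted[1L]
  combined_result("sidak", -expm1(ps$L * log1p(-p1)), k = 1L, statistic = p1)
}

# batch Simes over a row-sorted matrix of P-values
.simes_batch <- function(psort) {
  L <- ncol(psort)
  out <- psort[, 1L] * L
  for (i in 2:L) out <- pmin(out, L * psort[, i] / i)
  pmin(out, 1)
}
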