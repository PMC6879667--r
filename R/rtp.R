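# Rank truncated product distribution.
#
# For k < L the combined P-value is the marginal CDF of the product of the
# k smallest of L uniform P-values, obtained by conditioning on the (k+1)-th
# order statistic p ~ Beta(k+1, L-k): given p the k smallest are iid
# uniforms on (0, p), so their product is p^k times a product of k iid
# uniforms, and
#
#   Pr(W_k <= w) = F_B(p0) + int_{p0}^1 f_B(p) * Gbar_k(k log p + t) dp,
#
# with t = -log w, p0 = exp(-t/k), f_B the Beta(k+1, L-k) density and
# Gbar_k the Gamma(k, 1) survival function. The integrand is positive, so
# the form is cancellation-free in both tails; the region where the gamma
# argument would be negative (the conditional event is impossible) is
# excluded by starting the integral at p0. Fixed-order Gauss-Legendre on
# (p0, 1) is used; the integrand is smooth there for k >= 2 and the node
# count is validated against adaptive quadrature in the test suite
# (absolute tolerance 1e-9). k = 1 has the exact closed form 1-(1-w)^L
# (the integrand then has a near-pole just outside the interval that
# defeats fixed-order rules). k = L is the Fisher case: chi-square with
# 2L df at 2t.

.gl_nodes <- function(n = 256L) {
  key <- paste0("gl", n)
  if (is.null(.art_cache[[key]]))
    .art_cache[[key]] <- pracma::gaussLegendre(n, 0, 1)
  .art_cache[[key]]
}

# Vectorised over neg_log_w. `expo` is the power of the beta quantile in
# the integrand: expo = k gives Pr(W_k <= w), expo = k + 1 gives
# Pr(W_{k+1} <= w) from the same conditioning (shape stays k).
.rtp_cdf_batch <- function(neg_log_w, k, L, expo = k, n_nodes = 256L) {
  t <- as.numeric(neg_log_w)
  if (any(!is.finite(t))) stop("non-finite -log(w)")
  out <- numeric(length(t))
  pos <- t > 0
  out[!pos] <- 1  # w >= 1: the product is certainly <= w
  if (!any(pos)) return(out)
  t <- t[pos]
  if (expo == L) {
    out[pos] <- pchisq(2 * t, df = 2 * L, lower.tail = FALSE)
    return(out)
  }
  if (expo > L) stop("beta exponent exceeds L")
  if (k == 1L && expo == 1L) {
    out[pos] <- -expm1(L * log1p(-exp(-t)))
    return(out)
  }
  gl <- .gl_nodes(n_nodes)
  p0 <- exp(-t / expo)
  acc <- pbeta(p0, k + 1, L - k)
  scale <- 1 - p0
  for (j in seq_along(gl$x)) {
    p <- p0 + scale * gl$x[j]
    acc <- acc + (gl$w[j] * scale) * dbeta(p, k + 1, L - k) *
      pgamma(expo * log(p) + t, shape = k, lower.tail = FALSE)
  }
  out[pos] <- pmin(acc, 1)
  out
}

#' RTP combined P-value
#'
#' Evaluates the null cumulative distribution of the rank truncated
#' product -- the product of the k smallest of L independent uniform
#' P-values -- at the observed product, via a single bounded integral.
#' At `k = 1` this equals the Sidak minimum-P correction `1 - (1 - P_(1))^L`
#' and at `k = L` the Fisher combined P-value (chi-square with 2L df).
#'
#' @param x a [pvalue_set()], numeric vector of P-values, or a
#'   [truncation_product()] (in which case `L` is taken from it).
#' @param k truncation point; ignored when `x` is a truncation product.
#' @param n_nodes Gauss-Legendre order for the integral.
#' @return A [combined_result()] with `statistic = -log(W_k)`.
#' @examples
#' rtp_pvalue(c(0.001, 0.04, 0.3, 0.7), k = 2)
#' @seealso [art_pvalue()] for the integration-free alternative,
#'   [rtp_pvalue_legacy()] for the closed-form cross-check.
#' @export
rtp_pvalue <- function(x, k = NULL, n_nodes = 256L) {
  tp <- if (inherits(x, "truncation_product")) x else truncation_product(x, k)
  p <- .rtp_cdf_batch(tp$neg_log_w, tp$k, tp$L, n_nodes = n_nodes)
  combined_result("rtp", p, k = tp$k, statistic = tp$neg_log_w)
}

#' RTP combined P-value at the next truncation point
#'
#' Given the product of the k+1 smallest P-values, evaluates
#' `Pr(W_{k+1} <= w)` re-using the conditioning on the (k+1)-th order
#' statistic, i.e. the same integral as [rtp_pvalue()] with the beta
#' quantile raised to the power k+1. Both truncation points can therefore
#' be assessed from one pass over the sorted P-values.
#'
#' @param tp a [truncation_product()] whose `neg_log_w` is interpreted as a
#'   realisation of `-log(W_{k+1})`; its `k` slot is the conditioning k.
#' @param L number of tests; defaults to the value stored in `tp`.
#' @inheritParams rtp_pvalue
#' @return A [combined_result()] with `k = tp$k + 1`.
#' @export
rtp_pvalue_next <- function(tp, L = tp$L, n_nodes = 256L) {
  stopifnot(inherits(tp, "truncation_product"))
  if (tp$k + 1L > L) stop("need k + 1 <= L")
  p <- .rtp_cdf_batch(tp$neg_log_w, tp$k, L, expo = tp$k + 1L, n_nodes = n_nodes)
  combined_result("rtp", p, k = tp$k + 1L, statistic = tp$neg_log_w)
}

#' Legacy closed-form RTP distribution (cross-check)
#'
#' Order-statistic closed form of `Pr(W_k <= w)` for `k < L`: a finite sum
#' of alternating-sign binomial terms, each multiplying a bounded
#' one-dimensional integral, plus the beta boundary mass. Retained as an
#' independent numerical cross-check of [rtp_pvalue()]; the alternating
#' coefficients grow combinatorially with `L - k`, so the evaluation loses
#' accuracy for large problems and should not be used as the production
#' path (it warns beyond `L > 25`).
#'
#' @inheritParams rtp_pvalue_next
#' @param tp a [truncation_product()].
#' @return A [combined_result()].
#' @export
rtp_pvalue_legacy <- function(tp, L = tp$L) {
  stopifnot(inherits(tp, "truncation_product"))
  k <- tp$k
  if (k >= L) stop("legacy closed form requires k < L")
  if (L > 25)
    warning("alternating coefficients are unstable for L > 25; ",
            "prefer rtp_pvalue()")
  t <- tp$neg_log_w
  if (t <= 0) return(combined_result("rtp_legacy", 1, k = k, statistic = t))
  p0 <- exp(-t / k)
  # log of the Beta(k+1, L-k) normalising constant times the p^k p^-k cancel
  lC <- lgamma(L + 1) - lgamma(k + 1) - lgamma(L - k)
  gl <- .gl_nodes(64L)
  inv_fact <- 1 / factorial(0:(k - 1))
  acc <- 0
  for (m in 0:(L - k - 1)) {
    a <- (m + 1) / k
    # J_s = int_0^t x^s e^{a(x-t)} dx = int_0^{min(t, 45/a)} (t-u)^s e^{-a u} du,
    # positive integrand, evaluated by fixed-order quadrature (the forward
    # recurrence in s is unstable for s > a)
    hi <- min(t, 45 / a)
    u <- hi * gl$x
    e <- gl$w * hi * exp(-a * u)
    tmu <- t - u
    J_over_fact <- 0
    pow <- rep(1, length(u))
    for (s in 0:(k - 1)) {
      J_over_fact <- J_over_fact + sum(e * pow) * inv_fact[s + 1]
      pow <- pow * tmu
    }
    acc <- acc + choose(L - k - 1, m) * (-1)^m * J_over_fact
  }
  p <- pbeta(p0, k + 1, L - k) + exp(lC - t) * acc / k
  p <- min(max(p, 0), 1)
  combined_result("rtp_legacy", p, k = k, statistic = t)
}
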