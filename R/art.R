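# Augmented rank truncation (ART).
#
# Condition on the k-th order statistic P_(k): the k-1 smaller P-values are
# iid uniform on (0, P_(k)), so
#
#   Gamma_k := -log W_{k-1} + (k-1) log P_(k) = sum_{i<k} -log(P_(i)/P_(k))
#
# is Gamma(k-1, 1) and independent of P_(k). P_(k) itself is
# Beta(k, L-k+1); its survival probability mapped through the Gamma(lambda)
# quantile gives a third independent gamma variable, with the shape lambda
# chosen so that this term has the same expectation as -(k-1) log P_(k).
# The sum A_k is then exactly Gamma(k-1+lambda, 1) under the global null --
# no integration is needed for the combined P-value.

#' Gamma shape weight of the ART statistic
#'
#' `lambda = (k - 1) * (digamma(L + 1) - digamma(k))`, i.e. `(k-1)` times
#' the null expectation of `-log P_(k)`. Equals
#' `(k-1) * sum(1 / (k:L))`.
#'
#' @param k truncation point.
#' @param L number of tests.
#' @return The shape weight (0 when `k = 1`).
#' @examples
#' art_shape_lambda(2, 2)  # 1/2
#' @export
art_shape_lambda <- function(k, L) {
  if (any(k < 1) || any(k > L)) stop("need 1 <= k <= L")
  (k - 1) * (digamma(L + 1) - digamma(k))
}

#' ART statistic and its components
#'
#' Computes `A_k = -log(W_{k-1}) + (k-1) log(P_(k)) +
#' Ginv_lambda(1 - B_k(P_(k)))`, where `W_{k-1}` is the product of the
#' `k-1` smallest P-values, `B_k` the Beta(k, L-k+1) CDF and `Ginv_lambda`
#' the Gamma(lambda, 1) quantile function. The survival probability
#' `1 - B_k` is evaluated directly on the lower beta tail (no
#' cancellation for small `P_(k)`).
#'
#' @inheritParams truncation_product
#' @param k truncation point, `2 <= k <= L` (for `k = 1` see
#'   [art_pvalue()], which reduces to the Sidak minimum-P form).
#' @return An object of class `"art_components"`: list with
#'   `neg_log_prod_km1`, `p_k`, `lam`, `beta_cdf_at_pk`, `a_k`, `k`, `L`.
#' @examples
#' art_statistic(c(0.1, 0.2), k = 2)
#' @export
art_statistic <- function(pvals, k) {
  ps <- pvalue_set(pvals)
  k <- .check_k(k, ps$L, min_k = 2L)
  sorted <- ps$sorted
  nlw <- -sum(log(sorted[seq_len(k - 1L)]))
  pk <- sorted[k]
  lam <- art_shape_lambda(k, ps$L)
  bcdf <- pbeta(pk, k, ps$L - k + 1)
  a_k <- nlw + (k - 1) * log(pk) +
    qgamma(bcdf, shape = lam, lower.tail = FALSE)
  structure(
    list(neg_log_prod_km1 = nlw, p_k = pk, lam = lam,
         beta_cdf_at_pk = bcdf, a_k = a_k, k = k, L = ps$L),
    class = "art_components"
  )
}

#' @export
print.art_components <- function(x, ...) {
  cat(sprintf("ART components (k = %d, L = %d): a_k = %.6g, lambda = %.6g\n",
              x$k, x$L, x$a_k, x$lam))
  invisible(x)
}

#' ART combined P-value
#'
#' The upper tail of the exact Gamma(k-1+lambda, 1) null law of the ART
#' statistic at the observed value. For `k = 1` the statistic degenerates
#' (`lambda = 0`) and the method reduces to the Sidak minimum-P combined
#' P-value `1 - (1 - P_(1))^L`, which is returned with a note.
#'
#' @param x a [pvalue_set()], numeric vector of P-values, or an
#'   `"art_components"` object from [art_statistic()].
#' @param k truncation point; ignored when `x` is `"art_components"`.
#' @return A [combined_result()] carrying `lambda` and the statistic `a_k`.
#' @examples
#' art_pvalue(c(0.001, 0.04, 0.3, 0.7), k = 2)
#' @export
art_pvalue <- function(x, k = NULL) {
  if (!inherits(x, "art_components")) {
    ps <- pvalue_set(x)
    k <- .check_k(k, ps$L)
    if (k == 1L) {
      res <- sidak_minp_pvalue(ps)
      return(combined_result("art", res$p_combined, k = 1L,
                             statistic = res$statistic, lambda = 0,
                             notes = "k = 1 reduces to the Sidak minimum-P form"))
    }
    x <- art_statistic(ps, k)
  }
  p <- pgamma(x$a_k, shape = x$k - 1 + x$lam, lower.tail = FALSE)
  combined_result("art", p, k = x$k, statistic = x$a_k, lambda = x$lam)
}

# batch over rows: nlw = -rowSums(log of k-1 smallest), pk = k-th smallest
.art_pvalue_batch <- function(nlw, pk, k, L) {
  if (k == 1L) return(-expm1(L * log1p(-pk)))
  lam <- art_shape_lambda(k, L)
  a <- nlw + (k - 1) * log(pk) +
    qgamma(pbeta(pk, k, L - k + 1), shape = lam, lower.tail = FALSE)
  pgamma(a, shape = k - 1 + lam, lower.tail = FALSE)
}
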