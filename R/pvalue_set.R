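#' Validated set of P-values
#'
#' Wraps a numeric vector of P-values for use by the combining functions.
#' Values must lie in \[0, 1\]; values of exactly 0 or 1 are clamped into
#' the open interval (to `1e-300` and `1 - 1e-16` respectively) so that
#' log-space arithmetic stays finite, with a warning reporting how many
#' entries were affected.
#'
#' @param values numeric vector of P-values, length >= 1.
#' @param clamp logical; clamp boundary values instead of failing.
#'
#' @return An object of class `"pvalue_set"`: a list with elements
#'   `values` (in input order, after clamping), `sorted` (nondecreasing),
#'   `L` (number of tests) and `n_clamped`.
#' @examples
#' ps <- pvalue_set(c(0.02, 0.8, 0.4))
#' ps$L
#' ps$sorted
#' @export
pvalue_set <- function(values, clamp = TRUE) {
  if (inherits(values, "pvalue_set")) return(values)
  if (!is.numeric(values) || length(values) < 1L)
    stop("'values' must be a numeric vector of length >= 1")
  if (anyNA(values) || any(!is.finite(values)))
    stop("P-values must be finite and non-missing")
  if (any(values < 0) || any(values > 1))
    stop("P-values must lie in [0, 1]; offending indices: ",
         paste(utils::head(which(values < 0 | values > 1), 5L), collapse = ", "))
  lo <- 1e-300
  hi <- 1 - 1e-16
  n_clamped <- sum(values < lo | values > hi)
  if (n_clamped > 0) {
    if (!clamp)
      stop("P-values of exactly 0 or 1 present and clamp = FALSE")
    warning(sprintf("%d P-value(s) at the boundary clamped into (0, 1)", n_clamped))
    values <- pmin(pmax(values, lo), hi)
  }
  structure(
    list(values = as.numeric(values),
         sorted = sort.int(as.numeric(values), method = "radix"),
         L = length(values),
         n_clamped = n_clamped),
    class = "pvalue_set"
  )
}

#' @export
print.pvalue_set <- function(x, ...) {
  cat(sprintf("P-value set: L = %d tests, min = %.4g, median = %.4g\n",
              x$L, x$sorted[1L], stats::median(x$values)))
  invisible(x)
}

#' Product of the k smallest P-values
#'
#' The rank truncated product statistic W_k. The product is accumulated as
#' a sum of logs, so very small P-values do not underflow.
#'
#' @param pvals a [pvalue_set()] or numeric vector of P-values.
#' @param k integer truncation point, `1 <= k <= L`.
#'
#' @return An object of class `"truncation_product"`: list with `k`, `L`,
#'   `w` (the product, may underflow to 0 for display purposes only) and
#'   `neg_log_w` (`-log(w)`, the quantity used internally).
#' @examples
#' truncation_product(c(0.0007, 0.0941, 0.3), k = 2)$w
#' @export
truncation_product <- function(pvals, k) {
  ps <- pvalue_set(pvals)
  k <- .check_k(k, ps$L)
  neg_log_w <- -sum(log(ps$sorted[seq_len(k)]))
  structure(
    list(k = k, L = ps$L, w = exp(-neg_log_w), neg_log_w = neg_log_w),
    class = "truncation_product"
  )
}

#' @export
print.truncation_product <- function(x, ...) {
  cat(sprintf("Truncation product: k = %d of L = %d, -log(w) = %.6g\n",
              x$k, x$L, x$neg_log_w))
  invisible(x)
}

.check_k <- function(k, L, min_k = 1L) {
  if (length(k) != 1L || !is.finite(k) || k != round(k))
    stop("'k' must be a single integer")
  k <- as.integer(k)
  if (k < min_k || k > L)
    stop(sprintf("'k' must satisfy %d <= k <= L = %d (got %d)", min_k, L, k))
  k
}

#' Result of a combined P-value test
#'
#' Container returned by all combining functions.
#'
#' @param method character label of the method.
#' @param p_combined the combined P-value.
#' @param k truncation point used, or `NA` when not applicable.
#' @param statistic test statistic value, or `NA`.
#' @param ... further named fields stored alongside (e.g. `lambda`).
#' @return An object of class `"combined_result"`.
#' @export
combined_result <- function(method, p_combined, k = NA_integer_,
                            statistic = NA_real_, ...) {
  stopifnot(is.character(method), length(method) == 1L)
  if (!is.na(p_combined) && (p_combined < 0 || p_combined > 1))
    stop("combined P-value outside [0, 1]")
  structure(
    c(list(method = method, k = k, statistic = statistic,
           p_combined = p_combined), list(...)),
    class = "combined_result"
  )
}

#' @export
print.combined_result <- function(x, ...) {
  ktxt <- if (is.na(x$k)) "" else sprintf(" (k = %d)", x$k)
  cat(sprintf("%s combined P-value%s: %.6g\n", x$method, ktxt, x$p_combined))
  if (!is.na(x$statistic))
    cat(sprintf("  statistic = %.6g\n", x$statistic))
  if (!is.null(x$lambda))
    cat(sprintf("  lambda = %.6g\n", x$lambda))
  invisible(x)
}

#' @export
as.data.frame.combined_result <- function(x, ...) {
  data.frame(method = x$method, k = x$k, statistic = x$statistic,
             p_combined = x$p_combined,
             notes = if (is.null(x$notes)) "" else x$notes,
             stringsAsFactors = FALSE)
}
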