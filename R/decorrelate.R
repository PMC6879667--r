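# Decorrelation by orthogonal transformation (DOT).
#
# If the vector y of association statistics is MVN(0, Sigma) under the
# null, then with Sigma = Q Lambda Q^T and H = Q Lambda^{-1/2} Q^T the
# transformed vector y_e = H^T y is MVN(0, I): the transformed P-values
# 1 - Phi(y_e) are iid uniform and any independence-based combiner
# applies. Among all square roots of Sigma^{-1}, this symmetric choice is
# invariant to the ordering of the coordinates in the equicorrelation
# case (a permutation of y yields the same, permuted, y_e).

#' Orthogonal decorrelating transform of a correlation matrix
#'
#' Eigendecomposes `sigma` and forms the symmetric inverse square root
#' `H = Q diag(1/sqrt(lambda)) Q^T`, so that `H^T sigma H = I`.
#'
#' @param sigma symmetric correlation matrix (unit diagonal).
#' @param strict if `TRUE`, eigenvalues below the floor raise an error;
#'   by default they are floored with a warning (near-singular LD
#'   matrices reconstructed from haplotype frequencies are common).
#' @param floor_tol eigenvalues below `floor_tol * max(eigenvalue)` are
#'   floored to that threshold.
#' @return Object of class `"correlation_model"`: list with `sigma`,
#'   `eigvecs`, `eigvals` (after flooring), `transform` (the matrix H),
#'   `n_floored` and `L`.
#' @examples
#' m <- orthogonal_transform(matrix(c(1, .5, .5, 1), 2))
#' zapsmall(t(m$transform) %*% m$sigma %*% m$transform)
#' @export
orthogonal_transform <- function(sigma, strict = FALSE, floor_tol = 1e-10) {
  sigma <- as.matrix(sigma)
  if (nrow(sigma) != ncol(sigma) || !isSymmetric(sigma, tol = 1e-8))
    stop("'sigma' must be a symmetric square matrix")
  if (any(abs(diag(sigma) - 1) > 1e-8))
    stop("'sigma' must have unit diagonal (a correlation matrix)")
  sigma <- (sigma + t(sigma)) / 2
  eg <- eigen(sigma, symmetric = TRUE)
  floor_val <- floor_tol * max(eg$values)
  low <- eg$values < floor_val
  if (any(eg$values < -1e-10 * max(abs(eg$values))) && strict)
    stop("'sigma' has negative eigenvalues")
  if (any(low)) {
    if (strict)
      stop(sprintf("%d eigenvalue(s) below the floor %.3g", sum(low), floor_val))
    warning(sprintf("%d eigenvalue(s) floored at %.3g; H^T sigma H = I holds only approximately",
                    sum(low), floor_val))
    eg$values[low] <- floor_val
  }
  H <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  structure(list(sigma = sigma, eigvecs = eg$vectors, eigvals = eg$values,
                 transform = H, n_floored = sum(low), L = nrow(sigma)),
            class = "correlation_model")
}

#' @export
print.correlation_model <- function(x, ...) {
  cat(sprintf("Decorrelating transform: L = %d, eigenvalues in [%.3g, %.3g]%s\n",
              x$L, min(x$eigvals), max(x$eigvals),
              if (x$n_floored > 0) sprintf(" (%d floored)", x$n_floored) else ""))
  invisible(x)
}

#' Decorrelate P-values through the orthogonal transform
#'
#' Maps each P-value to a normal score `z = qnorm(1 - p)`, applies the
#' decorrelating transform `y_e = H^T z`, and maps back:
#' `p_e = 1 - pnorm(y_e)` (default, one-sided), or the 1-df chi-square
#' survival of `y_e^2` when `two_sided = TRUE`. If the original
#' statistics are truly MVN(0, sigma) under the null, the outputs are
#' iid uniform and any independence-based combiner can be applied to
#' them.
#'
#' @inheritParams truncation_product
#' @param model a `"correlation_model"` from [orthogonal_transform()].
#' @param two_sided square the transformed scores and return two-sided
#'   P-values (use when effects of both signs are of interest).
#' @return A [pvalue_set()] of decorrelated P-values.
#' @examples
#' m <- orthogonal_transform(diag(3))
#' decorrelate_pvalues(c(.1, .5, .9), m)$values
#' @export
decorrelate_pvalues <- function(pvals, model, two_sided = FALSE) {
  ps <- pvalue_set(pvals)
  stopifnot(inherits(model, "correlation_model"))
  if (ps$L != model$L)
    stop(sprintf("length of P-values (%d) != dimension of model (%d)",
                 ps$L, model$L))
  z <- qnorm(ps$values, lower.tail = FALSE)
  ye <- drop(crossprod(model$transform, z))
  pe <- if (two_sided) pchisq(ye^2, df = 1, lower.tail = FALSE)
        else pnorm(ye, lower.tail = FALSE)
  pvalue_set(pe)
}

#' LD correlation matrix from haplotype frequencies
#'
#' For biallelic SNPs, the linkage-disequilibrium coefficient between
#' loci i and j is `D_ij = P_ij - p_i p_j`, the difference between the
#' di-locus haplotype frequency of the two minor alleles and the product
#' of the minor allele frequencies; its correlation-scale version is
#' `r_ij = D_ij / sqrt(p_i (1 - p_i) p_j (1 - p_j))`.
#'
#' @param tab data frame with columns `haplotype` (strings over `{0,1}`
#'   of common length L, `1` marking the minor allele) and `freq`
#'   (nonnegative, summing to 1).
#' @return Symmetric L x L correlation matrix with unit diagonal.
#' @examples
#' tab <- data.frame(haplotype = c("11", "10", "01", "00"),
#'                   freq = c(.4, .1, .1, .4))
#' ld_correlation_from_haplotypes(tab)  # r = 0.6
#' @export
ld_correlation_from_haplotypes <- function(tab) {
  if (!all(c("haplotype", "freq") %in% names(tab)))
    stop("'tab' needs columns 'haplotype' and 'freq'")
  hap <- as.character(tab$haplotype)
  f <- as.numeric(tab$freq)
  if (anyDuplicated(hap)) stop("duplicated haplotypes")
  if (length(unique(nchar(hap))) != 1L) stop("haplotypes differ in length")
  if (any(!grepl("^[01]+$", hap))) stop("haplotypes must be strings over {0,1}")
  if (any(f < 0)) stop("negative haplotype frequency")
  if (abs(sum(f) - 1) > 1e-9) stop("haplotype frequencies must sum to 1")
  L <- nchar(hap[1L])
  M <- matrix(as.integer(unlist(strsplit(hap, ""))), nrow = length(hap),
              ncol = L, byrow = TRUE)
  p <- drop(crossprod(M, f))                   # minor allele frequencies
  mono <- which(p <= 0 | p >= 1)
  if (length(mono) > 0)
    stop("monomorphic SNP at locus/loci ", paste(mono, collapse = ", "))
  P2 <- crossprod(M, f * M)                    # di-locus frequencies
  D <- P2 - tcrossprod(p)
  s <- 1 / sqrt(p * (1 - p))
  r <- D * tcrossprod(s)
  diag(r) <- 1
  r <- pmin(pmax(r, -1), 1)
  (r + t(r)) / 2
}
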