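# Independent oracles used to validate the analytic implementations.
# These deliberately avoid the package's own evaluation paths.

# Pr(product of the k smallest of L uniforms <= w) by brute-force
# Monte-Carlo; returns the estimate and its standard error.
mc_rtp_oracle <- function(k, L, w, B, seed) {
  withr::with_seed(seed, {
    hits <- 0L
    done <- 0L
    while (done < B) {
      n <- min(200000L, B - done)
      u <- matrix(runif(n * L), n, L)
      sm <- t(apply(u, 1L, sort.int))[, seq_len(k), drop = FALSE]
      prod_k <- exp(rowSums(log(sm)))
      hits <- hits + sum(prod_k <= w)
      done <- done + n
    }
    p <- hits / B
    list(p = p, se = sqrt(p * (1 - p) / B))
  })
}

# Pr(W_k <= w) by adaptive quadrature of the conditional representation
# (independent of the fixed-order Gauss-Legendre path in the package).
quad_rtp_oracle <- function(k, L, t, expo = k) {
  if (expo == L) return(pchisq(2 * t, df = 2 * L, lower.tail = FALSE))
  p0 <- exp(-t / expo)
  f <- function(p) dbeta(p, k + 1, L - k) *
    pgamma(expo * log(p) + t, shape = k, lower.tail = FALSE)
  pbeta(p0, k + 1, L - k) +
    integrate(f, p0, 1, rel.tol = 1e-12, subdivisions = 2000L)$value
}

# Two-layer nested Monte-Carlo adaptive RTP oracle: for the observed
# vector, per-k P-values from an outer null sample; the min-P adjusted
# P-value from an inner sample whose per-k P-values use their own
# fresh null sample (no rank-sharing shortcut).
nested_artp_oracle <- function(pvals, ks, B_outer, B_inner, seed) {
  withr::with_seed(seed, {
    L <- length(pvals)
    stat_of <- function(m) {
      sm <- t(apply(m, 1L, sort.int))
      sapply(ks, function(k) rowSums(-log(sm[, seq_len(k), drop = FALSE])))
    }
    null1 <- stat_of(matrix(runif(B_inner * L), B_inner, L))
    obs <- sapply(ks, function(k)
      sum(-log(sort(pvals)[seq_len(k)])))
    perk_obs <- sapply(seq_along(ks), function(j)
      (sum(null1[, j] >= obs[j]) + 1) / (B_inner + 1))
    null2 <- stat_of(matrix(runif(B_outer * L), B_outer, L))
    null3 <- stat_of(matrix(runif(B_inner * L), B_inner, L))
    perk_null <- sapply(seq_along(ks), function(j)
      (colSums(outer(null3[, j], null2[, j], ">=")) + 1) / (B_inner + 1))
    minp_null <- apply(perk_null, 1L, min)
    (sum(minp_null <= min(perk_obs)) + 1) / (B_outer + 1)
  })
}

# harmonic-sum evaluation of the ART shape weight
harmonic_lambda <- function(k, L) (k - 1) * sum(1 / (k:L))
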