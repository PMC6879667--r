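# Simulation harness: data-generating designs, rejection-rate estimation
# and table-scale reproduction with Monte-Carlo standard errors.

#' Simulation design for type-I error and power studies
#'
#' Describes one cell of a simulation study: L test statistics drawn as
#' `z ~ MVN(mu, sigma)` and converted to P-values (two-sided by default),
#' to which a combining method is applied at level `alpha`.
#'
#' Effect models: `"null"` (mu = 0), `"constant"` (all means equal `mu`),
#' `"uniform"` (each mean redrawn per test per replicate from
#' `U(mu_lo, mu_hi)`), `"sparse"` (a fraction `prop` of tests carry mean
#' `mu`, the rest 0; positions redrawn per replicate). Correlation
#' models: `"identity"`, `"equicorrelation"` (parameter `rho`), and
#' `"random_factor"` (one matrix realised from
#' [gen_random_correlation()] at design construction, targeting
#' `mean_abs_rho`).
#'
#' Every replicate has its own RNG stream derived from `(seed,
#' replicate)`, so any single replicate can be regenerated in isolation
#' with [gen_pvalues()].
#'
#' @param L number of tests.
#' @param k truncation point used by fixed-k methods.
#' @param ks candidate set for adaptive methods (default `1:k`).
#' @param B number of replicates.
#' @param effect_model one of `"null"`, `"constant"`, `"uniform"`,
#'   `"sparse"`.
#' @param mu effect size for the constant and sparse models.
#' @param mu_lo,mu_hi range of the uniform effect model.
#' @param prop fraction of true effects in the sparse model.
#' @param sigma_model one of `"identity"`, `"equicorrelation"`,
#'   `"random_factor"`.
#' @param rho equicorrelation coefficient, in `(-1/(L-1), 1)`.
#' @param mean_abs_rho target mean absolute off-diagonal correlation for
#'   the random-factor model.
#' @param two_sided convert statistics to two-sided P-values
#'   `2 * (1 - Phi(|z|))` (default) or one-sided `1 - Phi(z)`.
#' @param seed base seed of the design.
#' @return Object of class `"simulation_design"`.
#' @examples
#' d <- simulation_design(L = 20, k = 5, B = 500, effect_model = "constant",
#'                        mu = 0.5, seed = 1)
#' gen_pvalues(d, replicate = 3)
#' @export
simulation_design <- function(L, k = min(10L, L), ks = NULL, B = 10000L,
                              effect_model = c("null", "constant",
                                               "uniform", "sparse"),
                              mu = 0.5, mu_lo = 0.05, mu_hi = 0.45,
                              prop = 0.05,
                              sigma_model = c("identity", "equicorrelation",
                                              "random_factor"),
                              rho = 0.5, mean_abs_rho = 0.45,
                              two_sided = TRUE, seed = 1L) {
  effect_model <- match.arg(effect_model)
  sigma_model <- match.arg(sigma_model)
  stopifnot(L >= 1, B >= 1, is.finite(mu), prop >= 0, prop <= 1)
  k <- .check_k(k, L)
  if (is.null(ks)) ks <- seq_len(k)
  ks <- .check_ks(ks, L)
  sigma <- switch(sigma_model,
    identity = NULL,
    equicorrelation = {
      if (rho <= -1 / (L - 1) || rho >= 1)
        stop("'rho' must lie in (-1/(L-1), 1)")
      m <- matrix(rho, L, L); diag(m) <- 1; m
    },
    random_factor = gen_random_correlation(L, mean_abs_rho,
                                           seed = .sub_seed(seed, 0L, 7L))
  )
  d <- list(L = L, k = k, ks = ks, B = as.integer(B),
            effect_model = effect_model, mu = mu, mu_lo = mu_lo,
            mu_hi = mu_hi, prop = prop, sigma_model = sigma_model,
            rho = rho, mean_abs_rho = mean_abs_rho,
            two_sided = two_sided, seed = seed, sigma = sigma,
            cache = new.env(parent = emptyenv()))
  class(d) <- "simulation_design"
  d
}

#' @export
print.simulation_design <- function(x, ...) {
  cat(sprintf("Simulation design: L = %d, k = %d, B = %d, effects = %s, sigma = %s, %s P-values, seed = %d\n",
              x$L, x$k, x$B, x$effect_model, x$sigma_model,
              if (x$two_sided) "two-sided" else "one-sided", x$seed))
  invisible(x)
}

.design_chol <- function(design) {
  if (is.null(design$sigma)) return(NULL)
  if (is.null(design$cache$chol))
    design$cache$chol <- chol(design$sigma)
  design$cache$chol
}

# per-replicate mean vector and standard normal draws, from the
# replicate's own stream
.replicate_draw <- function(design, replicate) {
  .with_seed(.sub_seed(design$seed, replicate), {
    g <- rnorm(design$L)   # drawn first: degenerate effect models then
    mu <- switch(design$effect_model,  # reproduce the null stream exactly
      null = 0,
      constant = design$mu,
      uniform = runif(design$L, design$mu_lo, design$mu_hi),
      sparse = design$mu * (runif(design$L) < design$prop))
    list(mu = mu, g = g)
  })
}

.z_to_p <- function(z, two_sided) {
  if (two_sided) 2 * pnorm(-abs(z)) else pnorm(z, lower.tail = FALSE)
}

#' Generate the P-values of one simulation replicate
#'
#' @param design a [simulation_design()].
#' @param replicate replicate index (1-based); each index has its own
#'   deterministic RNG stream.
#' @return A [pvalue_set()] of length `design$L`.
#' @export
gen_pvalues <- function(design, replicate) {
  stopifnot(inherits(design, "simulation_design"))
  d <- .replicate_draw(design, replicate)
  R <- .design_chol(design)
  z <- if (is.null(R)) d$g else drop(d$g %*% R)
  pvalue_set(.z_to_p(z + d$mu, design$two_sided))
}

# B x L matrices of statistics (z) and P-values, rows = replicates;
# cached on the design so several methods can share one batch
.gen_z_matrix <- function(design, B = design$B) {
  key <- paste0("Z", B)
  if (!is.null(design$cache[[key]])) return(design$cache[[key]])
  G <- matrix(NA_real_, B, design$L)
  MU <- matrix(NA_real_, B, design$L)
  for (i in seq_len(B)) {
    d <- .replicate_draw(design, i)
    G[i, ] <- d$g
    MU[i, ] <- d$mu
  }
  R <- .design_chol(design)
  if (!is.null(R)) G <- G %*% R
  design$cache[[key]] <- G + MU
  design$cache[[key]]
}

# row-sorted k smallest P-values of the batch, grown on demand
.design_psort <- function(P, design, B, k, decorr = FALSE) {
  key <- paste0("psort", B, "_", decorr)
  cur <- design$cache[[key]]
  if (!is.null(cur) && ncol(cur) >= k) return(cur[, seq_len(k), drop = FALSE])
  ps <- .row_sort_smallest(P, k)
  design$cache[[key]] <- ps
  ps
}

#' Random correlation matrix with a target mean absolute correlation
#'
#' Factor-model recipe: loadings `W` (`L x m`) with standard normal
#' entries give `S = W W^T + eps I`, rescaled to unit diagonal; `m` is
#' chosen so that the expected mean absolute off-diagonal correlation
#' (approximately `sqrt(2 / (pi m))`) is at least the target, and the
#' matrix is then shrunk towards the identity to match the target
#' exactly. The realised value is returned as attribute
#' `"mean_abs_rho"`.
#'
#' @param L dimension.
#' @param target_mean_abs_rho target mean absolute off-diagonal
#'   correlation, in (0, 1).
#' @param seed integer seed.
#' @param m number of factors (default chosen from the target).
#' @param eps ridge added before rescaling (keeps the matrix PD).
#' @return An `L x L` positive-definite correlation matrix.
#' @examples
#' S <- gen_random_correlation(4, 0.29, seed = 1)
#' mean(abs(S[lower.tri(S)]))
#' @export
gen_random_correlation <- function(L, target_mean_abs_rho, seed = 1L,
                                   m = NULL, eps = 0.05) {
  if (target_mean_abs_rho <= 0 || target_mean_abs_rho >= 1)
    stop("'target_mean_abs_rho' must lie in (0, 1)")
  draw <- function(m) .with_seed(seed, {
    W <- matrix(rnorm(L * m), L, m)
    S <- tcrossprod(W) + diag(eps, L)
    d <- 1 / sqrt(diag(S))
    S * tcrossprod(d)
  })
  # step the factor count down until the realised mean |rho| reaches the
  # target from above, then shrink towards the identity to match exactly
  # (shrinking scales off-diagonals and preserves positive definiteness)
  if (is.null(m)) {
    m <- max(1L, round(2 / (pi * target_mean_abs_rho^2)))
    repeat {
      S <- draw(m)
      if (mean(abs(S[lower.tri(S)])) >= target_mean_abs_rho || m == 1L) break
      m <- m - 1L
    }
  } else {
    S <- draw(m)
  }
  r <- mean(abs(S[lower.tri(S)]))
  if (r > target_mean_abs_rho) {
    S <- (target_mean_abs_rho / r) * S
    diag(S) <- 1
    r <- mean(abs(S[lower.tri(S)]))
  }
  structure(S, mean_abs_rho = r)
}

#' Monte-Carlo rejection rate of a combining method
#'
#' Runs `B` replicates of `design`, applies the requested method to each
#' and returns the fraction of combined P-values at or below `alpha`,
#' with its binomial standard error.
#'
#' Methods: `"rtp"`, `"art"`, `"fisher"`, `"simes"`, `"sidak"` (fixed-k
#' or global combiners applied directly); `"artp"`, `"art_a"` (adaptive
#' over `design$ks`); `"rtp_decorr"`, `"art_decorr"`, `"art_a_decorr"`
#' (statistics decorrelated through the design's known correlation
#' matrix before combining); `"rtp_resampling"`, `"artp_resampling"`
#' (the observed truncated product referred to a null bank of correlated
#' statistics drawn under the design's correlation matrix -- the
#' resampling comparator for dependent data).
#'
#' @param method method label (see Details).
#' @param design a [simulation_design()].
#' @param alpha rejection level(s); may be a vector.
#' @param B number of replicates (defaults to `design$B`).
#' @param ref_B size of internal null reference samples used by the
#'   adaptive and resampling methods.
#' @return Object of class `"rate_estimate"`: list with `rate`, `se`
#'   (binomial), `alpha`, `B`, `method`.
#' @examples
#' d <- simulation_design(L = 20, k = 5, B = 400, seed = 1)
#' estimate_rate("rtp", d, alpha = 0.05)
#' @export
estimate_rate <- function(method, design, alpha = 0.05, B = design$B,
                          ref_B = 50000L) {
  stopifnot(inherits(design, "simulation_design"))
  p <- .combined_pvalues_batch(method, design, B, ref_B)
  rate <- vapply(alpha, function(a) mean(p <= a), numeric(1))
  structure(list(method = method, alpha = alpha, rate = rate,
                 se = sqrt(rate * (1 - rate) / B), B = B,
                 L = design$L, k = design$k),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s: L = %d, k = %d, B = %d\n", x$method, x$L, x$k, x$B))
  for (i in seq_along(x$alpha))
    cat(sprintf("  alpha = %-6g rate = %.4f (se %.4f)\n",
                x$alpha[i], x$rate[i], x$se[i]))
  invisible(x)
}

# combined P-values of all B replicates under `method`
.combined_pvalues_batch <- function(method, design, B = design$B,
                                    ref_B = 50000L) {
  L <- design$L; k <- design$k; ks <- design$ks
  Z <- .gen_z_matrix(design, B)
  decorr <- FALSE
  if (method %in% c("rtp_decorr", "art_decorr", "art_a_decorr")) {
    if (is.null(design$sigma))
      stop("decorrelation methods need a correlated design")
    H <- orthogonal_transform(design$sigma)$transform
    Z <- Z %*% H   # H symmetric: rows become H^T z
    method <- sub("_decorr$", "", method)
    decorr <- TRUE
  }
  P <- .z_to_p(Z, design$two_sided)
  if (method %in% c("rtp_resampling", "artp_resampling")) {
    if (is.null(design$sigma))
      stop("resampling methods need a correlated design")
    return(.resampling_pvalues(method, P, design, ref_B))
  }
  switch(method,
    fisher = pchisq(-2 * rowSums(log(pmax(P, 1e-300))), df = 2 * L,
                    lower.tail = FALSE),
    simes = .simes_batch(.design_psort(P, design, B, L, decorr)),
    sidak = -expm1(L * log1p(-.rowmin(P))),
    rtp = {
      ps <- .design_psort(P, design, B, k, decorr)
      .rtp_cdf_batch(-rowSums(log(ps[, seq_len(k), drop = FALSE])), k, L)
    },
    art = {
      ps <- .design_psort(P, design, B, k, decorr)
      nlw <- if (k == 1L) 0 else -rowSums(log(ps[, seq_len(k - 1L), drop = FALSE]))
      .art_pvalue_batch(nlw, ps[, k], k, L)
    },
    artp = {
      ps <- .design_psort(P, design, B, max(ks), decorr)
      obs <- .cum_neg_log(ps)[, ks, drop = FALSE]
      ref <- .with_seed(.sub_seed(design$seed, 1L, 13L),
                        .cum_neg_log(.null_order_stats(ref_B, L, max(ks))))[, ks, drop = FALSE]
      .artp_adjust_batch(obs, ref)$p_adj
    },
    art_a = {
      ps <- .design_psort(P, design, B, max(ks), decorr)
      perk <- .perk_pvalues(ps, ks, L)
      pmin_o <- .rowmin(perk)
      sm <- .minp_null_sample(L, ks, max(ref_B, 100000L),
                              seed = .sub_seed(design$seed, 2L, 17L))
      pmax((findInterval(pmin_o, sm) + 1) / (length(sm) + 1), pmin_o)
    },
    stop("unknown method: ", method)
  )
}

# resampling comparators: the observed partial-product (or its per-k
# profile) is referred to a bank of null statistics drawn as
# MVN(0, sigma), mirroring permutation approaches that preserve LD
.resampling_pvalues <- function(method, P, design, ref_B) {
  L <- design$L; k <- design$k; ks <- design$ks
  kmax <- if (method == "artp_resampling") max(ks) else k
  Pn <- .with_seed(.sub_seed(design$seed, 3L, 19L), {
    G <- matrix(rnorm(ref_B * L), ref_B, L) %*% .design_chol(design)
    .z_to_p(G, design$two_sided)
  })
  ref <- .cum_neg_log(.row_sort_smallest(Pn, kmax))
  obs <- .cum_neg_log(.row_sort_smallest(P, kmax))
  if (method == "rtp_resampling") {
    s <- sort.int(ref[, k], method = "quick")
    (ref_B - findInterval(obs[, k], s) + 1) / (ref_B + 1)
  } else {
    .artp_adjust_batch(obs[, ks, drop = FALSE],
                       ref[, ks, drop = FALSE])$p_adj
  }
}

#' Resampling RTP P-value for correlated statistics
#'
#' Single-dataset version of the resampling comparator: the observed
#' product of the k smallest (two-sided) P-values is referred to `B`
#' draws of the null statistics `MVN(0, sigma)`.
#'
#' @inheritParams truncation_product
#' @param sigma correlation matrix of the statistics.
#' @param B number of null draws.
#' @param seed integer seed.
#' @param two_sided sidedness used to convert null draws to P-values.
#' @return A [combined_result()].
#' @export
rtp_resampling <- function(pvals, k, sigma, B = 20000L, seed = 1L,
                           two_sided = TRUE) {
  ps <- pvalue_set(pvals)
  k <- .check_k(k, ps$L)
  stat <- -sum(log(ps$sorted[seq_len(k)]))
  R <- chol(sigma)
  sn <- .with_seed(seed, {
    Pn <- .z_to_p(matrix(rnorm(B * ps$L), B, ps$L) %*% R, two_sided)
    sort.int(rowSums(-log(.row_sort_smallest(Pn, k))), method = "quick")
  })
  p <- (B - findInterval(stat, sn) + 1) / (B + 1)
  combined_result("rtp_resampling", p, k = k, statistic = stat, B = B)
}
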