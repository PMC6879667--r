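# Adaptive truncation: the truncation point k is chosen to minimise the
# per-k combined P-value over a candidate set, and the minimum is then
# adjusted for that selection.

.check_ks <- function(ks, L) {
  if (is.null(ks) || length(ks) == 0L) stop("candidate set 'ks' is empty")
  if (any(ks != round(ks))) stop("'ks' must be integers")
  ks <- as.integer(ks)
  if (is.unsorted(ks, strictly = TRUE)) stop("'ks' must be strictly increasing")
  if (ks[1L] < 1L || ks[length(ks)] > L)
    stop(sprintf("'ks' must lie in [1, L = %d]", L))
  ks
}

#' Empirical adaptive RTP (single-layer simulation)
#'
#' Adaptive rank truncated product: for every candidate truncation point
#' the RTP P-value is estimated empirically by ranking the observed
#' partial product against a stored `B x max(ks)` matrix of null partial
#' products (the single-layer shortcut that avoids nested simulation);
#' the statistic is the minimum per-k P-value, and its selection-adjusted
#' P-value is the fraction of null rows whose own minimum is at most the
#' observed one, with the `(r + 1) / (B + 1)` correction.
#'
#' @inheritParams truncation_product
#' @param ks strictly increasing candidate truncation points (default
#'   `1:kmax`).
#' @param kmax convenience shorthand for `ks = 1:kmax`.
#' @param B number of null reference replicates (>= 1000).
#' @param seed integer seed for the null reference matrix.
#' @return A [combined_result()] with fields `k` (the minimising
#'   truncation point), `p_combined` (adjusted), and `per_k`, a data frame
#'   of the per-k empirical P-values.
#' @examples
#' artp_adaptive_empirical(c(0.001, 0.01, 0.3, 0.6, 0.9), kmax = 5,
#'                         B = 2000, seed = 1)
#' @export
artp_adaptive_empirical <- function(pvals, ks = NULL, kmax = NULL,
                                    B = 10000L, seed = 1L) {
  ps <- pvalue_set(pvals)
  if (is.null(ks)) ks <- seq_len(if (is.null(kmax)) ps$L else kmax)
  ks <- .check_ks(ks, ps$L)
  if (B < 1000L) stop("'B' must be at least 1000")
  .check_null_matrix_size(B, max(ks))
  obs <- cumsum(-log(ps$sorted))[ks]
  ref <- .with_seed(seed, .cum_neg_log(.null_order_stats(B, ps$L, max(ks))))[, ks, drop = FALSE]
  adj <- .artp_adjust_batch(matrix(obs, nrow = 1L), ref)
  per_k <- data.frame(k = ks, neg_log_w = obs, p_rtp_emp = adj$perk[1L, ])
  combined_result("artp", adj$p_adj[1L], k = ks[adj$argmin[1L]],
                  statistic = adj$minp[1L], per_k = per_k, B = B)
}

# Shared single-layer adjustment. obs: n x K matrix of observed -log
# partial products at the candidate ks; ref: B x K matching null matrix.
# Returns per-k empirical p's for the observed rows, their min, the argmin
# and the adjusted p.
.artp_adjust_batch <- function(obs, ref) {
  B <- nrow(ref); K <- ncol(ref); n <- nrow(obs)
  perk <- matrix(NA_real_, n, K)
  minp_null <- rep(1, B)
  for (j in seq_len(K)) {
    s <- sort.int(ref[, j], method = "quick")
    perk[, j] <- (B - findInterval(obs[, j], s) + 1) / (B + 1)
    minp_null <- pmin(minp_null, rank(-ref[, j], ties.method = "average") / B)
  }
  minp <- .rowmin(perk)
  argmin <- max.col(-perk, ties.method = "first")
  sm <- sort.int(minp_null, method = "quick")
  p_adj <- (findInterval(minp, sm) + 1) / (B + 1)
  list(perk = perk, minp = minp, argmin = argmin, p_adj = pmax(p_adj, minp))
}

.check_null_matrix_size <- function(B, cols) {
  cap <- getOption("artcombine.max_null_cells", 2e8)
  if (as.double(B) * cols > cap)
    stop(sprintf(paste0("null reference matrix of %g cells exceeds the cap ",
                        "of %g; lower B (or raise ",
                        "options(artcombine.max_null_cells = ...))"),
                 as.double(B) * cols, cap))
}

#' Multivariate normal model of the per-k partial-sum statistics
#'
#' Null means, scales and correlation of the standardised per-candidate-k
#' statistics underlying the adaptive ART. Each per-k combined P-value is
#' mapped to a normal score `Z_k = qnorm(1 - P_k)`; the correlation matrix
#' of the scores is estimated from a fixed-seed null sample generated via
#' the normalised-spacings representation of uniform order statistics
#' (partial products at nested k share their leading spacings, so the
#' correlation is positive and increases with k/k').
#'
#' @param ks candidate truncation points.
#' @param L number of tests.
#' @param n_null size of the fixed-seed null sample used for estimation.
#' @param seed seed for that sample.
#' @return Object of class `"partial_sum_model"`: list with `ks`, `L`,
#'   `R` (correlation of the normal scores, PSD-projected if needed),
#'   `shapes` (gamma shapes `k - 1 + lambda_k`, `NA` at `k = 1`),
#'   `n_null`, `seed`.
#' @export
partial_sum_model <- function(ks, L, n_null = 50000L, seed = 1L) {
  ks <- .check_ks(ks, L)
  lam <- ifelse(ks >= 2L, art_shape_lambda(pmax(ks, 2L), L), NA_real_)
  shapes <- ifelse(ks >= 2L, ks - 1 + lam, NA_real_)
  if (length(ks) == 1L) {
    R <- matrix(1, 1, 1)
  } else {
    P <- .with_seed(seed, .perk_pvalues(.null_order_stats(n_null, L, max(ks)), ks, L))
    R <- cor(qnorm(1 - P))
    ev <- eigen(R, symmetric = TRUE)
    if (any(ev$values < -1e-10)) {
      warning("estimated correlation not PSD; projecting to the nearest PSD matrix")
      v <- pmax(ev$values, 1e-10)
      R <- ev$vectors %*% (v * t(ev$vectors))
      d <- 1 / sqrt(diag(R))
      R <- R * tcrossprod(d)
    }
  }
  structure(list(ks = ks, L = L, R = R, shapes = shapes,
                 n_null = n_null, seed = seed),
            class = "partial_sum_model")
}

#' @export
print.partial_sum_model <- function(x, ...) {
  cat(sprintf("Partial-sum model: L = %d, candidate ks = {%s}\n",
              x$L, paste(x$ks, collapse = ", ")))
  cat(sprintf("  score correlation range (off-diagonal): [%.3f, %.3f]\n",
              min(x$R[lower.tri(x$R)], 1), max(x$R[lower.tri(x$R)], -1)))
  invisible(x)
}

# sorted null sample of min-k per-k P-values, cached per (L, ks, n, seed)
.minp_null_sample <- function(L, ks, n, seed) {
  key <- paste0("minp_", L, "_", paste(ks, collapse = "."), "_", n, "_", seed)
  if (is.null(.art_cache[[key]])) {
    minp <- .with_seed(seed, {
      out <- numeric(n); done <- 0L
      while (done < n) {
        m <- min(20000L, n - done)
        out[done + seq_len(m)] <-
          .rowmin(.perk_pvalues(.null_order_stats(m, L, max(ks)), ks, L))
        done <- done + m
      }
      out
    })
    .art_cache[[key]] <- sort.int(minp, method = "quick")
  }
  .art_cache[[key]]
}

#' Adaptive ART (ART-A) combined P-value
#'
#' For every candidate truncation point the exact per-k combined P-value
#' is computed analytically (Sidak form at `k = 1`, the gamma tail of the
#' ART statistic otherwise); the statistic is their minimum, and the
#' selection-adjusted P-value is `Pr(min_k P_k <= observed)` under the
#' global null.
#'
#' Two evaluations of that null law are provided. The default,
#' `method = "exact"`, integrates the exact joint law of the per-k
#' P-values by fixed-seed Monte-Carlo over the normalised-spacings
#' representation of uniform order statistics (deterministic given
#' `seed`; the sample is cached and reused across calls with the same
#' `(L, ks, n_mvn, seed)`). `method = "mvn"` instead models the vector of
#' normal scores `qnorm(1 - P_k)` as multivariate normal with correlation
#' from [partial_sum_model()] -- the classical normal-approximation route;
#' it is faster for very large `L` but its tail is only approximate (see
#' the package vignette for measurements).
#'
#' @inheritParams artp_adaptive_empirical
#' @param n_mvn Monte-Carlo sample size for the null of the minimum.
#' @param method `"exact"` or `"mvn"`.
#' @param model optional precomputed [partial_sum_model()] (for
#'   `method = "mvn"`).
#' @return A [combined_result()] with the adjusted P-value, the
#'   minimising `k`, and `per_k`, the per-candidate analytic P-values.
#'   The adjusted value is never below the unadjusted minimum.
#' @examples
#' art_a_pvalue(c(0.001, 0.01, 0.3, 0.6, 0.9), kmax = 5,
#'              n_mvn = 10000, seed = 1)
#' @export
art_a_pvalue <- function(pvals, ks = NULL, kmax = NULL, n_mvn = 100000L,
                         seed = 1L, method = c("exact", "mvn"),
                         model = NULL) {
  method <- match.arg(method)
  ps <- pvalue_set(pvals)
  if (is.null(ks)) ks <- seq_len(if (is.null(kmax)) ps$L else kmax)
  ks <- .check_ks(ks, ps$L)
  if (n_mvn < 10000L) stop("'n_mvn' must be at least 10000")
  u <- matrix(ps$sorted[seq_len(max(ks))], nrow = 1L)
  perk <- drop(.perk_pvalues(u, ks, ps$L))
  pmin_obs <- min(perk)
  argmin <- ks[which.min(perk)]
  if (length(ks) == 1L) {
    p_adj <- pmin_obs  # no selection: Pr(P_k <= m) = m exactly
  } else if (method == "exact") {
    sm <- .minp_null_sample(ps$L, ks, n_mvn, seed)
    p_adj <- (findInterval(pmin_obs, sm) + 1) / (n_mvn + 1)
  } else {
    if (is.null(model)) model <- partial_sum_model(ks, ps$L, seed = seed)
    if (!identical(model$ks, ks) || model$L != ps$L)
      stop("'model' does not match 'ks' and L")
    zmax <- .mvn_max_sample(model, n_mvn, seed)
    p_adj <- (sum(zmax >= qnorm(1 - pmin_obs)) + 1) / (n_mvn + 1)
  }
  combined_result("art_a", max(p_adj, pmin_obs), k = argmin,
                  statistic = pmin_obs,
                  per_k = data.frame(k = ks, p_art = perk),
                  method_detail = method)
}

# sorted sample of max_k Z_k under the MVN model, cached
.mvn_max_sample <- function(model, n, seed) {
  key <- paste0("mvnmax_", model$L, "_", paste(model$ks, collapse = "."),
                "_", n, "_", seed)
  if (is.null(.art_cache[[key]])) {
    zmax <- .with_seed(seed + 1, {
      Z <- MASS::mvrnorm(n, mu = rep(0, ncol(model$R)), Sigma = model$R)
      .rowmin(-Z) * -1
    })
    .art_cache[[key]] <- sort.int(zmax, method = "quick")
  }
  .art_cache[[key]]
}
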