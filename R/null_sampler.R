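# Shared machinery for sampling uniform order statistics under the global
# null and for row-wise partial sorting.
#
# The k smallest of L iid uniforms are generated without sorting through
# the normalised-spacings representation: with E_1, ..., E_{L+1} iid
# Exp(1) and S_j their partial sums, (S_1, ..., S_L) / S_{L+1} is
# distributed as the full vector of uniform order statistics. Only the
# first kmax columns are materialised.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# deterministic sub-seed for replicate streams; stays below 2^31
.sub_seed <- function(seed, index, salt = 0L) {
  (as.double(seed) * 2654435761 + as.double(index) * 40503 +
     as.double(salt) * 97) %% 2147483647
}

# B x kmax matrix of the kmax smallest order statistics of L uniforms
.null_order_stats <- function(B, L, kmax, chunk = 20000L) {
  stopifnot(kmax >= 1L, kmax <= L)
  out <- matrix(NA_real_, B, kmax)
  done <- 0L
  while (done < B) {
    n <- min(chunk, B - done)
    e <- matrix(rexp(n * (L + 1L)), n, L + 1L)
    tot <- rowSums(e)
    cs <- e[, seq_len(kmax), drop = FALSE]
    if (kmax > 1L) for (j in 2:kmax) cs[, j] <- cs[, j] + cs[, j - 1L]
    out[done + seq_len(n), ] <- cs / tot
    done <- done + n
  }
  out
}

# cumulative -sum(log) across columns: column k holds -log of the partial
# product of the k smallest P-values
.cum_neg_log <- function(u) {
  nl <- -log(u)
  if (ncol(nl) > 1L) for (j in 2:ncol(nl)) nl[, j] <- nl[, j] + nl[, j - 1L]
  nl
}

# per-candidate-k combined P-values (columns follow ks); Sidak for k = 1,
# exact gamma ART tail otherwise. u: rows of at least max(ks) smallest
# order statistics, cnl: matching .cum_neg_log(u).
.perk_pvalues <- function(u, ks, L, cnl = .cum_neg_log(u)) {
  out <- matrix(NA_real_, nrow(u), length(ks))
  for (j in seq_along(ks)) {
    k <- ks[j]
    out[, j] <- if (k == 1L) -expm1(L * log1p(-u[, 1L]))
                else .art_pvalue_batch(cnl[, k - 1L], u[, k], k, L)
  }
  out
}

# rows of the k smallest entries, each row sorted ascending
.row_sort_smallest <- function(m, k) {
  if (k >= ncol(m)) return(t(apply(m, 1L, sort.int, method = "quick")))
  t(apply(m, 1L, function(r) sort.int(r, partial = seq_len(k))[seq_len(k)]))
}

.rowmin <- function(m) do.call(pmin, as.data.frame(m))
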