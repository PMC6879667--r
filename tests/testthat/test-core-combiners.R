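test_that("pvalue_set validates, clamps and sorts", {
  ps <- pvalue_set(c(0.5, 0.1, 0.9))
  expect_equal(ps$L, 3)
  expect_equal(ps$sorted, sort(ps$values))
  expect_error(pvalue_set(c(0.2, 1.5)), "\\[0, 1\\]")
  expect_error(pvalue_set(numeric(0)))
  expect_warning(ps0 <- pvalue_set(c(0, 0.5, 1)), "clamped")
  expect_true(all(ps0$values > 0 & ps0$values < 1))
  expect_equal(ps0$n_clamped, 2)
})

test_that("truncation product multiplies the k smallest in log space", {
  expect_equal(truncation_product(0.5, 1)$w, 0.5)
  expect_equal(truncation_product(c(0.2, 0.1), 2)$w, 0.02)
  tab <- mor_table8()
  expect_equal(truncation_product(tab$pvalue, 2)$w, 0.0007 * 0.0941,
               tolerance = 1e-12)
  # w nonincreasing in k; no underflow for tiny inputs
  ws <- sapply(1:5, function(k) truncation_product(rep(1e-200, 5), k)$neg_log_w)
  expect_true(all(diff(ws) > 0))
  expect_error(truncation_product(c(0.1, 0.2), 3), "k")
})

test_that("RTP combined P-value matches closed forms and oracles", {
  # minimum-P closed form at k = 1
  expect_equal(rtp_pvalue(truncation_product(c(0.1, 0.4), 1))$p_combined,
               0.19, tolerance = 1e-12)
  # Fisher identity at k = L
  for (p in list(c(0.2, 0.01, 0.6), runif(8, 0.01, 0.99))) {
    expect_equal(rtp_pvalue(p, length(p))$p_combined,
                 fisher_pvalue(p)$p_combined, tolerance = 1e-8)
  }
  # frozen brute-force oracle (1e7 draws, seed 20260929): product of the
  # 2 smallest of 4 uniforms <= 0.01 occurred with frequency 0.1718751,
  # s.e. 0.000119
  tp <- structure(list(k = 2L, L = 4L, w = 0.01, neg_log_w = -log(0.01)),
                  class = "truncation_product")
  expect_lt(abs(rtp_pvalue(tp)$p_combined - 0.1718751), 3 * 0.000119)
})

test_that("fixed-order quadrature agrees with adaptive quadrature", {
  grid <- expand.grid(k = c(2, 3, 5, 10, 50), L = c(12, 20, 100, 500),
                      t = c(2, 10, 30, 70))
  grid <- grid[grid$k < grid$L, ]
  for (i in seq_len(nrow(grid))) {
    k <- grid$k[i]; L <- grid$L[i]; t <- grid$t[i]
    expect_lt(abs(artcombine:::.rtp_cdf_batch(t, k, L) -
                    quad_rtp_oracle(k, L, t)), 1e-9,
              label = sprintf("absolute error at k=%d L=%d t=%g", k, L, t))
  }
})

test_that("RTP is monotone in w and bounded", {
  ts <- seq(0.5, 40, length.out = 30)
  for (cfg in list(c(2, 10), c(5, 20), c(10, 100))) {
    p <- artcombine:::.rtp_cdf_batch(ts, cfg[1], cfg[2])
    expect_true(all(diff(p) <= 1e-12))  # larger t = smaller w = smaller P
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_equal(artcombine:::.rtp_cdf_batch(0, 3, 10), 1)  # w = 1
})

test_that("simultaneous evaluation at k+1 matches direct evaluation", {
  # Pr(W_{k+1} <= w) via the k-conditioning equals the direct k+1 form
  tp <- structure(list(k = 2L, L = 5L, w = 1e-3, neg_log_w = -log(1e-3)),
                  class = "truncation_product")
  direct <- structure(list(k = 3L, L = 5L, w = 1e-3, neg_log_w = -log(1e-3)),
                      class = "truncation_product")
  expect_equal(rtp_pvalue_next(tp)$p_combined, rtp_pvalue(direct)$p_combined,
               tolerance = 1e-8)
  # k + 1 = L limit is the Fisher case
  tpf <- structure(list(k = 1L, L = 2L, w = 0.02, neg_log_w = -log(0.02)),
                   class = "truncation_product")
  expect_equal(rtp_pvalue_next(tpf)$p_combined,
               pchisq(-2 * log(0.02), df = 4, lower.tail = FALSE),
               tolerance = 1e-8)
  # upper bound as w -> 1
  tp1 <- structure(list(k = 2L, L = 6L, w = 1, neg_log_w = 0),
                   class = "truncation_product")
  expect_equal(rtp_pvalue_next(tp1)$p_combined, 1)
})

test_that("legacy closed form agrees with the integral form on the k < L <= 20 grid", {
  worst <- 0
  for (k in c(1, 2, 3, 5, 10, 15, 19)) for (L in unique(c(k + 1, 12, 20))) {
    if (k >= L) next
    for (w in c(0.5, 0.2, 1e-3, 1e-6)) {
      tp <- structure(list(k = as.integer(k), L = as.integer(L), w = w,
                           neg_log_w = -log(w)), class = "truncation_product")
      d <- abs(rtp_pvalue_legacy(tp)$p_combined - rtp_pvalue(tp)$p_combined)
      worst <- max(worst, d)
    }
  }
  expect_lt(worst, 1e-6)
  # frozen brute-force oracle (1e7 draws, seed 20260929): k=5, L=20,
  # w=1e-6 gave 0.2052451, s.e. 0.000128
  tp <- structure(list(k = 5L, L = 20L, w = 1e-6, neg_log_w = -log(1e-6)),
                  class = "truncation_product")
  expect_lt(abs(rtp_pvalue_legacy(tp)$p_combined - 0.2052451), 3 * 0.000128)
  # closed form at k = 1
  tp1 <- structure(list(k = 1L, L = 3L, w = 0.05, neg_log_w = -log(0.05)),
                   class = "truncation_product")
  expect_equal(rtp_pvalue_legacy(tp1)$p_combined, 1 - (1 - 0.05)^3,
               tolerance = 1e-8)
  expect_warning(
    rtp_pvalue_legacy(structure(list(k = 5L, L = 30L, w = .1,
                                     neg_log_w = -log(.1)),
                                class = "truncation_product")),
    "unstable")
})

test_that("RTP P-values are uniform under the null (KS)", {
  set.seed(101)
  for (k in c(1, 2, 5)) for (L in c(5, 20)) {
    u <- artcombine:::.null_order_stats(20000, L, k)
    t <- rowSums(-log(u[, seq_len(k), drop = FALSE]))
    p <- artcombine:::.rtp_cdf_batch(t, k, L)
    expect_gt(ks.test(p, "punif")$p.value, 0.001,
              label = sprintf("KS uniformity k=%d L=%d", k, L))
  }
})

test_that("Fisher, Simes and Sidak benchmarks", {
  expect_equal(fisher_pvalue(0.37)$p_combined, 0.37, tolerance = 1e-12)
  expect_warning(f1 <- fisher_pvalue(rep(1, 5)), "clamped")
  expect_equal(f1$p_combined, 1, tolerance = 1e-10)
  f <- fisher_pvalue(c(0.1, 0.2))
  expect_equal(f$statistic, 7.824046, tolerance = 1e-6)
  expect_equal(f$p_combined, pchisq(f$statistic, 4, lower.tail = FALSE))

  expect_equal(simes_pvalue(rep(0.3, 7))$p_combined, 0.3, tolerance = 1e-12)
  expect_equal(simes_pvalue(0.42)$p_combined, 0.42)
  tab <- mor_table8()
  expect_equal(simes_pvalue(tab$pvalue)$p_combined, 0.0077, tolerance = 1e-12)

  expect_equal(sidak_minp_pvalue(0.05)$p_combined, 0.05)
  expect_equal(sidak_minp_pvalue(c(0.1, 0.6))$p_combined, 0.19,
               tolerance = 1e-12)
  # Simes never exceeds Bonferroni
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_lte(simes_pvalue(p)$p_combined, min(1, length(p) * min(p)) + 1e-15)
  }
})

test_that("RTP at k = 1 is exactly the Sidak minimum-P correction", {
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1), 0, 1)
    expect_equal(rtp_pvalue(p, 1)$p_combined,
                 sidak_minp_pvalue(p)$p_combined, tolerance = 1e-10)
  }
})
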