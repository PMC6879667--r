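test_that("orthogonal transform: identity, closed-form 2x2, validity", {
  m <- orthogonal_transform(diag(4))
  expect_equal(m$transform, diag(4), tolerance = 1e-12)

  s <- matrix(c(1, .5, .5, 1), 2)
  m2 <- orthogonal_transform(s)
  expect_equal(sort(m2$eigvals), c(0.5, 1.5))
  Q <- cbind(c(1, 1), c(1, -1)) / sqrt(2)
  H_expected <- Q %*% diag(c(1.5, 0.5)^-0.5) %*% t(Q)
  expect_equal(m2$transform, H_expected, tolerance = 1e-12)
  expect_equal(t(m2$transform) %*% s %*% m2$transform, diag(2),
               tolerance = 1e-12)

  expect_error(orthogonal_transform(matrix(1:4, 2)), "symmetric")
  expect_error(orthogonal_transform(matrix(c(2, 0, 0, 2), 2)), "diagonal")
})

test_that("H^T Sigma H = I for random PSD correlation matrices", {
  set.seed(606)
  for (i in 1:20) {
    L <- sample(3:30, 1)
    S <- gen_random_correlation(L, runif(1, 0.1, 0.6), seed = i)
    m <- orthogonal_transform(S)
    expect_lt(max(abs(t(m$transform) %*% S %*% m$transform - diag(L))), 1e-8)
  }
})

test_that("near-singular matrices are floored (or rejected in strict mode)", {
  S <- matrix(0.999999999999, 3, 3); diag(S) <- 1
  expect_warning(m <- orthogonal_transform(S), "floored")
  expect_gt(m$n_floored, 0)
  expect_error(suppressWarnings(orthogonal_transform(S, strict = TRUE)))
})

test_that("equicorrelation transform commutes with permutations", {
  L <- 6
  S <- matrix(0.4, L, L); diag(S) <- 1
  H <- orthogonal_transform(S)$transform
  y <- c(-1.2, 0.3, 2.5, 0.0, -0.7, 1.1)
  perm <- c(3, 1, 6, 2, 5, 4)
  ye <- drop(crossprod(H, y))
  ye_perm <- drop(crossprod(H, y[perm]))
  expect_equal(ye_perm, ye[perm], tolerance = 1e-10)
})

test_that("decorrelation round-trips through the identity and fixes the median", {
  p <- c(0.1, 0.5, 0.9, 0.33)
  m <- orthogonal_transform(diag(4))
  expect_equal(decorrelate_pvalues(p, m)$values, p, tolerance = 1e-12)
  s <- matrix(c(1, .7, .7, 1), 2)
  expect_equal(decorrelate_pvalues(c(0.5, 0.5), orthogonal_transform(s))$values,
               c(0.5, 0.5), tolerance = 1e-12)
  expect_error(decorrelate_pvalues(c(.1, .2, .3), m), "dimension")
})

test_that("decorrelated null P-values are uniform and uncorrelated", {
  set.seed(707)
  L <- 10; B <- 20000
  S <- matrix(0.5, L, L); diag(S) <- 1
  H <- orthogonal_transform(S)$transform
  Y <- MASS::mvrnorm(B, rep(0, L), S)
  Pe <- pnorm(Y %*% H, lower.tail = FALSE)
  for (j in seq_len(L))
    expect_gt(ks.test(Pe[, j], "punif")$p.value, 0.001)
  Ze <- qnorm(Pe)
  cors <- cor(Ze)[lower.tri(diag(L))]
  expect_lt(max(abs(cors)), 4 / sqrt(B))
})

test_that("full decorrelation pipeline preserves the type-I error of ART", {
  d <- simulation_design(L = 20, k = 5, B = 4000,
                         sigma_model = "equicorrelation", rho = 0.5, seed = 17)
  r <- estimate_rate("art_decorr", d, alpha = 0.05)
  expect_lt(abs(r$rate - 0.05), 3 * sqrt(0.05 * 0.95 / 4000) + 0.005)
})

test_that("LD correlations from haplotype frequencies", {
  # independence
  t0 <- data.frame(haplotype = c("11", "10", "01", "00"),
                   freq = c(.25, .25, .25, .25))
  expect_equal(ld_correlation_from_haplotypes(t0)[1, 2], 0, tolerance = 1e-12)
  # complete LD
  t1 <- data.frame(haplotype = c("11", "00"), freq = c(.3, .7))
  expect_equal(ld_correlation_from_haplotypes(t1)[1, 2], 1, tolerance = 1e-12)
  # hand-computed intermediate case: D = .4 - .25 = .15, r = .15/.25 = .6
  t2 <- data.frame(haplotype = c("11", "10", "01", "00"),
                   freq = c(.4, .1, .1, .4))
  r2 <- ld_correlation_from_haplotypes(t2)
  expect_equal(r2[1, 2], 0.6, tolerance = 1e-12)
  expect_equal(diag(r2), c(1, 1))
  # monomorphic locus is reported by index
  t3 <- data.frame(haplotype = c("10", "00"), freq = c(.5, .5))
  expect_error(ld_correlation_from_haplotypes(t3), "locus.* 2")
  expect_error(ld_correlation_from_haplotypes(
    data.frame(haplotype = c("11", "0"), freq = c(.5, .5))), "length")
  expect_error(ld_correlation_from_haplotypes(
    data.frame(haplotype = c("11", "00"), freq = c(.6, .6))), "sum to 1")
})

test_that("haplotype-derived matrices are symmetric, bounded and PSD", {
  set.seed(808)
  for (i in 1:10) {
    L <- sample(3:8, 1)
    nh <- sample(4:12, 1)
    hap <- unique(replicate(nh, paste(rbinom(L, 1, 0.5), collapse = "")))
    f <- runif(length(hap)); f <- f / sum(f)
    tab <- data.frame(haplotype = hap, freq = f)
    r <- tryCatch(ld_correlation_from_haplotypes(tab), error = function(e) NULL)
    if (is.null(r)) next  # monomorphic draw
    expect_true(isSymmetric(r))
    expect_true(all(r >= -1 & r <= 1))
    expect_gt(min(eigen(r, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("DOT-based power exceeds the resampling comparator under heterogeneous effects", {
  d <- simulation_design(L = 10, k = 10, B = 10000,
                         effect_model = "uniform", mu_lo = -0.45, mu_hi = 1.3,
                         sigma_model = "random_factor", mean_abs_rho = 0.45,
                         two_sided = TRUE, seed = 6)
  pow_dot <- estimate_rate("rtp_decorr", d)$rate
  pow_res <- estimate_rate("rtp_resampling", d, ref_B = 20000)$rate
  expect_gt(pow_dot, pow_res + 0.2)
})
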