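# artcombine

Combined P-value tests for detecting weak, distributed signals — for
statistical geneticists and biostatisticians who need a single gene-,
pathway- or study-level P-value from many SNP- or test-level P-values,
with the evidence concentrated in the top-ranking (smallest) ones.

## What it implements

Given P-values `P_1, …, P_L` and a truncation point `k`:

* **RTP** — the rank truncated product `W_k = Π_{i≤k} P_(i)`. Its null CDF
  is evaluated as one bounded integral obtained by conditioning on
  `P_(k+1) ~ Beta(k+1, L−k)`:

  `Pr(W_k ≤ w) = F_B(p₀) + ∫_{p₀}^1 f_B(p) · Ḡ_k(k·log p − log w) dp`,

  with `Ḡ_k` the Gamma(k,1) survival function and `p₀ = w^{1/k}`. At
  `k = 1` this is the Šidák correction `1 − (1 − P_(1))^L`; at `k = L` it
  is Fisher's chi-square with `2L` df. A legacy closed form is kept as a
  numerical cross-check (`rtp_pvalue_legacy()`).
* **ART** — the augmented rank truncation statistic

  `A_k = −log W_{k−1} + (k−1)·log P_(k) + G⁻¹_λ(1 − B_k(P_(k)))`,
  `λ = (k−1)(ψ(L+1) − ψ(k))`,

  which is **exactly** Gamma(k−1+λ, 1) under the global null — the
  combined P-value is a single gamma tail, no integration.
* **Adaptive variants** — `artp_adaptive_empirical()` (single-layer
  empirical aRTP) and `art_a_pvalue()` (ART-A: exact analytic per-k
  P-values, selection-adjusted minimum) search `k` over a candidate set
  and adjust for the search.
* **DOT decorrelation** — for correlated statistics `y ~ MVN(0, Σ)`,
  `H = QΛ^{−1/2}Qᵀ` from `Σ = QΛQᵀ` makes `Hᵀy` independent, so
  transformed P-values feed any combiner above
  (`orthogonal_transform()`, `decorrelate_pvalues()`); LD correlation
  matrices are reconstructed from haplotype frequencies via
  `D_ij = P_ij − p_i p_j` (`ld_correlation_from_haplotypes()`).
* **Simulation harness** — `simulation_design()`, `estimate_rate()`,
  `reproduce_table()` re-estimate type-I error and power surfaces at
  configurable Monte-Carlo scale, with binomial standard errors.

Benchmarks `fisher_pvalue()`, `simes_pvalue()` and `sidak_minp_pvalue()`
are included. See `vignette("art-methods")` for the full methodology.

## Worked example

Eleven published SNP-level P-values for association of μ-opioid receptor
(OPRM1) variants with pain sensitivity ship with the package:

```r
library(artcombine)
p <- mor_table8()$pvalue

simes_pvalue(p)
#> simes combined P-value: 0.0077
#>   statistic = 0.0077

rtp_pvalue(p, k = 2)
#> rtp combined P-value (k = 2): 0.0183538
#>   statistic = 9.62783

art_pvalue(p, k = 2)
#> art combined P-value (k = 2): 0.0211822
#>   statistic = 7.4737
#>   lambda = 2.01988

art_a_pvalue(p, kmax = 11, n_mvn = 1e5, seed = 1)
#> art_a combined P-value (k = 1): 0.0191098
#>   statistic = 0.00767311
```

Reading: the single strongest SNP (P = 0.0007) already gives a
multiplicity-corrected 0.0077 (Simes; Šidák gives 0.00767). Combining the
two smallest P-values keeps the gene-level evidence near 0.02 under both
RTP and ART — the two statistics agree closely, ART needing only standard
gamma/beta functions. The adaptive ART searches k = 1…11 and, after
paying the selection penalty, settles on k = 1 with an adjusted P-value
of 0.019. These combinations treat the P-values as independent; with the
gene's LD correlation matrix (e.g. from haplotype frequencies via
`ld_correlation_from_haplotypes()`), decorrelate first:

```r
model <- orthogonal_transform(ld_matrix)
p_ind <- decorrelate_pvalues(p, model)$values
art_pvalue(p_ind, k = 2)
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/artcombine.R combine --method art --k 2 --column pvalue \
    inst/extdata/mor_table8.tsv
```

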