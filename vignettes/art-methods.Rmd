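---
title: "Combining top-ranking P-values: rank truncation, augmentation, and decorrelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining top-ranking P-values: rank truncation, augmentation, and decorrelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(artcombine)
```

## The problem

Gene- and pathway-level association tests summarise the evidence carried by
many SNP-level P-values $P_1, \dots, P_L$ into a single combined P-value for
the global null hypothesis that none of the $L$ tests carries signal. When
only a minority of the tests is expected to be non-null, combiners that use
*all* P-values (Fisher's $-2\sum\log P_i \sim \chi^2_{2L}$) dilute the
signal, and combiners that use only the single smallest (Šidák/Bonferroni)
discard corroborating evidence. Rank truncation takes the middle road: fix a
truncation point $k$ and combine the $k$ smallest P-values.

This vignette describes the statistics implemented here, the numerical
choices behind them, and the simulation harness used to check calibration
and power.

## The RTP distribution as a single bounded integral

The rank truncated product statistic is
$W_k = \prod_{i=1}^{k} P_{(i)}$, the product of the $k$ smallest order
statistics. Its null distribution is awkward because the $k$ smallest of
$L$ uniforms are dependent; the dependence is induced entirely by the
$(k{+}1)$-th order statistic. Conditioning on $P_{(k+1)} = p \sim
\mathrm{Beta}(k{+}1, L{-}k)$, the $k$ smallest are iid uniform on $(0, p)$,
so with $t = -\log w$,

$$
\Pr(W_k \le w)
 = F_B(p_0) + \int_{p_0}^{1} f_B(p)\,
   \bar G_k\!\left(k \log p + t\right)\, dp,
 \qquad p_0 = e^{-t/k},
$$

where $f_B$, $F_B$ are the $\mathrm{Beta}(k{+}1, L{-}k)$ density and CDF and
$\bar G_k$ is the $\mathrm{Gamma}(k, 1)$ survival function. `rtp_pvalue()`
evaluates this form. Three limits serve as exact anchors: $k = 1$ gives the
Šidák correction $1 - (1 - P_{(1)})^L$, $k = L$ gives Fisher's chi-square
with $2L$ degrees of freedom, and the same conditioning evaluated with the
beta quantile raised to the power $k{+}1$ gives $\Pr(W_{k+1} \le w)$
(`rtp_pvalue_next()`), so adjacent truncation points share one pass over
the data.

**Numerical choices.** The integral is evaluated on $(p_0, 1)$ -- the region
where the gamma argument is positive -- by fixed-order Gauss–Legendre
quadrature (256 nodes), in the survival form shown above. Writing the
probability as a sum of positive terms, rather than one minus a number close
to one, keeps small combined P-values accurate in absolute terms; the test
suite validates the fixed rule against adaptive quadrature to an absolute
tolerance of $10^{-9}$ across $k \le 50$, $L \le 500$ and $t \le 70$. At
$k = 1$ the integrand has a near-pole just outside the interval (derivative
of order $1/w$ at $p_0$) that defeats any fixed rule, so the exact closed
form is used there; the identity with `sidak_minp_pvalue()` is then
machine-exact, as the test suite asserts at $10^{-10}$. P-values of exactly
0 or 1 are clamped to $[10^{-300}, 1 - 10^{-16}]$ with a warning so that
log-space products stay finite.

**The legacy closed form.** An order-statistic closed form of the same CDF
(`rtp_pvalue_legacy()`) is retained purely as a cross-check: a finite sum of
alternating-sign binomial terms, each multiplying a bounded one-dimensional
integral. Its inner integrals are evaluated by quadrature rather than by the
forward recurrence in the polynomial degree, which is unstable once the
degree exceeds the exponential rate. Even so, the alternating binomial
coefficients grow combinatorially with $L - k$, and the form visibly loses
accuracy beyond $L \approx 25$ (it warns there). Agreement with the
integral form to $10^{-6}$ over the whole $k < L \le 20$ grid is part of
the acceptance checks; the integral form is the production path.

## The augmented statistic ART

Conditioning on $P_{(k)}$ instead yields an *integration-free* statistic.
The quantity

$$
\Gamma_k \;=\; -\log W_{k-1} + (k-1)\log P_{(k)}
        \;=\; \sum_{i<k} -\log\!\big(P_{(i)}/P_{(k)}\big)
$$

is exactly $\mathrm{Gamma}(k{-}1, 1)$ and independent of $P_{(k)}$. (Via
the Rényi spacings representation of uniform order statistics,
$\Gamma_k$ is literally the partial sum of the first $k-1$ standard
exponential spacings.) Scaling alone would discard the information in the
magnitude of $P_{(k)}$, so the statistic is *augmented*: the
$\mathrm{Beta}(k, L{-}k{+}1)$ survival probability of $P_{(k)}$ is mapped
through a $\mathrm{Gamma}(\lambda, 1)$ quantile and added,

$$
A_k = \Gamma_k + G^{-1}_{\lambda}\!\big(1 - B_k(P_{(k)})\big),
\qquad
\lambda = (k-1)\,\big(\psi(L+1) - \psi(k)\big),
$$

with $\psi$ the digamma function. The weight $\lambda$ equals $(k-1)$ times
the null expectation of $-\log P_{(k)}$, so the augmentation term carries
the same expected weight as the part of the product it replaces (the same
device as gamma-weighting in Lancaster-style combiners). Under the global
null $A_k \sim \mathrm{Gamma}(k - 1 + \lambda,\, 1)$ **exactly** -- the
combined P-value `art_pvalue()` is a single gamma tail. The test suite
verifies the null law by Kolmogorov–Smirnov on 50,000 simulated replicates
at $(k, L) \in \{(2,5), (5,20), (10,100)\}$, and verifies that ART and RTP
P-values are rank-correlated above 0.95 under the null.

Two guards: the beta survival probability is computed from the lower tail
(`qgamma(pbeta(p, k, L-k+1), shape, lower.tail = FALSE)`), avoiding
cancellation when $P_{(k)}$ is small; and $k = 1$, where $\lambda = 0$
degenerates the construction, routes to the Šidák form, which is the
$k = 1$ limit of RTP.

## Adaptive truncation

A good $k$ is rarely known in advance. Both adaptive variants evaluate a
candidate set (by default $\{1, \dots, k_{\max}\}$), take the smallest
per-k combined P-value, and pay the multiplicity price of that minimum;
the adjusted value is never below the unadjusted minimum, which the test
suite asserts on arbitrary inputs.

`artp_adaptive_empirical()` is the classical single-layer procedure: a
$B \times k_{\max}$ matrix of null partial products is stored; per-k
P-values of the observed data and of every null row are obtained by
ranking within columns (midrank at ties), and the minimum's null
distribution is read off the same matrix, with the $(r+1)/(B+1)$
estimator avoiding zero P-values. A configurable memory cap
(`options(artcombine.max_null_cells = ...)`) turns an oversized $B \times
L$ request into an explicit error rather than an allocation failure.

`art_a_pvalue()` is the analytic-marginal variant: every per-k P-value is
computed *exactly* (gamma tail, or Šidák at $k = 1$), and only the null
law of their minimum needs evaluating. Two evaluations are provided:

* `method = "exact"` (default): the joint null of the per-k P-values is a
  deterministic function of $L$ iid exponentials through the spacings
  representation, so the minimum's null distribution is integrated by
  fixed-seed Monte-Carlo over that representation ($10^5$ draws by
  default, sorted once and cached; deterministic given `seed`).
* `method = "mvn"`: the vector of normal scores $\Phi^{-1}(1 - P_k)$ is
  modelled as multivariate normal with correlation estimated from a
  fixed-seed null sample (`partial_sum_model()`); the minimum is then
  evaluated under that Gaussian model.

The MVN route is the textbook normal-approximation construction, and the
partial-sum model is useful in its own right (the correlation between
nested candidate statistics is positive and grows with $k/k'$, which the
tests check). It is not the default because the joint *tail* of the per-k
P-values is not Gaussian: the candidates share their leading exponential
spacings, and near the rejection threshold a Gaussian copula distorts the
adjusted P-value by more than the Monte-Carlo tolerance of the
calibration surfaces this package is tested against. Calibration is the
contract here, so the exact-representation evaluation is the default; the
two routes are compared directly in the test suite and agree to copula
accuracy away from the extreme tail.

## Correlated P-values: decorrelate, then combine

SNP-level statistics within a gene are correlated through linkage
disequilibrium (LD). If the statistic vector is $\mathbf{y} \sim
\mathrm{MVN}(\mathbf{0}, \Sigma)$ under the null, eigendecomposition
$\Sigma = Q \Lambda Q^{\top}$ gives the symmetric inverse square root
$H = Q \Lambda^{-1/2} Q^{\top}$, and $\mathbf{y}_e = H^{\top}\mathbf{y}$
has identity covariance: the transformed P-values $1 - \Phi(\mathbf{y}_e)$
are iid uniform and any combiner above applies unchanged. Among all square
roots of $\Sigma^{-1}$, the symmetric one is used because it is invariant
to coordinate order in the equicorrelation case -- permuting the inputs
permutes, rather than changes, the outputs (asserted in the tests).

Numerical and design choices:

* The default P-to-score convention is one-sided ($z = \Phi^{-1}(1-p)$,
  back-transform $1 - \Phi$). When effects of both signs matter, pass
  `two_sided = TRUE` to square the transformed scores and use the 1-df
  chi-square survival; the simulation harness uses the two-sided
  convention throughout, consistent with squaring association statistics.
* Eigenvalues below $10^{-10}$ of the largest are floored with a warning
  (near-singular LD matrices reconstructed from haplotype frequencies are
  common); `strict = TRUE` turns the floor into an error. After flooring,
  $H^{\top}\Sigma H = I$ holds only approximately, which the result
  records.
* $\Sigma$ is treated as known. Propagating the sampling uncertainty of an
  estimated correlation matrix is out of scope here.

`ld_correlation_from_haplotypes()` reconstructs the LD correlation matrix
from a haplotype frequency table: with $p_i$ the minor-allele frequency
(sum of frequencies of haplotypes carrying the minor allele at locus $i$)
and $P_{ij}$ the di-locus frequency, $D_{ij} = P_{ij} - p_i p_j$ and
$r_{ij} = D_{ij} / \sqrt{p_i(1-p_i)p_j(1-p_j)}$. Monomorphic loci are an
error (named by index); the output is symmetric, bounded in $[-1, 1]$ and
PSD up to numerical tolerance.

## The simulation harness and what it emulates

`simulation_design()` fixes one cell of a study: $L$ statistics
$z \sim \mathrm{MVN}(\mu, \Sigma)$ converted to P-values (two-sided by
default). Effect models: none, constant $\mu$, per-test uniform
$\mu_i \sim U(\mu_{lo}, \mu_{hi})$ redrawn each replicate, or sparse (a
fraction $\pi$ of tests at $\mu$). Correlation models: identity,
equicorrelation $\rho \in (-1/(L-1), 1)$, or a random factor model
($\Sigma \propto WW^\top + \epsilon I$ rescaled to unit diagonal, with the
factor count stepped so the realised mean $|\rho|$ can be shrunk exactly
onto a target; the realised value is recorded). One matrix is realised
per design. Every replicate draws from its own stream derived from
`(seed, replicate)`, so any cell of any table can be regenerated in
isolation with `gen_pvalues()`.

This generator emulates the standard "many weak signals" setting:
Gaussian statistics with known correlation and homogeneous noise. It does
not emulate discreteness of small-sample P-values, heavy-tailed or
misspecified marginal statistics, or LD estimated with error -- passing
calibration here says nothing about those complications on real data.

`estimate_rate()` applies a method to all replicates (vectorised over the
sorted columns it actually needs) and returns the rejection fraction with
its binomial standard error. `reproduce_table()` reruns a packaged
reference grid at `scale` times the reference replicate count
($10^5$) and flags cells deviating by more than 3 combined standard
errors; it refuses scales so small that the Monte-Carlo standard error
would exceed 0.05. Resampling comparators for correlated designs
(`rtp_resampling`, and the adaptive analogue) refer the observed truncated
product to a bank of null statistics drawn under the design's $\Sigma$,
mirroring permutation procedures that preserve LD.

**Problem sizes.** The packaged checks use $B = 20{,}000$ null replicates
per type-I cell and $B = 10{,}000$ per power cell -- enough for a binomial
standard error of about $0.0015$ at $\alpha = 0.05$ and about $0.005$ on a
power of one half, which resolves every comparison the tests make.

## Design decisions that were genuinely open

* **Simes multiplier.** The Simes statistic is implemented as
  $\min_i L\,P_{(i)}/i$ with the total number of tests as multiplier --
  the standard definition, consistent with its equivalence to the
  Benjamini–Hochberg step-up and with the Šidák/Bonferroni benchmarks.
* **Sidedness.** Power and type-I surfaces use two-sided P-values by
  default. Under this convention the constant-effect power surface
  reproduces the reference values closely (see `reproduce_table("T4")`),
  which fixes the convention; one-sided remains available per design.
* **Uniform-effect surface.** With effects drawn per test per replicate
  from $U(0.05, 0.45)$ and two-sided P-values -- the design as stated --
  the re-estimated powers are materially lower than the corresponding
  reference cells (`reproduce_table("T5")` flags them), and the one-sided
  alternative overshoots them. The reference cells behave like a constant
  effective effect near $0.42$–$0.44$. The generator keeps the stated
  design rather than tuning toward the reference values; the discrepancy
  is documented rather than hidden.
* **Sparse-effect surface.** The packaged sparse design uses $\mu = 1.4$
  for the non-null fraction, following the tabulated description of that
  surface; its source states two conflicting effect sizes, so these cells
  are indicative and are not part of the acceptance checks.
* **ART-A adjustment.** Exact-representation Monte-Carlo by default, MVN
  model as an option, as discussed above.
* **Correlated-table $\Sigma$.** Random-factor matrices are realised once
  per design cell with the reference mean $|\rho|$ as target. Under
  heterogeneous effects (uniform on $[-0.45, 1.3]$) the decorrelation
  route gains substantially over the resampling comparator and the gain
  grows with $L$, whereas under pure equicorrelation the gain at small
  $L$ is modest; the qualitative power-growth checks therefore use the
  random-factor model, and the equicorrelated model is used for the
  type-I calibration of the decorrelation pipeline.

## Known limitations

* The legacy closed form is a cross-check, not a production path, and is
  unreliable past $L \approx 25$.
* Fixed-order quadrature guarantees *absolute* accuracy ($10^{-9}$); the
  relative accuracy of extreme tail values below about $10^{-7}$ degrades
  (a few percent at $10^{-25}$). Methods compared at conventional levels
  are unaffected.
* The empirical aRTP shares one null reference matrix across calls at the
  same seed; its granularity limits meaningful adjusted P-values to about
  $1/B$.
* Decorrelation assumes the correlation matrix is known and the
  statistics are Gaussian; LD matrices from haplotype frequencies may
  differ slightly from genotype correlations.
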