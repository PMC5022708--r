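---
title: "Models and methods for trait covariance matrix analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for trait covariance matrix analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantmat)
```

## The object of study

Multivariate evolution is governed, to first order, by the Lande
equation $\Delta \bar z = G\beta$: the change in trait means is the
product of the additive genetic covariance matrix $G$ and the
directional selection gradient $\beta$. Everything in this package
operates on $p \times p$ trait covariance or correlation matrices —
$G$, its phenotypic proxy $P$, pooled within-group matrices $W$,
between-group matrices $B$ — represented as labelled `trait_matrix`
objects with a declared role. Symmetry is enforced on construction
(asymmetry up to $10^{-8}$, the scale of CSV round-trip noise, is
repaired by averaging; anything larger is treated as a data error and
refused), correlation matrices are forced to an exactly unit diagonal,
and covariance matrices must be positive semi-definite within
$10^{-10}\,\mathrm{tr}$.

Two package-wide conventions deserve a note. First, every eigenvector
reported anywhere has its largest-magnitude entry positive; without a
sign convention, statistics built on cosines against principal
components would be irreproducible across BLAS implementations.
Second, every stochastic function takes an explicit `seed` and runs
under a local RNG scope (the caller's RNG state is never touched);
equal seeds give bit-identical results.

## Estimation and measurement error

`calculate_matrix()` estimates a covariance matrix as the residual
cross-product of per-trait least-squares fits on a shared fixed-effects
design, divided by $n - \mathrm{rank}(X)$. With no factors this is
exactly the $n-1$ sample covariance; with factors it is the pooled
within-group (MANCOVA residual) matrix, removing nuisance mean
structure such as sexual dimorphism. Mixed and animal models are out of
scope; matrices estimated elsewhere can be read in and used directly.

`bayesian_calculate_matrix()` adds a conjugate inverse-Wishart
shrinkage estimate. The prior scale is $\Lambda_0 = \nu_0\,
\mathrm{diag}(s^2_1, \dots, s^2_p)$ — observed variances on the
diagonal, zeros elsewhere — so correlations are shrunk toward zero
while the variance scale is data-driven. The posterior is
IW$(\nu_0 + n,\ \Lambda_0 + S)$ and the reported point estimate is the
posterior mode $\Lambda_n / (\nu_n + p + 1)$. Two quantities are left
open by the estimator's usual presentations and were fixed as design
choices: the default prior degrees of freedom is $\nu_0 = p + 2$, the
weakest proper prior with a finite mean, and the prior scale is
multiplied by $\nu_0$ so that the prior's implied variance targets stay
at the observed variances regardless of $\nu_0$. Passing a numeric
$\nu_0 \le p - 1$ is permitted for exploration but flagged as an
improper-prior regime. Posterior draws are generated by Wishart
sampling on the inverse scale (`stats::rWishart`), guaranteeing
symmetric positive-definite draws.

`calc_repeatability()` quantifies measurement error from repeated
measurements: a one-way ANOVA per trait with individual as the factor,
variance components $s^2_W = MS_W$ and $s^2_A = (MS_A - MS_W)/n_0$
with the standard unbalanced-design correction
$n_0 = (N - \sum n_i^2/N)/(a-1)$, and repeatability
$r = s^2_A / (s^2_A + s^2_W)$. Negative among-individual components are
clamped to zero — the standard ANOVA convention — so $r$ lands in
$[0, 1]$ and $r = 1$ means measurement error contributes nothing.

## Matrix error and repeatability corrections

Estimated matrices always carry sampling error, so even two matrices
sampled from the same population correlate below 1. The package
estimates that ceiling — the matrix repeatability — three ways:
nonparametric bootstrap over individuals (`bootstrap_rep()`),
parametric Monte Carlo from the fitted matrix (`monte_carlo_rep()`),
and the analytic expression for correlation matrices (`alpha_rep()`,
$\alpha = (\sigma^2_r - \varepsilon^2)/\sigma^2_r$ with
$\varepsilon^2 = (1-\bar{r^2})^2/(n-2)$), which is asymptotic and
should only be trusted when $n$ comfortably exceeds $p$. Observed
between-matrix correlations are corrected by dividing by the geometric
mean of the two repeatabilities (`corrected_correlation()`); noisy
repeatabilities can push the ratio past 1, in which case it is capped
at 1 and the cap reported. Both resampling repeatabilities default to
1000 iterations — enough that their own Monte-Carlo error is well below
the sampling error they measure at desk scale.

`extend_matrix()` addresses a different error pathology: the smallest
eigenvalues of an estimated covariance matrix are badly attenuated,
which wrecks anything touching the inverse. Extension replaces the
eigenvalues below a retained rank $k^*$ by $\lambda_{k^*}$. The
retained rank is an explicit parameter; a heuristic (`retained_rank =
NULL`) picks the first $k$ where the relative spectral drop
$(\lambda_k - \lambda_{k+1})/\lambda_1$ falls below $10^{-4}$, but the
explicit parameter is canonical because no published threshold rule
exists.

## Selection-response statistics

`skewer_stats()` estimates the Hansen–Houle statistics as Monte-Carlo
means over random selection gradients drawn uniformly on the unit
sphere: evolvability $\bar e = E[\beta' G \beta]$, respondability
$E[\lVert G\beta\rVert]$, flexibility $E[\cos(G\beta, \beta)]$,
conditional evolvability $E[(\beta' G^{-1} \beta)^{-1}]$, autonomy,
and the constraints statistic $E[\,\lvert\cos(G\beta,
\Lambda_1)\rvert\,]$. Three numerical decisions:

* autonomy is computed as the draw-wise ratio $c(\beta)/e(\beta)$ on
  paired draws, which is identical to the joint-expectation form
  evaluated draw-wise and makes the identity $\bar a \cdot e = c$ exact
  per draw;
* constraints uses the absolute cosine, because the sign of a leading
  eigenvector is arbitrary — a signed mean would be sign-convention
  noise;
* the integration measure ICV uses the sample ($n-1$) standard
  deviation of the eigenvalues; the divisor is unstated in the
  literature the statistic comes from and the sample convention is the
  one `stats::sd` users expect.

Each statistic carries its Monte-Carlo standard error; the default
1000 gradients put that error near 1% for well-conditioned matrices,
and the closed form $\bar e = \mathrm{tr}(G)/p$ provides a free
cross-check used throughout the tests.

## Matrix comparison

Four correlations and two distances. Random skewers
(`random_skewers()`) compares the responses $A\beta$ and $B\beta$ to
shared random gradients by their mean cosine; significance uses the
empirical null of cosines between independent random unit vectors in
the same dimension — preferred over random-matrix nulls because
realistic random covariance matrices are themselves hard to generate.
`mantel_cor()` is the element-wise Pearson correlation of the lower
triangles with a joint row/column permutation test, restricted to
correlation matrices (covariances of different scales inflate the
statistic through the variances alone, so covariance input is an
error, not a warning). The identity relabelling is excluded from the
permutation draws: it reproduces the observed statistic exactly, and
with small $p$ it would otherwise tie the self-comparison p-value
above its nominal $1/(B+1)$. The add-one convention keeps p-values
strictly positive. `krz_cor()` measures the overlap of leading
principal subspaces with default size $k = \lfloor p/2 \rfloor - 1$
(at least 1) — the printed formula in the source literature is
typeset ambiguously, so the size is an exposed parameter.
`pca_similarity()` weights every squared cosine by the associated
eigenvalue pair and normalizes by $\sum_i \lambda^A_i \lambda^B_i$
over descending-sorted pairs, the unique normalization that makes
self-similarity exactly 1.

The overlap distance treats two covariance matrices as zero-mean
Gaussian densities and estimates the misclassification probability
$q(f,g) = E_f[g/(f+g)]$ by plain Monte Carlo (default $10^4$ draws per
direction, symmetrized over both directions), then
$d = \sqrt{1 - 2q}$. The Riemannian (affine-invariant) distance is
$\sqrt{\sum_i \log^2 \lambda_i(A^{-1}B)}$, invariant under any change
of basis. `compare_all()` drives all-pairs tables, placing raw values
in the lower triangle and repeatability-corrected values and
repeatabilities in the upper triangle and diagonal when supplied.

## Decomposition on the SPD manifold

SPD matrices form a curved space; averaging and PCA must respect it.
`mean_matrix()` computes the Fréchet (geometric) mean by the standard
fixed-point iteration
$M \leftarrow M^{1/2} \exp\!\big(\tfrac1n \sum_i \log(M^{-1/2} X_i
M^{-1/2})\big) M^{1/2}$, initialized at the arithmetic mean (always
SPD) and stopped when the Frobenius norm of the mean log term — the
Riemannian gradient — reaches `tol` ($10^{-10}$ by default), so the
stationarity condition holds to the same order at convergence.

`eigentensor_decomposition()` maps each sample member to the tangent
space at $M$ via $f(X) = \log(M^{-1/2} X M^{-1/2})$, vectorizes the
symmetric images with off-diagonal entries scaled by $\sqrt 2$ — the
scaling under which the Euclidean inner product of the vectors equals
the Frobenius inner product of the matrices, which is what makes the
resulting eigentensors Frobenius-orthonormal — and eigendecomposes the
sample covariance of those vectors. `project_matrix()` and
`revert_matrix()` move between matrices and score vectors; the
exponential map guarantees SPD output for any finite scores. All
$p(p+1)/2$ eigentensors are computed; how many to interpret is left to
the user, since no principled truncation rule exists for this
decomposition. The tailored null-distribution hypothesis test that can
be layered on posterior samples is out of scope.

`srd()` decomposes the response to selection trait by trait: for each
random gradient, trait $i$'s response row $(A_{ij}\beta_j)_j$ under the
two matrices is compared by Pearson correlation, and the per-trait mean
and SD over gradients localize which traits drive a difference between
matrices. The flagging rule (centered mean score below zero) is a
reporting convenience; the raw scores are the result.

`rs_projection()` compares posterior samples of matrices direction by
direction: for each random unit $\beta$, the posterior of
$\beta' G \beta$ per population, flagging directions whose equal-tailed
credible intervals (default 95%) fail to overlap. Equal-tailed
intervals were chosen over HPD: they are deterministic, quantile-based
and reproducible, at a small cost in interval length.

## Modularity

`test_modularity()` scores a priori modularity hypotheses: Mantel
correlation of the binary same-module matrix with the observed
correlation matrix, the within/between means AVG+ and AVG−, their
ratio, and the Modularity Hypothesis Index $(AVG^+ - AVG^-)/ICV$
(usable when correlations differ in sign, unlike the ratio); the ICV
here is computed from the correlation matrix itself. A union
"full model" hypothesis is appended, and contrast-free hypotheses are
skipped with a note.

`l_modularity()` searches for modules without prior information by
maximizing a Newman-type modularity on the fully connected weighted
graph whose edge weights are $|r_{ij}|$. Negative correlations enter by
absolute value — a weighted graph needs nonnegative weights, and the
literature is silent on signed variants; when that policy is
undesirable, remove the size factor first (`remove_size()`) or set
`allow_negative = FALSE` to be refused explicitly. The null term is
Newman's $k_i k_j / 2m$ with $m$ the total edge weight (half the sum of
strengths) and self-pairs retained in the null sum; this is the
bookkeeping under which the single-module partition scores exactly
zero, so any positive $L$ is structure beyond the strength-product
null. The greedy optimizer (agglomerative merges plus single-trait
relocation, 20 seeded restarts) is validated against exhaustive
enumeration of set partitions, which is exposed for $p \le 12$
(enumerating 4140 partitions at $p = 8$ is instant; Bell numbers make
$p > 12$ impractical).

`remove_size()` projects out the direction of the first principal
component: residual $= m - (mv)(mv)'/(v'mv)$, leaving a PSD matrix of
rank $p-1$ with exactly zero variance along $v$, plus the normalized
size vector so the rank-1 component reconstructs the input. A warning
fires when PC1's entries are not predominantly one sign, since then
"size" is a questionable reading of the removed factor.

## Drift tests

Under pure drift the between-taxon covariance is proportional to the
within-group matrix, $B \propto (t/N_e) W$. `drift_test()` regresses
$\log B_i$ on $\log \lambda_i^W$ over the principal components of $W$
and tests the slope against 1 with a 95% t interval. Components with
$\lambda_i / \lambda_1$ below $10^{-8}$ are dropped before taking logs
(they are numerical zeros); the cutoff is exposed. The taxa/trait
guideline from the comparative literature (at least ~20 traits, ~8
taxa) is enforced as a warning, not an error. The verdict wording is
deliberate: failing to reject drift is compatibility, not evidence
against selection.

`multiv_drift_test()` covers the two-population case: simulate derived
means from $N(z_0, (t/N_e)W + \mathrm{diag}(se^2))$ — the diagonal
term carries the standard errors of the observed derived means — and
compare the observed divergence norm against the simulated null with an
add-one p-value. The drift scale $t/N_e$ is not identifiable from two
populations and must be supplied. `pc_score_correlation()` tests all
pairs of PC score vectors for correlation (under drift they are
uncorrelated; correlation indicates correlated directional selection),
with Bonferroni control at level $\alpha$ over the pairs actually
tested — conservative, but the natural default when the test count is
small and the claim per pair is qualitative.

## Phylogenetically structured pooling

`phylo_w()` assigns every internal node of a rooted tree the
sample-size-weighted mean of its children's matrices by post-order
traversal; the root is the global weighted mean regardless of topology
(weighted-mean associativity, asserted in the tests). Branch lengths
are deliberately ignored — the pooling is a MANCOVA-style estimator,
not a Brownian-motion reconstruction — and a warning says so whenever
the tree carries lengths. Per-element maximum-likelihood ancestral
reconstruction is out of scope because it does not preserve positive
definiteness. For G-matrices there is no obviously correct weight
(sample size? family count?), so weights are always user-supplied.
`phylo_compare()` then compares sister lineages at every internal
node, handling multifurcations as all child pairs with a note.

## Synthetic data

The generators exist so that every analysis in the package can be
exercised without external data, and they define the conditions under
which the package validates itself:

* `random_spd_matrix()` — random orthogonal basis, log-uniform
  eigenvalues in $[0.5, 4]$ by default, or an explicit spectrum.
* `size_spectrum()` — the spectrum typical of morphological covariance
  matrices: a dominant leading eigenvalue (the size axis, roughly half
  the total variance, default $\lambda_1 = 50$ against a geometric
  tail from 4 down to 0.25). The drift calibrations use this spectrum
  because it is the regime the drift regression is designed for: with
  a flat, nearly degenerate spectrum the log-eigenvalue axis has no
  leverage structure and a selection signal confined to PC1 inflates
  the regression's residual variance in step with its slope estimate,
  capping the rejection probability well below 1 no matter how strong
  selection is. That is a property of OLS on a leverage-free design,
  not of the biology the test targets.
* `random_matrix()` — random correlation matrices at a requested
  integration level (mean squared correlation), built from an
  exponentially decaying spectrum with accept/reject tuning. The
  construction is a pragmatic stand-in for published
  random-correlation-matrix algorithms whose internals are not
  reproduced here; outputs are labelled for informal tests and are not
  a calibrated null model of biological covariance.
* `simulate_population()` / `simulate_radiation()` — MVN individuals
  (with optional replicate-level measurement error, the input
  `calc_repeatability()` expects) and MVN taxon means under
  $B = (t/N_e)W$, with an optional deterministic displacement along a
  selection vector (taxon $i$ displaced by $s\, i/n$), which models
  correlated directional selection and gives the drift tests something
  to reject.

What the generators do *not* emulate: non-Gaussian trait
distributions, phylogenetic autocorrelation of taxon means, missing
data, and estimation-induced correlation between $W$ and the means.
Passing tests therefore demonstrate correctness of the algorithms
under the stated models, not robustness to real-data pathologies.

## Problem sizes and numerical tolerances

The validation suite runs at desk scale, chosen so each check is
decisive yet quick: identity checks over 20 random matrices at
$p = 3{-}12$; Monte-Carlo closed-form checks at $10^4$–$10^5$
gradients (standard errors well below the asserted 3-SE bands);
drift calibrations over 100 seeded radiations of 20 taxa by 20
traits; Mantel null calibration over 500 replicates of 199
permutations; module recovery over 20 jittered planted matrices
checked against exhaustive enumeration. Exact identities (self
comparisons, round trips, closed forms) are asserted at
$10^{-8}$–$10^{-12}$; Monte-Carlo quantities at 3 standard errors of
their own estimate.

## Known limitations

Mixed/animal-model G estimation, shrinkage estimators beyond the
inverse-Wishart posterior, Flury common-principal-component
hierarchies, signed modularity, HPD intervals, branch-length-aware
ancestral matrices and the tailored eigentensor hypothesis test are
all deliberately absent — either out of scope or deferred to
specialist tools. The alpha repeatability expression is asymptotic and
unreliable for $n \lesssim p$ (warned). L-modularity's
absolute-value policy for negative correlations is a documented
convention, not a claim about the original intent of the statistic.
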