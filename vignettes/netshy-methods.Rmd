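---
title: "Laplacian-weighted module summarization: model, benchmark and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laplacian-weighted module summarization: model, benchmark and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netshy)
```

This vignette is the package's account of its science: the summarization
model, the generative benchmark, the evaluation conventions, the choices we
made where the design was genuinely open, and what the passing tests do and
do not establish.

## 1. The summarization model

A module is a weighted, non-negative, undirected graph on `p` labelled
nodes, stored as a symmetric adjacency matrix $A$ with zero diagonal
(self-loops are excluded by construction). Its graph Laplacian is
$L = D - A$ with $D_{kk} = \sum_l a_{kl}$ the weighted degrees; $L$ is
positive semidefinite, its rows and columns sum to zero, and the
multiplicity of its zero eigenvalue counts connected components.

Given an $n \times p$ profile matrix $X$ (subjects by nodes, no missing
values, columns aligned to the network's node order), three subject-level
summaries are provided:

* **nonet** (eigengene): first principal component of $X$. Columns are
  mean-centered, never variance-scaled; scaling would change the estimand,
  and the benchmark's simulated features share a scale by construction.
* **netshy**: first principal component of $X^{*} = X L$, centered the same
  way. Multiplying by $L$ does two things: it annihilates per-subject
  constant offsets exactly (columns of $L$ sum to zero), and it re-weights
  directions of feature space by how strongly they contrast connected
  neighbourhoods, which amplifies topology-consistent signal relative to
  isotropic measurement noise.
* **hub**: the profile of the most highly connected node, the classical
  single-node baseline. Degree ties break to the lowest node index, a fixed
  documented convention.

The decomposition is an SVD of the centered matrix rather than an
eigensolve of the covariance, so the contract is unchanged when $n < p$.
Principal components have a sign ambiguity; we fix it by making the loading
entry of largest absolute value positive. Association results are reported
as absolute correlations, so the convention is cosmetic. Centering happens
*after* forming $X^{*}$ (centering $X$ first and then multiplying would give
the same scores, since right-multiplication commutes with column centering
of the subject dimension, but the stored centering vector refers to the
$X^{*}$ columns).

Scores destined for regression-type downstream analyses can be passed
through `inverse_normal_transform()`, the rank-based map
$z_i \mapsto \Phi^{-1}\!\big((r_i - c)/(n - 2c + 1)\big)$ with Blom's offset
$c = 3/8$ (configurable) and average ranks for ties.

## 2. The generative benchmark

`simulate_scenario1()` builds one dataset from five ingredients, each with
its own sub-seed derived from the master seed (a string-hash of the
component name folded with the seed, so streams are distinct and every run
is bit-reproducible):

1. **Network**: a $G(p, \alpha_0)$ Erdős–Rényi graph — every unordered pair
   is an edge independently with probability $\alpha_0$ — with edge weights
   drawn $\mathrm{Unif}(0.1, 0.8)$. The generator does not condition on
   connectivity; isolated nodes are legitimate draws.
2. **Precision**: in a Gaussian graphical model the adjacency plays the role
   of the precision matrix, whose off-diagonal zeros encode conditional
   independence. A raw adjacency is indefinite, so it is diagonally loaded,
   $\Omega = A + (\max(0, -\lambda_{\min}(A)) + \delta) I$ — the loading
   preserves the zero pattern exactly — and the covariance is
   $\Sigma = \mathrm{cov2cor}(\Omega^{-1})$, rescaled to unit diagonal so
   all features share a scale. This is the standard construction used by
   GGM simulators.
3. **True profiles**: $X_0 \sim N(0, \Sigma)$, $n$ independent subjects.
4. **Phenotype**: $Y_0 = \beta_0 + X_0 \beta + \varepsilon$ with
   $\beta_k$ = weighted degree of node $k$ (highly connected nodes drive the
   phenotype), $\beta_0 \sim N(0,1)$ drawn once per dataset, and
   $\varepsilon_i \sim N(0, \sigma_\varepsilon^2)$.
5. **Measurement noise**: $X = X_0 + E$, $e_{ij} \sim N(0, \sigma_e^2)$
   i.i.d.

`simulate_scenario2_like()` runs the same pipeline on a *supplied* network
(optionally hard-thresholded to a target sparsity first), emulating the case
where the module comes from an empirical multi-omics network.
`synthetic_mp_network()` provides a synthetic 20-node stand-in with a
metabolite-like and a protein-like block at realized sparsity ≈ 0.51; it is
a fixture for exercising that code path, not a reconstruction of any
published module's weights.

What the generator emulates: a module whose conditional-dependence structure
*is* the network, a phenotype aligned with connectivity, and observation
through a noisy instrument. What it does not emulate: heteroscedastic or
correlated measurement error, non-Gaussian marginals, covariate structure
(batch, demographics), or the mismatch between a globally estimated network
and the local correlation of the module's own features beyond the additive
noise device. Conclusions from passing tests therefore speak to the model
above, not to any particular cohort.

## 3. Evaluation criteria and the ratio convention

With a dataset in hand, each method's score vector $Z$ and loading $\phi$
are scored by

* $\rho = |\mathrm{corr}(Z, Y_0)|$, and
* $\mathrm{PVE} = \lVert X_0^{c}\phi\rVert^2 / \lVert X_0^{c}\rVert_F^2$,
  computed on the column-centered *true* matrix $X_0$ regardless of where
  the loading came from — the criterion deliberately asks how much of the
  noise-free signal a loading retains.

Both are compared to the optimal baseline: the first PC of $X_0$ itself,
whose PVE is the variational maximum. Ratios near 1 are best; PVE ratios
cannot exceed 1, correlation ratios can in principle (sampling noise folded
by the absolute value), though in the benchmark's operating range they stay
below it.

**Ratio of means, not mean of ratios.** The subsampling study
(`subsample_study()`) draws subject subsets without replacement, recomputes
every method *and* the optimal baseline on each subset, and then reports,
per size, `mean(rho) / mean(rho_opt)` and `mean(pve) / mean(pve_opt)` over
the iterations (the spread column is `sd(raw) / mean(opt)`, the raw sd on
the ratio scale). The alternative — averaging per-subset ratios — is
unstable here: the optimal correlation on a 50-subject subset can be
arbitrarily close to zero, and a ratio with a near-zero denominator has no
useful mean. The same principle governs how `run_benchmark()` pools
replicate master datasets: raw criteria are pooled across replicates first
(law of total variance for the sds) and ratios rebuilt from the pooled
means, so no single master with a weak optimal correlation can dominate a
cell. At the full master size the study reports a single-shot row
(`iterations = 1`, `sd = 0`).

`real_data_robustness()` is the same engine for observed data: with no
noise-free $X_0$, neither PVE nor the optimal baseline exists, so it reports
raw $|\mathrm{corr}(Z, Y)|$ per method and size, and robustness is judged by
dropping rates (`dropping_rate()`).

`bootstrap_correlation_difference()` compares two methods' phenotype
correlations by resampling subjects with replacement, recomputing both
scores per resample, and forming
$\Delta_b = |\rho^{(1)}_b| - |\rho^{(2)}_b|$; the two-sided p-value is
$2\min(\hat F(\Delta \le 0), \hat F(\Delta \ge 0))$, floored at $1/B$ and
capped at 1. Degenerate resamples (constant phenotype or profiles) are
redrawn and counted.

## 4. Calibrated operating point

The generative model leaves three scales unpinned: $\sigma_\varepsilon$,
$\sigma_e$ and the loading constant $\delta$. The packaged benchmark fixes
them once, by least squares against the reference size-50 criterion ratios
of the sparse cell ($p = 30$, $\alpha_0 = 0.3$) only, and freezes the result
for every other cell:

```{r}
benchmark_noise()
```

Notes on each:

* $\sigma_e = 2.5$ — with unit-variance features this is a low
  signal-to-noise regime; it is what separates the methods at small $n$.
* $\sigma_\varepsilon = 1$ — the phenotype's linear signal variance
  ($\beta^\top \Sigma \beta$, order $10^1$–$10^2$ at these sizes) dwarfs any
  plausible $\sigma_\varepsilon$, so this scale has essentially no leverage
  on the ratios and stays at its generic default.
* $\delta = 0.04$ — $\delta$ sets the top of $\Sigma$'s spectrum
  ($\lambda_{\max} \approx$ the reciprocal of the smallest loaded
  eigenvalue) and hence the eigengap that both estimators race against; the
  positive-definiteness step is the least-determined part of the model, so
  $\delta$ belongs to the calibrated triple rather than being fixed a
  priori.

`sim_config()` keeps neutral defaults ($\sigma_\varepsilon = \sigma_e = 1$,
$\delta = 0.1$) for free exploration; `run_benchmark()` and the acceptance
script use the calibrated triple via `benchmark_noise()`.

## 5. What the benchmark shows — and a structural caveat

At the calibrated operating point, the size-50 subsampling ratios of the
two reference cells ($\alpha_0 = 0.3$ and $0.9$ at $p = 30$) and their
orderings are reproduced by `tests/testthat/test-acceptance.R`, and
`scripts/acceptance.R` recomputes the dense-cell PVE ratios from scratch.
Two structural findings from building the benchmark deserve emphasis:

* **The topology advantage is a small-sample phenomenon under this noise
  model.** Because the measurement error is i.i.d. and homoscedastic,
  $\mathrm{cov}(X) = \Sigma + \sigma_e^2 I$ shares eigenvectors with
  $\Sigma$: as $n$ grows the plain first PC converges to the optimal
  direction, while the Laplacian reweighting carries a small population
  bias. The crossover sits around subset sizes of a few hundred at these
  settings; below it, NetSHy's better-conditioned spectrum wins clearly on
  PVE. Claims that the topology-aware summary dominates at *every* sample
  size are not reproducible under this noise model and are not asserted.
* **The bootstrap comparison is conservative at the null.** When the
  phenotype is independent of the profiles, both correlations sit at the
  non-differentiable fold of $|\cdot|$, where the percentile bootstrap is
  inconsistent: measured p-values are right-shifted (no spurious
  significance, but far from uniform). The test is trustworthy in the
  regime it is meant for — comparing two clearly nonzero correlations — and
  should be read as conservative, not exact, near zero.

## 6. Numerical conventions and degenerate inputs

* Adjacency symmetry is validated to `1e-10` and then exactly symmetrized by
  averaging; negative weights and non-square matrices are errors; nonzero
  diagonals are zeroed with a warning.
* Sparsity counts strictly positive weights; no nonzero tolerance is
  applied.
* Positive-semidefiniteness checks use a `1e-8` eigenvalue slack (standard
  double-precision headroom).
* Constant matrices (zero total variance after centering), empty networks
  (zero Laplacian), all-tied vectors for the inverse-normal transform, and
  constant inputs to correlations raise typed errors (`netshy_degenerate_*`,
  `netshy_no_hub`, `netshy_alignment_error`) rather than returning NaNs.
* Subsampling schedules must be strictly decreasing and below the master
  size; subsampling is without replacement, the bootstrap with replacement.
* Text writers emit 17-significant-digit decimals and readers parse with
  strtod, so dataset bundles round-trip doubles exactly.
* All stochastic entry points either accept an explicit `seed` (restoring
  the caller's RNG state afterwards) or derive named sub-seeds from a master
  seed.

## 7. Problem sizes used by the shipped checks

The test suite exercises the reference cells at 24 replicate masters ×
250 subsample iterations per size (schedule 500, 300, 200, 100, 50 from
$n = 1000$ masters), the engine-correctness checks at $n = 10^4$, and the
bootstrap calibration at 200 seeds × $B = 200$; the acceptance script uses
16 replicate masters × 1000 iterations at size 50. These sizes keep each
quantity's Monte Carlo error a fraction of the tolerances being asserted
while the whole suite stays in the minutes range on one CPU; the protocol
itself (master size, schedule, without-replacement subsampling) is fixed by
the study design, not by these counts.

## 8. Known limitations

* Only the first principal component is validated as a summary;
  `n_components > 1` is exposed for exploration, not endorsed.
* The loading constant $\delta$ stands in for an unspecified
  positive-definiteness step; other constructions (e.g. diagonal dominance
  scaling) would change the spectrum and with it the quantitative — though
  not the qualitative small-sample — conclusions.
* The correlation-ratio criterion is a folded, ratio-type statistic; its
  per-subset version is heavy-tailed, which is why the package fixes the
  ratio-of-means convention throughout. Comparisons across publications
  that averaged per-subset ratios are not like-for-like.
* Real-cohort results (observed multi-omic modules with external
  phenotypes and genotypes) require data this package does not ship;
  `real_data_robustness()` implements the protocol, nothing more.
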