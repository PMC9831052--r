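# netshy

Topology-aware, subject-level summarization of biological network modules.

## The problem

Biological networks — co-expression, protein–protein, multi-omic modules —
are usually analysed module by module: a highly interconnected subset of `p`
nodes is reduced to a single value per subject, and that summary is related
to a phenotype downstream. The conventional summary is the *eigengene*: the
first principal component of the `n × p` profile matrix `X`. It maximizes
explained variance but is blind to the module's wiring. The other common
baseline, the *hub profile*, keeps only the most connected node and discards
everyone else.

**NetSHy** is a hybrid: it folds the module topology into the decomposition.
With `A` the symmetric, non-negative adjacency of the module and

```
L = D − A,          D_kk = Σ_l a_kl        (graph Laplacian)
X* = X L
```

the NetSHy score `Z` is the first principal component of the column-centered
`X*`, and the loading `φ` (unit vector, one entry per node) stores each
node's contribution. Because the columns of `L` sum to zero, any per-subject
constant offset of all features cancels exactly, and directions consistent
with the connectivity structure are amplified relative to isotropic
measurement noise. This package implements the summarizers (`netshy`,
`nonet`, `hub`), the rank-based inverse-normal transform used before
regression-based downstream analyses, and the full simulation benchmark that
quantifies when topology helps.

The benchmark simulates from a Gaussian graphical model seeded by the
network: `A` (diagonally loaded to be positive definite) acts as the
precision matrix, true profiles are drawn `X0 ~ N(0, Σ)`, the phenotype is
degree-weighted, `Y0 = β0 + X0 β + ε` with `β` the weighted node degrees, and
the observed profiles are `X = X0 + E` with i.i.d. Gaussian measurement
noise. Methods are scored by

- `ρ = |corr(Z, Y0)|`, the recovered phenotype association, and
- `PVE = ‖X0 φ‖² / ‖X0‖²`, the share of *true* variance the loading retains,

each relative to the optimal baseline computed from the noise-free `X0`
(ratios near 1 are best). A subsampling protocol (1000 random subsets without
replacement at sizes 500…50 from an `n = 1000` master) probes robustness, and
a subject-level bootstrap compares two methods' phenotype correlations.

## Worked example

```r
library(netshy)

# a weighted random module: 30 nodes, edge probability 0.3, Unif(0.1, 0.8) weights
net <- er_network(p = 30, alpha0 = 0.3, seed = 7)
net
#> <module_network> 30 nodes, 146 edges, sparsity 0.336

# a full benchmark dataset built on that topology
sim <- simulate_scenario1(sim_config(p = 30, alpha0 = 0.3, n_master = 1000,
                                     sigma_e = 2.5, pd_delta = 0.04, seed = 7))

# topology-aware summary of the observed (noisy) profiles
s <- summarize_netshy(sim$X, sim$net)
s
#> <module_summary: netshy> 1000 subjects, 30 features, PVE on input 0.209
head(augment(s), 3)       # one score per subject
#>   subject_id score
#> 1 S1          54.6
#> 2 S2         -12.6
#> 3 S3          28.8

# both criteria against the optimal baseline from the noise-free profiles
evaluate_summaries(sim, methods = c("netshy", "nonet", "hub"))
#>   method   rho    pve rho_opt pve_opt rho_ratio pve_ratio
#> 1 netshy 0.196  0.296   0.189   0.365     1.04      0.810
#> 2 nonet  0.168  0.355   0.189   0.365     0.890     0.971
#> 3 hub    0.145 NA       0.189   0.365     0.766    NA
```

At the full sample size the plain PC keeps slightly more true variance. The
topology advantage appears when subjects get scarce — the regime the
subsampling study probes:

```r
st <- subsample_study(sim, sizes = c(500, 300, 200, 100, 50),
                      iterations = 200, seed = 8)
dplyr::filter(st, size == 50, metric %in% c("rho_ratio", "pve_ratio"))
#>    size method metric     mean    sd iterations
#> 1    50 netshy rho_ratio 1.01  0.583        200
#> 2    50 netshy pve_ratio 0.717 0.130        200
#> 3    50 nonet  rho_ratio 0.840 0.552        200
#> 4    50 nonet  pve_ratio 0.551 0.221        200
autoplot(st)   # mean ± sd trajectories across the schedule
```

At 50 subjects NetSHy's loading still captures 72% of the attainable true
variance while the eigengene drops to 55%. Supporting tools:

```r
# bootstrap comparison of the two phenotype correlations (subjects resampled)
glance(bootstrap_correlation_difference(sim$X, sim$net, sim$y0, B = 500, seed = 9))
#>   method_1 method_2 observed p_value     B n_redrawn
#> 1 netshy   nonet      0.0281   0.024   500         0

# rank-based inverse-normal transform before downstream regression
head(inverse_normal_transform(s$scores), 3)
#>         S1         S2         S3
#>  1.9329960 -0.4550299  1.0085892
```

`run_benchmark()` sweeps whole `p × alpha0` grids (or a supplied network
thinned to target sparsities) and returns one long tibble; `write_sim()` /
`read_sim()` round-trip complete datasets as plain-text bundles; a CLI
launcher (`inst/cli/netshy.R`) exposes `summarize`, `simulate`, `benchmark`
and `evaluate` subcommands for shell use.

See `vignettes/netshy-methods.Rmd` for the model, the evaluation conventions,
the calibration of the benchmark's noise scales, and known limitations.

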