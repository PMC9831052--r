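# Builders shared across test files. All fixtures are generated in code.

path_network <- function(weights = c(0.2, 0.7)) {
  p <- length(weights) + 1L
  A <- matrix(0, p, p)
  for (i in seq_along(weights)) {
    A[i, i + 1L] <- A[i + 1L, i] <- weights[i]
  }
  module_network(A)
}

star_network <- function(p = 5, w = 0.5, center = 1L) {
  A <- matrix(0, p, p)
  A[center, -center] <- w
  A[-center, center] <- w
  module_network(A)
}

complete_network <- function(p = 4, w = 0.3) {
  A <- matrix(w, p, p)
  diag(A) <- 0
  module_network(A)
}

random_profiles <- function(n, p, seed = 1, feature_ids = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  as_profile_matrix(X, feature_ids = feature_ids)
}

# Independent spectral oracle: first PC via an explicit eigendecomposition of
# the centered cross-product (never the SVD route used by the package).
oracle_pc1 <- function(M) {
  Mc <- sweep(M, 2L, colMeans(M))
  ev <- eigen(crossprod(Mc), symmetric = TRUE)
  v <- ev$vectors[, 1L]
  list(loading = v, scores = drop(Mc %*% v))
}

# Align the sign of `v` to `ref` before comparing loadings.
sign_align <- function(v, ref) if (sum(v * ref) < 0) -v else v

tiny_sim <- function(p = 8, n = 150, alpha0 = 0.5, sigma_e = 1, sigma_eps = 1,
                     seed = 42) {
  simulate_scenario1(sim_config(
    p = p, alpha0 = alpha0, n_master = n,
    sigma_e = sigma_e, sigma_eps = sigma_eps, seed = seed
  ))
}
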