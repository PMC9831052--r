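#' Simulation configuration
#'
#' Bundles the knobs of the Gaussian graphical model benchmark: network size
#' `p` and edge probability `alpha0`, the master sample size, the two noise
#' scales, the diagonal-loading constant of the positive-definiteness step,
#' the edge-weight bounds, and the master seed from which every random stream
#' is derived (via [sub_seed()]).
#'
#' @param p Number of network nodes.
#' @param alpha0 Edge probability in \[0, 1\].
#' @param n_master Master sample size; subsampling schedules draw from this
#'   pool. Default 1000.
#' @param sigma_eps Standard deviation of the phenotype noise (the residual
#'   around the linear signal `beta0 + X0 beta`).
#' @param sigma_e Standard deviation of the element-wise measurement noise
#'   added to the true profiles.
#' @param pd_delta Diagonal loading added beyond `|min eigenvalue|` when
#'   turning the adjacency into a positive-definite precision matrix.
#' @param w_low,w_high Edge-weight bounds of the network generator.
#' @param seed Master integer seed.
#' @return A validated list of class `sim_config`.
#' @examples
#' sim_config(p = 30, alpha0 = 0.3, seed = 1)
#' @export
sim_config <- function(p = 30, alpha0 = 0.3, n_master = 1000,
                       sigma_eps = 1, sigma_e = 1, pd_delta = 0.1,
                       w_low = 0.1, w_high = 0.8, seed = 1) {
  check_scalar_number(p, "p", lower = 2)
  check_scalar_number(alpha0, "alpha0", lower = 0, upper = 1)
  check_scalar_number(n_master, "n_master", lower = 2)
  check_scalar_number(sigma_eps, "sigma_eps", lower = 0)
  check_scalar_number(sigma_e, "sigma_e", lower = 0)
  check_scalar_number(pd_delta, "pd_delta")
  if (pd_delta <= 0) {
    abort("`pd_delta` must be strictly positive.", class = "netshy_invalid_argument")
  }
  check_scalar_number(w_low, "w_low", lower = 0)
  check_scalar_number(w_high, "w_high")
  if (w_low >= w_high) {
    abort("`w_low` must be strictly below `w_high`.", class = "netshy_invalid_argument")
  }
  check_scalar_number(seed, "seed")
  structure(
    list(
      p = as.integer(p), alpha0 = alpha0, n_master = as.integer(n_master),
      sigma_eps = sigma_eps, sigma_e = sigma_e, pd_delta = pd_delta,
      w_low = w_low, w_high = w_high, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> p=%d alpha0=%.2f n_master=%d sigma_eps=%.3g sigma_e=%.3g pd_delta=%.3g seed=%d\n",
    x$p, x$alpha0, x$n_master, x$sigma_eps, x$sigma_e, x$pd_delta, x$seed
  ))
  invisible(x)
}

#' Turn a network adjacency into a Gaussian graphical model
#'
#' In a Gaussian graphical model the network adjacency plays the role of a
#' precision matrix (inverse covariance): zeros off the diagonal encode
#' conditional independence. A raw adjacency is not positive definite, so it
#' is diagonally loaded, `Omega = A + (max(0, -lambda_min(A)) + pd_delta) I`,
#' which preserves the off-diagonal zero pattern exactly. The covariance is
#' `Omega^{-1}` rescaled to unit diagonal (correlation form), so that all
#' simulated features share a common scale.
#'
#' @param net A [module_network()].
#' @param pd_delta Positive loading constant added beyond the spectral shift.
#' @return An object of class `precision_model` with fields `precision`
#'   (`Omega`), `covariance` (`Sigma`, unit diagonal), `shift` (the loading
#'   applied) and `node_ids`.
#' @examples
#' net <- er_network(10, 0.4, seed = 1)
#' m <- make_precision(net)
#' range(diag(m$covariance))
#' @export
make_precision <- function(net, pd_delta = 0.1) {
  net <- as_module_network(net)
  if (pd_delta <= 0) {
    abort("`pd_delta` must be strictly positive.", class = "netshy_invalid_argument")
  }
  A <- net$adjacency
  lam_min <- min(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  shift <- max(0, -lam_min) + pd_delta
  Omega <- A + diag(shift, nrow(A))
  Sigma <- stats::cov2cor(solve(Omega))
  dimnames(Omega) <- dimnames(Sigma) <- dimnames(A)
  structure(
    list(
      precision = Omega, covariance = Sigma,
      shift = shift, pd_delta = pd_delta, node_ids = net$node_ids
    ),
    class = "precision_model"
  )
}

#' @export
print.precision_model <- function(x, ...) {
  cat(sprintf(
    "<precision_model> p=%d, diagonal loading %.4g, condition number %.3g\n",
    length(x$node_ids), x$shift, kappa(x$covariance, exact = TRUE)
  ))
  invisible(x)
}

#' Draw true (noise-free) profiles from the graphical model
#'
#' Samples `n` subjects independently from `N(0, Sigma)` where `Sigma` is the
#' model covariance, giving the true profile matrix `X0`.
#'
#' @param model A [make_precision()] result.
#' @param n Sample size (>= 2).
#' @param seed Optional integer seed.
#' @return An `n x p` profile matrix with subject IDs `S1..Sn`.
#' @export
simulate_true_profiles <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "precision_model"))
  check_scalar_number(n, "n", lower = 2)
  X0 <- with_seed(seed, MASS::mvrnorm(n, mu = rep(0, length(model$node_ids)),
    Sigma = model$covariance
  ))
  as_profile_matrix(
    matrix(X0, nrow = n),
    subject_ids = paste0("S", seq_len(n)),
    feature_ids = model$node_ids
  )
}

#' Simulate a phenotype driven by node connectivity
#'
#' The phenotype is a linear function of the true profiles,
#' `Y0 = beta0 + X0 beta + eps`, with `eps_i ~ N(0, sigma_eps^2)`. The
#' coefficient of node `k` is its weighted degree, so highly connected nodes
#' have a proportionally large influence on the phenotype; the intercept
#' `beta0` is drawn once per dataset from `N(0, 1)`.
#'
#' @param X0 True profile matrix, columns aligned to `net`.
#' @param net A [module_network()].
#' @param sigma_eps Phenotype noise standard deviation.
#' @param seed Optional integer seed.
#' @return A list with `y0` (named length-`n` vector), `beta0` (scalar) and
#'   `beta` (named length-`p` vector of node degrees).
#' @export
simulate_phenotype <- function(X0, net, sigma_eps = 1, seed = NULL) {
  X0 <- as_profile_matrix(X0)
  net <- as_module_network(net)
  check_alignment(X0, net)
  check_scalar_number(sigma_eps, "sigma_eps", lower = 0)
  beta <- node_degrees(net)
  with_seed(seed, {
    beta0 <- stats::rnorm(1L)
    eps <- stats::rnorm(nrow(X0), 0, sigma_eps)
    y0 <- drop(beta0 + X0 %*% beta + eps)
    names(y0) <- rownames(X0)
    list(y0 = y0, beta0 = beta0, beta = beta)
  })
}

#' Perturb true profiles with measurement noise
#'
#' Emulates observing a module through a noisy instrument: the observed
#' profiles are `X = X0 + E` with `e_ij ~ N(0, sigma_e^2)` i.i.d.
#'
#' @param X0 True profile matrix.
#' @param sigma_e Measurement noise standard deviation.
#' @param seed Optional integer seed.
#' @return A profile matrix of the same shape and labels as `X0`.
#' @export
perturb_profiles <- function(X0, sigma_e = 1, seed = NULL) {
  X0 <- as_profile_matrix(X0)
  check_scalar_number(sigma_e, "sigma_e", lower = 0)
  E <- with_seed(seed, matrix(stats::rnorm(length(X0), 0, sigma_e), nrow = nrow(X0)))
  X <- X0 + E
  dimnames(X) <- dimnames(X0)
  X
}

new_module_sim <- function(net, model, X0, X, pheno, config) {
  structure(
    list(
      net = net, model = model, X0 = X0, X = X,
      y0 = pheno$y0, beta0 = pheno$beta0, beta = pheno$beta,
      config = config
    ),
    class = "module_sim"
  )
}

#' @export
print.module_sim <- function(x, ...) {
  cat(sprintf(
    "<module_sim> n=%d subjects, p=%d nodes, realized sparsity %.3f\n",
    nrow(x$X), n_nodes(x$net), sparsity(x$net)
  ))
  print(x$config)
  invisible(x)
}

# Shared downstream pipeline once a network is fixed: precision model, true
# profiles, phenotype, measurement noise. Sub-seeds are derived from the
# master seed so that the network source (generated vs supplied) does not
# perturb the downstream streams.
simulate_from_network <- function(net, config) {
  model <- make_precision(net, config$pd_delta)
  X0 <- simulate_true_profiles(model, config$n_master,
    seed = sub_seed(config$seed, "profiles")
  )
  pheno <- simulate_phenotype(X0, net, config$sigma_eps,
    seed = sub_seed(config$seed, "phenotype")
  )
  X <- perturb_profiles(X0, config$sigma_e,
    seed = sub_seed(config$seed, "measurement")
  )
  new_module_sim(net, model, X0, X, pheno, config)
}

#' Simulate a random-network benchmark dataset
#'
#' The random-network scenario: draw a weighted Erdos-Renyi network
#' (`p` nodes, edge probability `alpha0`, weights Unif(`w_low`, `w_high`)),
#' seed a Gaussian graphical model with it, draw true profiles
#' `X0 ~ N(0, Sigma)` for `n_master` subjects, build the degree-weighted
#' phenotype, and perturb the profiles with measurement noise. All randomness
#' derives from `config$seed` through named sub-seeds, so datasets are
#' bit-reproducible.
#'
#' @param config A [sim_config()].
#' @return A `module_sim` bundle: `net`, `model`, `X0`, `X`, `y0`, `beta0`,
#'   `beta`, `config`.
#' @examples
#' sim <- simulate_scenario1(sim_config(p = 10, n_master = 50, seed = 1))
#' sim$beta[1:3]
#' @export
simulate_scenario1 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  net <- er_network(config$p, config$alpha0, config$w_low, config$w_high,
    seed = sub_seed(config$seed, "network")
  )
  simulate_from_network(net, config)
}

#' Simulate a benchmark dataset from a supplied network
#'
#' The empirical-network scenario: instead of generating a random graph, run
#' the same generative pipeline on a network supplied by the user (for
#' example, a module extracted from a published multi-omics network).
#' Optionally hard-threshold the network first, to study the effect of
#' sparsifying the same topology.
#'
#' @param net A [module_network()] (its size overrides `config$p`).
#' @param config A [sim_config()].
#' @param threshold Optional weight cutoff applied via [hard_threshold()]
#'   before simulation.
#' @param target_sparsity Alternative to `threshold`: thin the network to this
#'   realized sparsity via [threshold_for_sparsity()].
#' @return A `module_sim` bundle (see [simulate_scenario1()]).
#' @export
simulate_scenario2_like <- function(net, config, threshold = NULL,
                                    target_sparsity = NULL) {
  stopifnot(inherits(config, "sim_config"))
  net <- as_module_network(net)
  if (!is.null(threshold) && !is.null(target_sparsity)) {
    abort("Supply `threshold` or `target_sparsity`, not both.",
      class = "netshy_invalid_argument"
    )
  }
  if (!is.null(target_sparsity)) {
    threshold <- threshold_for_sparsity(net, target_sparsity)
  }
  if (!is.null(threshold)) {
    net <- hard_threshold(net, threshold)
  }
  config$p <- n_nodes(net)
  simulate_from_network(net, config)
}

#' Synthetic stand-in for a published metabolite-protein module
#'
#' Generates a small two-block network that emulates the dimensions of an
#' empirical metabolite-protein module: `p = 20` nodes (7 labelled `M*` for
#' metabolites, 13 labelled `P*` for proteins by default) at a realized
#' sparsity near `alpha0 = 0.51`, with Unif(0.1, 0.8) edge weights. This is a
#' synthetic fixture — the published module's weights are not redistributed
#' here — intended for exercising the empirical-scenario code path.
#'
#' @param p Number of nodes.
#' @param alpha0 Edge probability.
#' @param n_block1 Number of nodes in the first (metabolite-like) block.
#' @param seed Integer seed.
#' @return A [module_network()].
#' @export
synthetic_mp_network <- function(p = 20, alpha0 = 0.51, n_block1 = 7, seed = 20) {
  check_scalar_number(n_block1, "n_block1", lower = 0, upper = p)
  net <- er_network(p, alpha0, seed = seed)
  ids <- c(
    paste0("M", seq_len(n_block1)),
    paste0("P", seq_len(p - n_block1))
  )
  module_network(net$adjacency, node_ids = ids)
}

#' Write or read a simulated dataset bundle
#'
#' A dataset is materialized as a directory of plain-text files:
#' `adjacency.csv` (labelled adjacency matrix), `X0.csv` and `X.csv`
#' (profile format), `phenotype.tsv` (`subject_id`, `y0`), `beta.tsv`
#' (`feature_id`, `beta`) and `config.json` (the generating configuration plus
#' `beta0`, for provenance). Doubles are written in round-trippable precision,
#' so `read_sim(write_sim(sim, dir))` reproduces the in-memory dataset
#' exactly; the precision model is recomputed from the stored adjacency.
#'
#' @param sim A `module_sim`.
#' @param dir Directory path (created if needed).
#' @return `write_sim` returns `dir` invisibly; `read_sim` returns a
#'   `module_sim`.
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "module_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_adjacency(sim$net, file.path(dir, "adjacency.csv"))
  write_profiles(sim$X0, file.path(dir, "X0.csv"))
  write_profiles(sim$X, file.path(dir, "X.csv"))
  readr::write_tsv(
    full_precision(tibble::tibble(subject_id = names(sim$y0), y0 = unname(sim$y0))),
    file.path(dir, "phenotype.tsv")
  )
  readr::write_tsv(
    full_precision(tibble::tibble(feature_id = names(sim$beta), beta = unname(sim$beta))),
    file.path(dir, "beta.tsv")
  )
  cfg <- unclass(sim$config)
  cfg$beta0 <- sim$beta0
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = I(17)
  )
  invisible(dir)
}

#' @rdname sim_io
#' @export
read_sim <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  beta0 <- cfg$beta0
  cfg$beta0 <- NULL
  config <- do.call(sim_config, cfg)
  net <- read_adjacency(file.path(dir, "adjacency.csv"))
  X0 <- read_profiles(file.path(dir, "X0.csv"))
  X <- read_profiles(file.path(dir, "X.csv"))
  # base-R parsers (strtod) round-trip the 17-digit decimals exactly
  pheno_df <- utils::read.delim(file.path(dir, "phenotype.tsv"))
  beta_df <- utils::read.delim(file.path(dir, "beta.tsv"))
  model <- make_precision(net, config$pd_delta)
  new_module_sim(
    net, model, X0, X,
    list(
      y0 = stats::setNames(pheno_df$y0, pheno_df$subject_id),
      beta0 = beta0,
      beta = stats::setNames(beta_df$beta, beta_df$feature_id)
    ),
    config
  )
}
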