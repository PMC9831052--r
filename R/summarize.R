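# First principal component of a raw matrix: columns are mean-centered (never
# variance-scaled) and the top right singular vector taken from an SVD of the
# centered matrix. The SVD route stays well-behaved when n < p, where an
# explicit covariance eigensolve would be rank-deficient.
pc1_core <- function(M, tol = 1e-12) {
  ctr <- colMeans(M)
  Mc <- sweep(M, 2L, ctr, check.margin = FALSE)
  total <- sum(Mc^2)
  if (total < tol) {
    abort("Input matrix is constant: the first PC is undefined.",
      class = "netshy_degenerate_input"
    )
  }
  sv <- svd(Mc, nu = 0L, nv = 1L)
  v <- sv$v[, 1L]
  j <- which.max(abs(v))
  if (v[j] < 0) v <- -v # sign convention: largest-|loading| entry positive
  list(
    scores = drop(Mc %*% v),
    loading = v,
    centering = ctr,
    var_explained = sv$d[1L]^2 / sum(sv$d^2)
  )
}

new_module_summary <- function(method, scores, loading, centering,
                               var_explained = NA_real_,
                               subject_ids = NULL, feature_ids = NULL) {
  scores <- stats::setNames(as.numeric(scores), subject_ids)
  if (!is.null(loading)) {
    loading <- stats::setNames(as.numeric(loading), feature_ids)
  }
  structure(
    list(
      method = method,
      scores = scores,
      loading = loading,
      centering = centering,
      var_explained = var_explained
    ),
    class = "module_summary"
  )
}

#' Summarize a module without network information (eigengene / NoNet)
#'
#' The conventional module representation: the first principal component of
#' the profile matrix `X` itself, ignoring topology. Columns of `X` are
#' mean-centered (not variance-scaled); the subject scores `Z` and the unit
#' loading vector are returned, with the sign fixed so that the loading entry
#' of largest absolute value is positive.
#'
#' @param X Profiles coercible via [as_profile_matrix()]: `n` subjects by `p`
#'   features.
#' @param n_components Number of components to retain. The method itself is
#'   defined by the first component; further components are exposed for
#'   exploratory use only, as columns of the `scores_all` / `loading_all`
#'   attributes.
#' @return A `module_summary` with fields `method`, `scores` (length `n`),
#'   `loading` (unit vector, length `p`), `centering` and `var_explained`.
#' @examples
#' X <- matrix(rnorm(40), 10, 4)
#' s <- summarize_nonet(X)
#' head(s$scores)
#' @export
summarize_nonet <- function(X, n_components = 1L) {
  X <- as_profile_matrix(X)
  if (nrow(X) < 2L) {
    abort("At least two subjects are required.", class = "netshy_invalid_profiles")
  }
  check_scalar_number(n_components, "n_components", lower = 1)
  pc <- pc1_core(X)
  out <- new_module_summary(
    "nonet", pc$scores, pc$loading, pc$centering, pc$var_explained,
    subject_ids = rownames(X), feature_ids = colnames(X)
  )
  if (n_components > 1L) {
    out <- add_extra_components(out, X, n_components)
  }
  out
}

#' Summarize a module with its topology (NetSHy)
#'
#' NetSHy combines the node profiles with the module topology before the
#' decomposition: the profile matrix is right-multiplied by the graph
#' Laplacian, `X* = X L`, and the first principal component of the
#' column-centered `X*` gives the subject scores. Because the columns of `L`
#' sum to zero, any per-subject constant offset of all features is annihilated
#' exactly, and nodes enter the summary weighted by how they sit in the
#' connectivity structure. The loading is a unit vector in the `X*` column
#' space (one entry per node).
#'
#' @inheritParams summarize_nonet
#' @param net A [module_network()] with at least one edge, whose node order
#'   matches the columns of `X`.
#' @return A `module_summary` (see [summarize_nonet()]) with
#'   `method = "netshy"`.
#' @examples
#' net <- er_network(5, 0.6, seed = 1)
#' X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, net$node_ids))
#' summarize_netshy(X, net)
#' @export
summarize_netshy <- function(X, net, n_components = 1L) {
  X <- as_profile_matrix(X)
  net <- as_module_network(net)
  check_alignment(X, net)
  if (sparsity(net) == 0) {
    abort("Network has no edges: the Laplacian is zero and NetSHy is undefined.",
      class = "netshy_degenerate_topology"
    )
  }
  Xs <- X %*% laplacian(net)$matrix
  pc <- pc1_core(Xs)
  out <- new_module_summary(
    "netshy", pc$scores, pc$loading, pc$centering, pc$var_explained,
    subject_ids = rownames(X), feature_ids = colnames(X)
  )
  if (n_components > 1L) {
    out <- add_extra_components(out, Xs, n_components)
  }
  out
}

add_extra_components <- function(out, M, n_components) {
  k <- min(as.integer(n_components), nrow(M) - 1L, ncol(M))
  Mc <- sweep(M, 2L, colMeans(M), check.margin = FALSE)
  sv <- svd(Mc, nu = 0L, nv = k)
  V <- sv$v
  for (j in seq_len(k)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  attr(out, "loading_all") <- V
  attr(out, "scores_all") <- Mc %*% V
  out
}

#' Summarize a module by its hub node profile
#'
#' Baseline representation that projects the whole module onto the profile of
#' its most highly connected node (the hub): the score vector is simply the
#' hub's column of `X`. No loading vector is associated with this method.
#'
#' @inheritParams summarize_netshy
#' @return A `module_summary` with `method = "hub"`, `loading = NULL`, and a
#'   `hub` attribute holding the hub index.
#' @export
summarize_hub <- function(X, net) {
  X <- as_profile_matrix(X)
  net <- as_module_network(net)
  check_alignment(X, net)
  hub <- find_hub(net)
  out <- new_module_summary(
    "hub", X[, hub], NULL, NULL, NA_real_,
    subject_ids = rownames(X)
  )
  attr(out, "hub") <- hub
  out
}

#' @export
print.module_summary <- function(x, ...) {
  cat(sprintf(
    "<module_summary: %s> %d subjects%s\n", x$method, length(x$scores),
    if (is.null(x$loading)) {
      sprintf(" (hub node %s)", names(attr(x, "hub")))
    } else {
      sprintf(", %d features, PVE on input %.3f", length(x$loading), x$var_explained)
    }
  ))
  invisible(x)
}

#' @export
tidy.module_summary <- function(x, ...) {
  if (is.null(x$loading)) {
    return(tibble::tibble(
      feature_id = character(), loading = numeric()
    ))
  }
  tibble::tibble(
    feature_id = names(x$loading) %||% paste0("V", seq_along(x$loading)),
    loading = unname(x$loading)
  )
}

#' @export
glance.module_summary <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n = length(x$scores),
    p = if (is.null(x$loading)) NA_integer_ else length(x$loading),
    var_explained = x$var_explained
  )
}

#' @export
augment.module_summary <- function(x, ...) {
  tibble::tibble(
    subject_id = names(x$scores) %||% paste0("S", seq_along(x$scores)),
    score = unname(x$scores)
  )
}

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles via their ranks:
#' `x_i -> qnorm((r_i - c) / (n - 2c + 1))` with offset `c = 3/8` (Blom) and
#' average ranks for ties. Module scores are typically inverse-normalized
#' before being regressed on genotype or other covariates, so that downstream
#' linear models see a marginally Gaussian response. The transform is monotone
#' in its input and maps tied inputs to identical outputs.
#'
#' @param z Numeric vector with at least two distinct values.
#' @param offset Rank offset `c`; 3/8 is Blom's choice.
#' @return Numeric vector of the same length (names preserved).
#' @examples
#' inverse_normal_transform(c(3, 1, 4, 1, 5))
#' @export
inverse_normal_transform <- function(z, offset = 3 / 8) {
  if (!is.numeric(z) || length(z) < 2L || anyNA(z)) {
    abort("`z` must be a numeric vector of length >= 2 without missing values.",
      class = "netshy_invalid_argument"
    )
  }
  if (length(unique(z)) == 1L) {
    abort("`z` is constant: ranks are undefined for the transform.",
      class = "netshy_degenerate_input"
    )
  }
  check_scalar_number(offset, "offset", lower = 0, upper = 0.5)
  r <- rank(z, ties.method = "average")
  n <- length(z)
  out <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  names(out) <- names(z)
  out
}

#' Read and write summary scores and loadings
#'
#' Scores are stored as a 2-column tab-separated table `(subject_id, score)`,
#' loadings as `(feature_id, loading)`.
#'
#' @param x A `module_summary`.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name summary_io
NULL

#' @rdname summary_io
#' @export
write_scores <- function(x, path) {
  readr::write_tsv(full_precision(augment(x)), path)
  invisible(path)
}

#' @rdname summary_io
#' @export
read_scores <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname summary_io
#' @export
write_loadings <- function(x, path) {
  readr::write_tsv(full_precision(tidy(x)), path)
  invisible(path)
}

#' @rdname summary_io
#' @export
read_loadings <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
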