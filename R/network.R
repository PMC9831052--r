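#' Weighted undirected network modules
#'
#' A module network is a weighted, non-negative, undirected graph on `p`
#' labelled nodes, stored as a symmetric adjacency matrix `A` with zero
#' diagonal. Entry `a_kl` is the edge weight (similarity) between nodes `k`
#' and `l`; `a_kl = 0` means no edge. Self-loops are excluded: the diagonal is
#' forced to zero on construction.
#'
#' @param adjacency A `p x p` numeric matrix of non-negative edge weights.
#'   Must be symmetric to within `tol`; it is exactly symmetrized by averaging
#'   `(A + t(A)) / 2` on construction.
#' @param node_ids Optional character vector of `p` unique node labels.
#'   Defaults to the matrix dimnames, or `V1..Vp`.
#' @param tol Symmetry tolerance for validation.
#' @return An object of class `module_network` with fields `adjacency` and
#'   `node_ids`.
#' @examples
#' A <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
#' net <- module_network(A, node_ids = c("a", "b"))
#' node_degrees(net)
#' @export
module_network <- function(adjacency, node_ids = NULL, tol = 1e-10) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency)) {
    abort("`adjacency` must be a numeric matrix.", class = "netshy_invalid_network")
  }
  p <- nrow(adjacency)
  if (ncol(adjacency) != p) {
    abort("`adjacency` must be square.", class = "netshy_invalid_network")
  }
  if (anyNA(adjacency)) {
    abort("`adjacency` must not contain missing values.", class = "netshy_invalid_network")
  }
  if (max(abs(adjacency - t(adjacency))) > tol) {
    abort("`adjacency` is not symmetric (tolerance 1e-10).", class = "netshy_invalid_network")
  }
  adjacency <- (adjacency + t(adjacency)) / 2
  if (any(adjacency < 0)) {
    abort("`adjacency` must be non-negative.", class = "netshy_invalid_network")
  }
  if (any(diag(adjacency) != 0)) {
    warn("Non-zero diagonal entries set to 0 (self-loops are excluded).")
    diag(adjacency) <- 0
  }
  node_ids <- node_ids %||% rownames(adjacency) %||% paste0("V", seq_len(p))
  node_ids <- as.character(node_ids)
  if (length(node_ids) != p || anyDuplicated(node_ids)) {
    abort("`node_ids` must be `p` unique labels.", class = "netshy_invalid_network")
  }
  dimnames(adjacency) <- list(node_ids, node_ids)
  structure(
    list(adjacency = adjacency, node_ids = node_ids),
    class = "module_network"
  )
}

#' Coerce to a module network
#'
#' Matrices are taken as adjacency matrices. Data frames are taken as
#' undirected edge lists with columns (node_a, node_b, weight); each unordered
#' pair may appear once and is mirrored into both triangles.
#'
#' @param x Object to coerce.
#' @param ... Passed to methods.
#' @return A [module_network()].
#' @export
as_module_network <- function(x, ...) UseMethod("as_module_network")

#' @export
as_module_network.module_network <- function(x, ...) x

#' @export
as_module_network.matrix <- function(x, ...) module_network(x, ...)

#' @rdname as_module_network
#' @param node_ids Optional node labels; defaults to the sorted union of the
#'   edge-list endpoints (so isolated nodes must be supplied explicitly).
#' @export
as_module_network.data.frame <- function(x, node_ids = NULL, ...) {
  if (ncol(x) < 3L) {
    abort("An edge list needs three columns: node_a, node_b, weight.",
      class = "netshy_invalid_network"
    )
  }
  a <- as.character(x[[1L]])
  b <- as.character(x[[2L]])
  w <- as.numeric(x[[3L]])
  node_ids <- node_ids %||% sort(unique(c(a, b)))
  p <- length(node_ids)
  A <- matrix(0, p, p, dimnames = list(node_ids, node_ids))
  for (i in seq_along(a)) {
    if (a[i] == b[i]) next # self-loops dropped
    A[a[i], b[i]] <- w[i]
    A[b[i], a[i]] <- w[i]
  }
  module_network(A, node_ids = node_ids)
}

n_nodes <- function(net) length(net$node_ids)

#' @export
print.module_network <- function(x, ...) {
  cat(sprintf(
    "<module_network> %d nodes, %d edges, sparsity %.3f\n",
    n_nodes(x), sum(x$adjacency[upper.tri(x$adjacency)] > 0), sparsity(x)
  ))
  invisible(x)
}

#' @export
tidy.module_network <- function(x, ...) {
  ut <- which(upper.tri(x$adjacency) & x$adjacency > 0, arr.ind = TRUE)
  tibble::tibble(
    node_a = x$node_ids[ut[, 1L]],
    node_b = x$node_ids[ut[, 2L]],
    weight = x$adjacency[ut]
  )
}

#' @export
glance.module_network <- function(x, ...) {
  deg <- node_degrees(x)
  tibble::tibble(
    p = n_nodes(x),
    n_edges = sum(x$adjacency[upper.tri(x$adjacency)] > 0),
    sparsity = sparsity(x),
    max_degree = if (all(deg == 0)) 0 else max(deg)
  )
}

#' Graph Laplacian of a module network
#'
#' Computes `L = D - A`, where `D` is the diagonal matrix of weighted node
#' degrees `D_kk = sum_l a_kl`. `L` is symmetric positive semidefinite, every
#' row and column sums to zero, and the multiplicity of its zero eigenvalue
#' equals the number of connected components.
#'
#' @param net A [module_network()].
#' @return An object of class `module_laplacian` with fields `matrix` (the
#'   `p x p` Laplacian) and `degrees` (the weighted degree vector).
#' @examples
#' net <- module_network(matrix(c(0, 0.5, 0.5, 0), 2, 2))
#' laplacian(net)$matrix
#' @export
laplacian <- function(net) {
  net <- as_module_network(net)
  deg <- node_degrees(net)
  L <- diag(deg, nrow = length(deg)) - net$adjacency
  dimnames(L) <- dimnames(net$adjacency)
  structure(list(matrix = L, degrees = deg), class = "module_laplacian")
}

#' @export
print.module_laplacian <- function(x, ...) {
  cat(sprintf(
    "<module_laplacian> %d nodes, total degree %.4g\n",
    length(x$degrees), sum(x$degrees)
  ))
  invisible(x)
}

#' Generate a weighted Erdos-Renyi network
#'
#' Draws a G(p, alpha0) random graph: each unordered node pair is connected
#' independently with probability `alpha0`, and every realized edge receives a
#' weight drawn from Unif(`w_low`, `w_high`). Isolated nodes are permitted
#' (the generator does not condition on connectivity).
#'
#' @param p Number of nodes (at least 2).
#' @param alpha0 Edge probability in \[0, 1\]; also the expected sparsity of
#'   the realized graph.
#' @param w_low,w_high Bounds of the uniform edge-weight distribution.
#' @param seed Optional integer seed; a fixed seed makes the draw
#'   bit-reproducible without disturbing the caller's RNG stream.
#' @return A [module_network()].
#' @examples
#' net <- er_network(30, 0.3, seed = 1)
#' sparsity(net)
#' @export
er_network <- function(p, alpha0, w_low = 0.1, w_high = 0.8, seed = NULL) {
  check_scalar_number(p, "p")
  if (p < 2) {
    abort("`p` must be at least 2.", class = "netshy_invalid_size")
  }
  check_scalar_number(alpha0, "alpha0", lower = 0, upper = 1)
  check_scalar_number(w_low, "w_low", lower = 0)
  check_scalar_number(w_high, "w_high")
  if (w_low >= w_high) {
    abort("`w_low` must be strictly below `w_high`.", class = "netshy_invalid_argument")
  }
  with_seed(seed, {
    g <- igraph::sample_gnp(p, alpha0)
    igraph::E(g)$weight <- stats::runif(igraph::gsize(g), w_low, w_high)
    A <- igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE)
    module_network(A)
  })
}

#' Remove weak edges by hard thresholding
#'
#' Sets every edge weight strictly below `t` to zero, leaving the remaining
#' weights unchanged. Idempotent at fixed `t`; realized sparsity is
#' non-increasing in `t`.
#'
#' @param net A [module_network()].
#' @param t Non-negative weight cutoff.
#' @return The thresholded [module_network()].
#' @export
hard_threshold <- function(net, t) {
  net <- as_module_network(net)
  check_scalar_number(t, "t", lower = 0)
  A <- net$adjacency
  A[A < t] <- 0
  module_network(A, node_ids = net$node_ids)
}

#' Cutoff that thins a network to a target sparsity
#'
#' Returns the hard-threshold value `t` such that [hard_threshold()] keeps
#' the `round(target * p(p-1)/2)` strongest edges, i.e. moves the realized
#' sparsity as close as possible to `target` from above.
#'
#' @param net A [module_network()].
#' @param target Desired realized sparsity in \[0, 1\].
#' @return A single numeric cutoff.
#' @export
threshold_for_sparsity <- function(net, target) {
  net <- as_module_network(net)
  check_scalar_number(target, "target", lower = 0, upper = 1)
  w <- net$adjacency[upper.tri(net$adjacency)]
  w <- w[w > 0]
  keep <- round(target * n_nodes(net) * (n_nodes(net) - 1) / 2)
  if (keep >= length(w)) {
    return(0)
  }
  if (keep == 0) {
    return(max(w) * (1 + 1e-12))
  }
  sort(w, decreasing = TRUE)[keep]
}

#' Realized sparsity of a network
#'
#' Fraction of unordered node pairs joined by an edge of strictly positive
#' weight: `#\{a_kl > 0, k < l\} / (p(p-1)/2)`. For a G(p, alpha0) draw this
#' concentrates around `alpha0`.
#'
#' @param net A [module_network()].
#' @return A fraction in \[0, 1\].
#' @export
sparsity <- function(net) {
  net <- as_module_network(net)
  w <- net$adjacency[upper.tri(net$adjacency)]
  sum(w > 0) / length(w)
}

#' Weighted node degrees
#'
#' @param net A [module_network()].
#' @return A named numeric vector; entry `k` is the row sum `sum_l a_kl`.
#' @export
node_degrees <- function(net) {
  net <- as_module_network(net)
  rowSums(net$adjacency)
}

#' Locate the hub node
#'
#' The hub is the most highly connected intramodular node, i.e. the node of
#' maximal weighted degree. Ties are broken deterministically in favour of
#' the lowest node index.
#'
#' @param net A [module_network()] with at least one edge.
#' @return The integer index of the hub node (its label is attached as the
#'   vector name).
#' @export
find_hub <- function(net) {
  net <- as_module_network(net)
  deg <- node_degrees(net)
  if (all(deg == 0)) {
    abort("Network has no edges: no hub node exists.", class = "netshy_no_hub")
  }
  idx <- which.max(deg) # which.max returns the first (lowest-index) maximum
  stats::setNames(as.integer(idx), net$node_ids[idx])
}

#' Read and write networks as plain text
#'
#' Two interchange formats are supported. The edge list is a 3-column
#' tab-separated table `(node_a, node_b, weight)` with one line per unordered
#' pair (header optional on read, written by default). The adjacency format
#' is a square comma-separated matrix with node labels in the first row and
#' first column; symmetry is validated on load (tolerance `1e-10`) and the
#' matrix exactly symmetrized by averaging.
#'
#' @param path File path.
#' @param net A [module_network()].
#' @return Readers return a [module_network()]; writers return `path`
#'   invisibly.
#' @name network_io
NULL

#' @rdname network_io
#' @export
read_edge_list <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1L]][3L])))
  df <- utils::read.delim(path,
    header = has_header, sep = "\t",
    col.names = c("node_a", "node_b", "weight"),
    colClasses = c("character", "character", "numeric")
  )
  as_module_network(df)
}

#' @rdname network_io
#' @export
write_edge_list <- function(net, path) {
  net <- as_module_network(net)
  readr::write_tsv(full_precision(tidy(net)), path)
  invisible(path)
}

#' @rdname network_io
#' @export
read_adjacency <- function(path) {
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  A <- as.matrix(df)
  if (!identical(rownames(A), colnames(A))) {
    abort("Adjacency file must have matching row and column labels.",
      class = "netshy_invalid_network"
    )
  }
  module_network(A, node_ids = rownames(A))
}

#' @rdname network_io
#' @export
write_adjacency <- function(net, path) {
  net <- as_module_network(net)
  df <- full_precision(tibble::as_tibble(net$adjacency, rownames = "node_id"))
  readr::write_csv(df, path)
  invisible(path)
}
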