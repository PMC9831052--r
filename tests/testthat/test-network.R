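test_that("Laplacian equals D - A on hand-built graphs", {
  net <- module_network(matrix(c(0, 0.5, 0.5, 0), 2, 2))
  L <- laplacian(net)
  expect_equal(unname(L$matrix), matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2))
  expect_equal(unname(L$degrees), c(0.5, 0.5))

  empty <- module_network(matrix(0, 3, 3))
  expect_equal(unname(laplacian(empty)$matrix), matrix(0, 3, 3))

  # 3-node path, checked against an independent elementwise D - A computation
  net <- path_network(c(0.2, 0.7))
  A <- net$adjacency
  expect_equal(unname(diag(laplacian(net)$matrix)), c(0.2, 0.9, 0.7))
  expect_equal(laplacian(net)$matrix, diag(rowSums(A)) - A, ignore_attr = TRUE)
})

test_that("invalid adjacency matrices are rejected", {
  A <- matrix(c(0, 1, 0.5, 0), 2, 2)
  expect_error(module_network(A), class = "netshy_invalid_network")
  B <- matrix(c(0, -0.1, -0.1, 0), 2, 2)
  expect_error(module_network(B), class = "netshy_invalid_network")
  expect_error(module_network(matrix(0, 2, 3)), class = "netshy_invalid_network")
  expect_warning(
    module_network(matrix(c(1, 0.2, 0.2, 0), 2, 2)),
    "self-loops"
  )
  expect_error(er_network(1, 0.5), class = "netshy_invalid_size")
})

test_that("generated Laplacians are PSD with zero row sums", {
  for (seed in 1:5) {
    net <- er_network(15, 0.4, seed = seed)
    L <- laplacian(net)$matrix
    expect_lt(max(abs(rowSums(L))), 1e-10)
    expect_equal(L, t(L))
    expect_gte(min(eigen(L, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("zero eigenvalues of L count connected components", {
  n_zero <- function(net) {
    ev <- eigen(laplacian(net)$matrix, symmetric = TRUE, only.values = TRUE)$values
    sum(abs(ev) < 1e-8)
  }
  expect_equal(n_zero(path_network(c(0.3, 0.4, 0.5))), 1L)
  # two components: a path and an edge
  A <- matrix(0, 5, 5)
  A[1, 2] <- A[2, 1] <- 0.3
  A[2, 3] <- A[3, 2] <- 0.4
  A[4, 5] <- A[5, 4] <- 0.6
  expect_equal(n_zero(module_network(A)), 2L)
  # three components: an edge plus two isolated nodes
  B <- matrix(0, 4, 4)
  B[1, 2] <- B[2, 1] <- 0.2
  expect_equal(n_zero(module_network(B)), 3L)
})

test_that("ER generator honours alpha0, weight bounds and seed", {
  expect_equal(sparsity(er_network(10, 0, seed = 1)), 0)
  net <- er_network(30, 0.3, seed = 7)
  w <- net$adjacency[upper.tri(net$adjacency)]
  expect_true(all(w[w > 0] > 0.1 & w[w > 0] < 0.8))
  expect_identical(er_network(20, 0.5, seed = 3), er_network(20, 0.5, seed = 3))

  # empirical edge fraction concentrates around alpha0
  p <- 30
  n_pairs <- p * (p - 1) / 2
  n_seeds <- 200
  frac <- vapply(seq_len(n_seeds), function(s) sparsity(er_network(p, 0.3, seed = s)), numeric(1))
  se <- sqrt(0.3 * 0.7 / (n_pairs * n_seeds))
  expect_lt(abs(mean(frac) - 0.3), 3 * se)

  # edge counts follow Binomial(p(p-1)/2, alpha0): chi-squared GOF on pooled bins
  counts <- round(frac * n_pairs)
  qs <- qbinom(c(0.2, 0.4, 0.6, 0.8), n_pairs, 0.3)
  brk <- c(-1, qs, n_pairs)
  obs <- table(cut(counts, brk))
  expected_p <- diff(pbinom(brk, n_pairs, 0.3))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = expected_p / sum(expected_p)))
  expect_gt(gof$p.value, 1e-3)
})

test_that("hard thresholding removes weak edges and nothing else", {
  net <- er_network(20, 0.6, seed = 2)
  expect_identical(hard_threshold(net, 0), net)
  wmax <- max(net$adjacency)
  expect_equal(sparsity(hard_threshold(net, wmax + 0.1)), 0)
  th <- hard_threshold(net, 0.4)
  expect_identical(hard_threshold(th, 0.4), th) # idempotent
  # sparsity is non-increasing in t
  ts <- seq(0, 0.9, by = 0.15)
  sp <- vapply(ts, function(t) sparsity(hard_threshold(net, t)), numeric(1))
  expect_true(all(diff(sp) <= 0))
  kept <- th$adjacency[th$adjacency > 0]
  expect_true(all(kept >= 0.4))
  expect_equal(th$adjacency[th$adjacency > 0], net$adjacency[net$adjacency >= 0.4])
})

test_that("threshold_for_sparsity hits the requested realized sparsity", {
  net <- synthetic_mp_network(p = 20, alpha0 = 0.51, seed = 20)
  expect_equal(sparsity(net), 0.51, tolerance = 0.15)
  t25 <- threshold_for_sparsity(net, 0.25)
  expect_equal(sparsity(hard_threshold(net, t25)), 0.25, tolerance = 0.011)
})

test_that("sparsity counts strictly positive unordered pairs", {
  expect_equal(sparsity(complete_network(5)), 1)
  expect_equal(sparsity(module_network(matrix(0, 4, 4))), 0)
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.1
  A[1, 3] <- A[3, 1] <- 0.2
  A[3, 4] <- A[4, 3] <- 0.3
  expect_equal(sparsity(module_network(A)), 0.5)
})

test_that("node degrees are weighted row sums", {
  expect_equal(unname(node_degrees(complete_network(6, 0.3))), rep(5 * 0.3, 6))
  A <- matrix(0, 3, 3)
  A[1, 2] <- A[2, 1] <- 0.4
  expect_equal(unname(node_degrees(module_network(A))), c(0.4, 0.4, 0))
  net <- er_network(6, 0.5, seed = 11)
  brute <- vapply(1:6, function(k) sum(net$adjacency[k, ]), numeric(1))
  expect_equal(unname(node_degrees(net)), brute)
})

test_that("hub is the maximal-degree node with lowest-index ties", {
  expect_equal(unname(find_hub(star_network(6, center = 3L))), 3L)
  # two nodes tied at maximal degree
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 0.5
  A[3, 4] <- A[4, 3] <- 0.5
  expect_equal(unname(find_hub(module_network(A))), 1L)
  net <- er_network(12, 0.4, seed = 5)
  expect_equal(unname(find_hub(net)), unname(which.max(rowSums(net$adjacency))))
  expect_error(find_hub(module_network(matrix(0, 3, 3))), class = "netshy_no_hub")
})

test_that("edge list and adjacency files round-trip", {
  net <- er_network(8, 0.5, seed = 9)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(net, f1)
  expect_equal(read_edge_list(f1)$adjacency, net$adjacency)
  # header is optional on read
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(readLines(f1)[-1L], f2)
  expect_equal(read_edge_list(f2)$adjacency, net$adjacency)

  f3 <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(net, f3)
  expect_equal(read_adjacency(f3), net)
})

test_that("edge-list coercion mirrors pairs and drops self-loops", {
  df <- data.frame(
    node_a = c("a", "b", "c"), node_b = c("b", "c", "c"),
    weight = c(0.3, 0.6, 9)
  )
  net <- as_module_network(df)
  expect_equal(net$node_ids, c("a", "b", "c"))
  expect_equal(net$adjacency["a", "b"], 0.3)
  expect_equal(net$adjacency["b", "a"], 0.3)
  expect_equal(diag(net$adjacency), c(a = 0, b = 0, c = 0))
  expect_equal(glance(net)$n_edges, 2L)
  expect_equal(nrow(tidy(net)), 2L)
})
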