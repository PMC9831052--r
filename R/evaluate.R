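#' Absolute correlation of a summary score with a phenotype
#'
#' Pearson correlation between the subject scores `Z` and the phenotype,
#' reported as an absolute value: the sign of a principal-component score is a
#' convention, so only the magnitude of the association is meaningful.
#'
#' @param z Length-`n` score vector.
#' @param y Length-`n` phenotype vector.
#' @return `|corr(z, y)|` in \[0, 1\].
#' @examples
#' phenotype_correlation(1:5, c(2, 4, 5, 4, 8))
#' @export
phenotype_correlation <- function(z, y) {
  if (length(z) != length(y)) {
    abort("`z` and `y` must have equal length.", class = "netshy_invalid_argument")
  }
  if (length(z) < 3L) {
    abort("At least 3 subjects are required for a correlation.",
      class = "netshy_invalid_argument"
    )
  }
  if (stats::sd(z) == 0 || stats::sd(y) == 0) {
    abort("Correlation is undefined for a constant input.",
      class = "netshy_degenerate_input"
    )
  }
  abs(stats::cor(z, y))
}

#' Proportion of variance explained by a loading
#'
#' Fraction of the total variance of the TRUE profile matrix captured along a
#' unit loading: `||X0c phi||^2 / ||X0c||_F^2`, with `X0c` the column-centered
#' `X0`. The loading may come from any method (e.g. from the observed `X`, or
#' from the Laplacian-transformed `X*`), but it is always evaluated against
#' `X0` — the criterion asks how much of the *true* signal a method's
#' direction retains. For the top right singular vector of `X0c` itself this
#' equals `sigma_1^2 / sum_k sigma_k^2`, the maximum attainable.
#'
#' @param loading Length-`p` loading; expected to be unit-norm and
#'   renormalized defensively.
#' @param X0 True profile matrix (`n x p`).
#' @return A proportion in \[0, 1\].
#' @export
variance_explained <- function(loading, X0) {
  X0 <- as_profile_matrix(X0)
  if (!is.numeric(loading) || length(loading) != ncol(X0)) {
    abort("`loading` must be numeric with one entry per feature.",
      class = "netshy_invalid_argument"
    )
  }
  nrm <- sqrt(sum(loading^2))
  if (nrm < 1e-12) {
    abort("`loading` has zero norm.", class = "netshy_degenerate_input")
  }
  loading <- loading / nrm
  X0c <- sweep(X0, 2L, colMeans(X0), check.margin = FALSE)
  total <- sum(X0c^2)
  if (total < 1e-12) {
    abort("`X0` is constant: PVE is undefined.", class = "netshy_degenerate_input")
  }
  sum((X0c %*% loading)^2) / total
}

#' Optimal baseline from the true profiles
#'
#' The performance ceiling: the first principal component of the noise-free
#' profile matrix `X0`. Its absolute correlation with the phenotype and its
#' PVE on `X0` are the reference values against which every method's criteria
#' are ratioed ("closer to 1 is better").
#'
#' @param X0 True profile matrix.
#' @param y0 Length-`n` phenotype.
#' @return A list with `rho_opt`, `pve_opt` and the `module_summary` (method
#'   `"opt"`).
#' @export
optimal_baseline <- function(X0, y0) {
  s <- summarize_nonet(X0)
  s$method <- "opt"
  list(
    rho_opt = phenotype_correlation(s$scores, y0),
    pve_opt = variance_explained(s$loading, X0),
    summary = s
  )
}

# Internal evaluation of one subject subset: raw criteria per method plus the
# optimal baseline recomputed on the same subset. `X`, `Xstar`, `X0` are
# master matrices; `idx` selects rows. Row subsetting commutes with the
# Laplacian transform, so Xstar is computed once upstream.
eval_subset <- function(X, Xstar, X0, y0, idx, methods) {
  X0s <- X0[idx, , drop = FALSE]
  y0s <- y0[idx]
  opt <- pc1_core(X0s)
  rho_opt <- phenotype_correlation(opt$scores, y0s)
  X0c <- sweep(X0s, 2L, colMeans(X0s), check.margin = FALSE)
  total <- sum(X0c^2)
  pve_opt <- sum((X0c %*% opt$loading)^2) / total

  out <- vector("list", length(methods))
  for (m in seq_along(methods)) {
    method <- methods[m]
    if (method == "nonet") {
      pc <- pc1_core(X[idx, , drop = FALSE])
      z <- pc$scores
      phi <- pc$loading
    } else if (method == "netshy") {
      pc <- pc1_core(Xstar[idx, , drop = FALSE])
      z <- pc$scores
      phi <- pc$loading
    } else if (method == "hub") {
      z <- X[idx, attr(Xstar, "hub") %||% 1L]
      phi <- NULL
    } else {
      abort(sprintf("Unknown method '%s'.", method), class = "netshy_invalid_argument")
    }
    rho <- phenotype_correlation(z, y0s)
    pve <- if (is.null(phi)) NA_real_ else sum((X0c %*% phi)^2) / total
    out[[m]] <- c(rho = rho, pve = pve)
  }
  names(out) <- methods
  out$opt <- c(rho = rho_opt, pve = pve_opt)
  out
}

#' Evaluate summarization methods on a simulated dataset
#'
#' Computes each method's summary on the observed data (`X`, and the network
#' for NetSHy / hub), then scores it against the truth: absolute correlation
#' of the scores with the phenotype `Y0`, and proportion of variance of the
#' true `X0` explained by the loading. Both criteria are reported together
#' with the optimal baseline from `X0` and the corresponding ratios. The hub
#' method has no loading, so its PVE is `NA`.
#'
#' @param sim A `module_sim` from [simulate_scenario1()] or
#'   [simulate_scenario2_like()].
#' @param methods Character subset of `c("netshy", "nonet", "hub")`.
#' @return A tibble with one row per method and columns `method`, `rho`,
#'   `pve`, `rho_opt`, `pve_opt`, `rho_ratio`, `pve_ratio`.
#' @examples
#' sim <- simulate_scenario1(sim_config(p = 10, n_master = 100, seed = 1))
#' evaluate_summaries(sim)
#' @export
evaluate_summaries <- function(sim, methods = c("netshy", "nonet")) {
  stopifnot(inherits(sim, "module_sim"))
  methods <- match.arg(methods, c("netshy", "nonet", "hub"), several.ok = TRUE)
  Xstar <- sim$X %*% laplacian(sim$net)$matrix
  attr(Xstar, "hub") <- find_hub(sim$net)
  res <- eval_subset(sim$X, Xstar, sim$X0, sim$y0, seq_len(nrow(sim$X)), methods)
  opt <- res$opt
  dplyr::bind_rows(lapply(methods, function(m) {
    tibble::tibble(
      method = m,
      rho = res[[m]][["rho"]], pve = res[[m]][["pve"]],
      rho_opt = opt[["rho"]], pve_opt = opt[["pve"]],
      rho_ratio = res[[m]][["rho"]] / opt[["rho"]],
      pve_ratio = res[[m]][["pve"]] / opt[["pve"]]
    )
  }))
}

# Subsampling engine shared by the simulation-mode and real-data-mode studies.
# `evaluator(idx)` returns a list of named numeric metric vectors, one per
# method; in simulation mode it also carries an "opt" element (the baseline
# recomputed on the same subset). Per size, raw criteria are averaged over the
# iterations; the ratio metrics are ratios of those means (the per-iteration
# ratio has a near-zero denominator whenever the subsample's optimal
# correlation is weak, so its mean is unstable), with the ratio sd reported on
# the same scale as sd(raw) / mean(opt).
run_subsampling <- function(n_total, sizes, iterations, seed, evaluator, methods) {
  if (any(sizes >= n_total)) {
    abort("All subsample sizes must be below the master sample size.",
      class = "netshy_schedule_error"
    )
  }
  if (any(diff(sizes) >= 0)) {
    abort("`sizes` must be strictly decreasing.", class = "netshy_schedule_error")
  }
  if (iterations < 2L) {
    abort("`iterations` must be at least 2.", class = "netshy_invalid_argument")
  }
  summarise_size <- function(size, means, sds, n_it) {
    rows <- list()
    has_opt <- "opt" %in% names(means)
    groups <- c(methods, if (has_opt) "opt")
    for (m in groups) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        size = size, method = m, metric = names(means[[m]]),
        mean = unname(means[[m]]), sd = unname(sds[[m]]),
        iterations = n_it
      )
      if (has_opt && m != "opt") {
        ratio_names <- paste0(names(means[[m]]), "_ratio")
        rows[[length(rows) + 1L]] <- tibble::tibble(
          size = size, method = m, metric = ratio_names,
          mean = unname(means[[m]] / means[["opt"]]),
          sd = unname(sds[[m]] / means[["opt"]]),
          iterations = n_it
        )
      }
    }
    rows
  }
  with_seed(seed, {
    rows <- list()
    # single-shot evaluation at the full master size
    full <- evaluator(seq_len(n_total))
    zero_sd <- lapply(full, function(v) v * 0)
    rows <- c(rows, summarise_size(n_total, full, zero_sd, 1L))
    for (s in sizes) {
      acc <- vector("list", iterations)
      for (it in seq_len(iterations)) {
        idx <- sample.int(n_total, s, replace = FALSE)
        acc[[it]] <- evaluator(idx)
      }
      means <- list()
      sds <- list()
      for (m in names(acc[[1L]])) {
        vals <- do.call(rbind, lapply(acc, `[[`, m))
        means[[m]] <- colMeans(vals)
        sds[[m]] <- apply(vals, 2L, stats::sd)
      }
      rows <- c(rows, summarise_size(s, means, sds, iterations))
    }
    dplyr::bind_rows(rows)
  })
}

#' Subsampling robustness study on a simulated dataset
#'
#' Starting from the master dataset, draws `iterations` random subject subsets
#' WITHOUT replacement at each size of the (strictly decreasing) schedule and
#' recomputes every summarization, both criteria and the optimal baseline on
#' each subset (the baseline is recomputed on the same subset's rows of
#' `X0`/`Y0`, so methods and ceiling face the same subjects). Raw criteria are
#' averaged over the iterations; the reported `rho_ratio` / `pve_ratio` at
#' each size are ratios of those means, `mean(rho) / mean(rho_opt)` and
#' `mean(pve) / mean(pve_opt)` — a per-iteration ratio would divide by a
#' near-zero `rho_opt` on unlucky subsamples and its average is unstable. The
#' ratio rows carry `sd(raw) / mean(opt)` as their spread, i.e. the raw sd
#' expressed on the ratio scale. The full master sample contributes a
#' single-shot row (`iterations = 1`, `sd = 0`).
#'
#' @param sim A `module_sim`.
#' @param sizes Strictly decreasing subsample sizes, all below `n_master`.
#' @param iterations Subsamples per size (>= 2).
#' @param seed Optional integer seed for the subsampling stream.
#' @param methods Methods to evaluate.
#' @return A tibble of class `subsample_result` with columns `size`, `method`,
#'   `metric` (`rho`, `pve`, `rho_opt`, `pve_opt`, `rho_ratio`, `pve_ratio`),
#'   `mean`, `sd`, `iterations`.
#' @examples
#' sim <- simulate_scenario1(sim_config(p = 10, n_master = 120, seed = 1))
#' subsample_study(sim, sizes = c(60, 30), iterations = 25, seed = 2)
#' @export
subsample_study <- function(sim, sizes = c(500, 300, 200, 100, 50),
                            iterations = 1000, seed = NULL,
                            methods = c("netshy", "nonet")) {
  stopifnot(inherits(sim, "module_sim"))
  methods <- match.arg(methods, c("netshy", "nonet", "hub"), several.ok = TRUE)
  Xstar <- sim$X %*% laplacian(sim$net)$matrix
  attr(Xstar, "hub") <- find_hub(sim$net)
  X <- sim$X
  X0 <- sim$X0
  y0 <- sim$y0
  out <- run_subsampling(
    nrow(X), sizes, iterations, seed,
    function(idx) eval_subset(X, Xstar, X0, y0, idx, methods),
    methods
  )
  structure(out,
    class = c("subsample_result", class(out)),
    schedule = sizes, seed = seed, mode = "simulation"
  )
}

# Real-data-mode subset evaluation: raw |corr| only, no truth available.
eval_subset_raw <- function(X, Xstar, y, idx, methods) {
  ys <- y[idx]
  out <- lapply(methods, function(method) {
    z <- switch(method,
      nonet = pc1_core(X[idx, , drop = FALSE])$scores,
      netshy = pc1_core(Xstar[idx, , drop = FALSE])$scores,
      hub = X[idx, attr(Xstar, "hub") %||% 1L],
      abort(sprintf("Unknown method '%s'.", method), class = "netshy_invalid_argument")
    )
    c(rho = phenotype_correlation(z, ys))
  })
  names(out) <- methods
  out
}

#' Subsampling robustness on observed data
#'
#' The real-data variant of [subsample_study()]: when no noise-free `X0` is
#' available, neither the PVE criterion nor the optimal baseline can be
#' computed, so the study reports the raw absolute correlation of each
#' summarization with the observed phenotype, per subsample size. Robustness
#' is then judged by how slowly a method's mean correlation drops as the
#' sample size decreases.
#'
#' @param X Observed profile matrix.
#' @param net A [module_network()] aligned with `X`.
#' @param y Observed length-`n` phenotype.
#' @inheritParams subsample_study
#' @return A `subsample_result` tibble whose only metric is `rho`.
#' @export
real_data_robustness <- function(X, net, y, sizes = c(500, 300, 200, 100, 50),
                                 iterations = 1000, seed = NULL,
                                 methods = c("netshy", "nonet")) {
  X <- as_profile_matrix(X)
  net <- as_module_network(net)
  check_alignment(X, net)
  methods <- match.arg(methods, c("netshy", "nonet", "hub"), several.ok = TRUE)
  if (length(y) != nrow(X)) {
    abort("`y` must have one entry per subject.", class = "netshy_invalid_argument")
  }
  Xstar <- X %*% laplacian(net)$matrix
  attr(Xstar, "hub") <- find_hub(net)
  out <- run_subsampling(
    nrow(X), sizes, iterations, seed,
    function(idx) eval_subset_raw(X, Xstar, y, idx, methods),
    methods
  )
  structure(out,
    class = c("subsample_result", class(out)),
    schedule = sizes, seed = seed, mode = "real_data"
  )
}

#' Drop in mean correlation across a subsampling schedule
#'
#' Convenience summary of a robustness study: for each method, the full-size
#' value minus the mean at the smallest subsample size, for each metric. A
#' smaller drop means a more robust summarization.
#'
#' @param result A `subsample_result`.
#' @return A tibble with columns `method`, `metric`, `full`, `smallest`,
#'   `drop`.
#' @export
dropping_rate <- function(result) {
  stopifnot(inherits(result, "subsample_result"))
  full_size <- max(result$size)
  min_size <- min(result$size)
  dplyr::inner_join(
    dplyr::select(
      dplyr::filter(result, .data$size == full_size),
      "method", "metric",
      full = "mean"
    ),
    dplyr::select(
      dplyr::filter(result, .data$size == min_size),
      "method", "metric",
      smallest = "mean"
    ),
    by = c("method", "metric")
  ) |>
    dplyr::mutate(drop = .data$full - .data$smallest)
}

#' Bootstrap test for the difference of two phenotype correlations
#'
#' Compares the absolute phenotype correlations of the topology-aware and the
#' plain first-PC summarization on the same observed data. Subjects are
#' resampled WITH replacement `B` times; within each resample both scores are
#' recomputed and the difference
#' `Delta_b = |corr(Z_netshy, y)| - |corr(Z_nonet, y)|` recorded. The
#' two-sided p-value is `2 * min(frac(Delta_b <= 0), frac(Delta_b >= 0))`,
#' floored at `1/B` and capped at 1. Degenerate resamples (constant phenotype
#' or constant profiles) are redrawn and counted.
#'
#' @param X Observed profile matrix.
#' @param net A [module_network()] aligned with `X`.
#' @param y Observed phenotype.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Optional integer seed.
#' @param methods Length-2 character vector naming the two summarizations to
#'   contrast (the difference is method 1 minus method 2).
#' @return A list of class `boot_cor_diff`: `p_value`, `observed` (full-sample
#'   difference), `diffs` (length `B`), `B`, `n_redrawn`.
#' @export
bootstrap_correlation_difference <- function(X, net, y, B = 1000, seed = NULL,
                                             methods = c("netshy", "nonet")) {
  X <- as_profile_matrix(X)
  net <- as_module_network(net)
  check_alignment(X, net)
  if (B < 100) {
    abort("`B` must be at least 100.", class = "netshy_invalid_argument")
  }
  if (length(methods) != 2L) {
    abort("`methods` must name exactly two summarizations.",
      class = "netshy_invalid_argument"
    )
  }
  Xstar <- X %*% laplacian(net)$matrix
  attr(Xstar, "hub") <- find_hub(net)
  n <- nrow(X)
  one_diff <- function(idx) {
    r <- eval_subset_raw(X, Xstar, y, idx, unique(methods))
    r[[methods[1L]]][["rho"]] - r[[methods[2L]]][["rho"]]
  }
  observed <- one_diff(seq_len(n))
  with_seed(seed, {
    diffs <- numeric(B)
    n_redrawn <- 0L
    for (b in seq_len(B)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        ok <- stats::sd(y[idx]) > 0 && sum(apply(X[idx, , drop = FALSE], 2L, stats::sd)) > 0
        if (ok) break
        n_redrawn <- n_redrawn + 1L
      }
      diffs[b] <- one_diff(idx)
    }
    p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
    p <- min(1, max(1 / B, p))
    structure(
      list(
        p_value = p, observed = observed, diffs = diffs,
        B = B, n_redrawn = n_redrawn, methods = methods
      ),
      class = "boot_cor_diff"
    )
  })
}

#' @export
print.boot_cor_diff <- function(x, ...) {
  cat(sprintf(
    "<boot_cor_diff> %s vs %s: observed diff %.4f, p = %.4g (B = %d)\n",
    x$methods[1L], x$methods[2L], x$observed, x$p_value, x$B
  ))
  invisible(x)
}

#' @export
glance.boot_cor_diff <- function(x, ...) {
  tibble::tibble(
    method_1 = x$methods[1L], method_2 = x$methods[2L],
    observed = x$observed, p_value = x$p_value,
    B = x$B, n_redrawn = x$n_redrawn
  )
}
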