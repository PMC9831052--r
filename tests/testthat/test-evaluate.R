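test_that("phenotype correlation is absolute Pearson", {
  y <- c(2, 4, 5, 4, 8, 1)
  expect_equal(phenotype_correlation(y, y), 1)
  expect_equal(phenotype_correlation(-y, y), 1)
  z <- c(1, 3, 2, 5, 4, 6)
  hand <- abs(sum((z - mean(z)) * (y - mean(y))) /
    sqrt(sum((z - mean(z))^2) * sum((y - mean(y))^2)))
  expect_equal(phenotype_correlation(z, y), hand)
  expect_error(phenotype_correlation(rep(1, 6), y), class = "netshy_degenerate_input")
  expect_error(phenotype_correlation(1:3, 1:4), class = "netshy_invalid_argument")
})

test_that("PVE matches its singular-value characterization", {
  # all signal in one column, loading on that column
  X0 <- matrix(0, 10, 4)
  X0[, 3] <- rnorm(10)
  expect_equal(variance_explained(c(0, 0, 1, 0), X0), 1)

  X0 <- random_profiles(12, 5, seed = 40)
  X0c <- sweep(X0, 2, colMeans(X0))
  sv <- svd(X0c)
  top <- sv$d[1]^2 / sum(sv$d^2)
  expect_equal(variance_explained(sv$v[, 1], X0), top, tolerance = 1e-10)
  # variational bound: no unit loading beats the top singular direction
  for (i in 1:50) {
    w <- rnorm(5)
    expect_lte(variance_explained(w / sqrt(sum(w^2)), X0), top + 1e-10)
  }
  expect_error(variance_explained(rep(0, 5), X0), class = "netshy_degenerate_input")
})

test_that("optimal baseline composes the plain PC with both criteria", {
  sim <- tiny_sim(p = 6, n = 40, seed = 41)
  opt <- optimal_baseline(sim$X0, sim$y0)
  s <- summarize_nonet(sim$X0)
  expect_equal(opt$rho_opt, phenotype_correlation(s$scores, sim$y0))
  expect_equal(opt$pve_opt, variance_explained(s$loading, sim$X0))
  expect_equal(opt$summary$method, "opt")

  # noiseless rank-1 truth: both criteria reach their ceiling
  u <- rnorm(30)
  v <- c(0.8, -0.6)
  X0 <- u %o% v
  y <- drop(X0 %*% v)
  o <- optimal_baseline(X0, y)
  expect_equal(o$rho_opt, 1, tolerance = 1e-8)
  expect_equal(o$pve_opt, 1, tolerance = 1e-8)
})

test_that("with no measurement noise the plain PC attains the optimum", {
  sim <- tiny_sim(p = 8, n = 100, sigma_e = 0, seed = 42)
  res <- evaluate_summaries(sim)
  nn <- res[res$method == "nonet", ]
  expect_equal(nn$rho_ratio, 1, tolerance = 1e-8)
  expect_equal(nn$pve_ratio, 1, tolerance = 1e-8)
})

test_that("evaluation is invariant to subject reordering", {
  sim <- tiny_sim(p = 7, n = 60, seed = 43)
  perm <- sample(60)
  sim_p <- sim
  sim_p$X0 <- sim$X0[perm, ]
  sim_p$X <- sim$X[perm, ]
  sim_p$y0 <- sim$y0[perm]
  expect_equal(
    as.data.frame(evaluate_summaries(sim_p)),
    as.data.frame(evaluate_summaries(sim)),
    tolerance = 1e-10
  )
})

test_that("hub method is scored on correlation only", {
  sim <- tiny_sim(p = 6, n = 50, seed = 44)
  res <- evaluate_summaries(sim, methods = c("netshy", "nonet", "hub"))
  hub <- res[res$method == "hub", ]
  expect_true(is.na(hub$pve))
  expect_false(is.na(hub$rho))
  expect_true(all(!is.na(res$pve[res$method != "hub"])))
})

test_that("subsampling near the master size has near-zero spread", {
  sim <- tiny_sim(p = 6, n = 120, seed = 45)
  st <- subsample_study(sim, sizes = c(118), iterations = 12, seed = 1)
  sds <- st$sd[st$size == 118 & st$metric %in% c("rho", "pve")]
  expect_lt(max(sds), 0.02)
})

test_that("subsampling is reproducible and obeys the schedule contract", {
  sim <- tiny_sim(p = 6, n = 100, seed = 46)
  a <- subsample_study(sim, sizes = c(50, 25), iterations = 20, seed = 9)
  b <- subsample_study(sim, sizes = c(50, 25), iterations = 20, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(
    subsample_study(sim, sizes = c(100, 50), iterations = 10, seed = 1),
    class = "netshy_schedule_error"
  )
  expect_error(
    subsample_study(sim, sizes = c(25, 50), iterations = 10, seed = 1),
    class = "netshy_schedule_error"
  )
  # single-shot master row & ratio accounting
  full <- a[a$size == 100, ]
  expect_true(all(full$iterations == 1))
  expect_true(all(full$sd == 0, na.rm = TRUE))
  m50 <- a[a$size == 50 & a$method == "netshy", ]
  opt50 <- a[a$size == 50 & a$method == "opt", ]
  expect_equal(
    m50$mean[m50$metric == "rho_ratio"],
    m50$mean[m50$metric == "rho"] / opt50$mean[opt50$metric == "rho"]
  )
})

test_that("reduced-iteration means agree with larger runs within MC error", {
  sim <- tiny_sim(p = 6, n = 200, seed = 47)
  small <- subsample_study(sim, sizes = c(50), iterations = 100, seed = 2)
  big <- subsample_study(sim, sizes = c(50), iterations = 400, seed = 3)
  for (metric in c("rho", "pve")) {
    for (m in c("netshy", "nonet")) {
      s_row <- small[small$method == m & small$metric == metric & small$size == 50, ]
      b_row <- big[big$method == m & big$metric == metric & big$size == 50, ]
      se <- sqrt(s_row$sd^2 / 100 + b_row$sd^2 / 400)
      expect_lt(abs(s_row$mean - b_row$mean), 4 * se)
    }
  }
})

test_that("PVE ratios never exceed 1 and ratios stay positive", {
  sim <- tiny_sim(p = 8, n = 150, seed = 48)
  st <- subsample_study(sim, sizes = c(75, 40), iterations = 30, seed = 4)
  ratios <- st[st$metric %in% c("pve_ratio", "rho_ratio"), ]
  expect_true(all(ratios$mean > 0))
  expect_true(all(ratios$mean[ratios$metric == "pve_ratio"] <= 1 + 1e-8))
})

test_that("real-data mode reports raw correlations through the same engine", {
  sim <- tiny_sim(p = 6, n = 100, seed = 49)
  st <- subsample_study(sim, sizes = c(40, 20), iterations = 15, seed = 5)
  rd <- real_data_robustness(sim$X, sim$net, sim$y0,
    sizes = c(40, 20),
    iterations = 15, seed = 5
  )
  expect_setequal(unique(rd$metric), "rho")
  sim_rho <- st[st$metric == "rho" & st$method %in% c("netshy", "nonet"), ]
  for (col in c("size", "method", "mean", "sd")) {
    expect_equal(rd[[col]], sim_rho[[col]])
  }
  dr <- dropping_rate(rd)
  expect_named(dr, c("method", "metric", "full", "smallest", "drop"))
  expect_equal(dr$drop, dr$full - dr$smallest)
})

test_that("bootstrap p-values respect their bounds and self-comparison", {
  sim <- tiny_sim(p = 6, n = 60, seed = 50)
  b <- bootstrap_correlation_difference(sim$X, sim$net, sim$y0, B = 100, seed = 6)
  expect_gte(b$p_value, 1 / 100)
  expect_lte(b$p_value, 1)
  expect_length(b$diffs, 100)
  self <- bootstrap_correlation_difference(sim$X, sim$net, sim$y0,
    B = 100,
    seed = 7, methods = c("netshy", "netshy")
  )
  expect_equal(self$p_value, 1)
  expect_true(all(self$diffs == 0))
  expect_error(
    bootstrap_correlation_difference(sim$X, sim$net, sim$y0, B = 50, seed = 1),
    class = "netshy_invalid_argument"
  )
})
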