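test_that("fit satisfies the model invariants", {
  sf <- small_fit()
  fit <- sf$fit
  # W columns centered
  expect_true(all(abs(colMeans(fit$W)) < 1e-8))
  # dispersions positive and bounded
  expect_true(all(fit$phi > 0 & fit$phi <= 1e8))
  # penalized log likelihood non-decreasing (1e-6 relative slack)
  tr <- fit$penalized_loglik_trace
  expect_true(all(diff(tr) >= -1e-6 * abs(tr[-length(tr)])))
  # dimensions
  expect_equal(dim(fit$W), c(ncol(sf$sim$counts), 3))
  expect_equal(dim(fit$alpha), c(3, nrow(sf$sim$counts)))
  # W columns orthogonal after the SVD step
  g <- crossprod(fit$W)
  expect_lt(max(abs(g[upper.tri(g)])) / max(diag(g)), 1e-8)
})

test_that("refitting with the same inputs is bit-reproducible", {
  sf <- small_fit()
  sim <- sf$sim
  fit2 <- suppressWarnings(
    fit_ruv3nb(sim$counts, scenario_M(sim), scenario_controls(sim),
               k = 3, seed = 5L, max_iter = 30))
  expect_identical(sf$fit$W, fit2$W)
  expect_identical(sf$fit$alpha, fit2$alpha)
  expect_identical(sf$fit$phi, fit2$phi)
})

test_that("estimated factors recover the simulated unwanted structure", {
  sf <- small_fit()
  cc <- cancor(sf$fit$W, sf$sim$truth$W_true)$cor
  expect_gte(mean(cc), 0.85)
  expect_gte(cc[1], 0.95)
})

test_that("k is lowered with a warning when controls are scarce", {
  sf <- small_fit()
  sim <- sf$sim
  few <- control_set(scenario_controls(sim)$taxa_ids[1:4], "empirical")
  expect_warning(
    fit <- fit_ruv3nb(sim$counts, scenario_M(sim), few, k = 7,
                      seed = 1, max_iter = 2),
    "lowering k")
  expect_equal(fit$k, 3)
})

test_that("large lambda_b shrinks the factor scores", {
  sf <- small_fit()
  sim <- sf$sim
  fit_big <- suppressWarnings(
    fit_ruv3nb(sim$counts, scenario_M(sim), scenario_controls(sim),
               k = 3, lambda_b = 1e6, seed = 5L, max_iter = 10))
  fit_ref <- suppressWarnings(
    fit_ruv3nb(sim$counts, scenario_M(sim), scenario_controls(sim),
               k = 3, lambda_b = 5, seed = 5L, max_iter = 10))
  expect_lt(norm(fit_big$W, "F"), norm(fit_ref$W, "F"))
})

test_that("PAC is the identity when a taxon has zero loadings", {
  # alpha = 0 for every taxon: reference mean equals fitted mean
  sf <- small_fit()
  fit <- sf$fit
  fit0 <- fit
  fit0$alpha[] <- 0
  adj <- suppressWarnings(
    percentile_adjusted_counts(fit0, sf$sim$counts, mode = "mid"))
  expect_identical(adj$pac, sf$sim$counts)
  adjr <- suppressWarnings(
    percentile_adjusted_counts(fit0, sf$sim$counts,
                               mode = "randomized", seed = 1))
  expect_identical(adjr$pac, sf$sim$counts)
})

test_that("mid-mode PAC is monotone in the observed count", {
  sf <- small_fit()
  fit <- sf$fit
  cm <- sf$sim$counts
  # bump one cell upward; its PAC cannot decrease
  i <- which(rowSums(cm) > 50)[1]
  cm2 <- cm
  cm2[i, 3] <- cm2[i, 3] + 25L
  a1 <- percentile_adjusted_counts(fit, cm)
  a2 <- percentile_adjusted_counts(fit, cm2)
  expect_gte(a2$pac[i, 3], a1$pac[i, 3])
})

test_that("PAC aligns samples whose difference is purely unwanted", {
  # two samples, same biology; sample 2 has a 4x multiplicative unwanted
  # effect on the taxon; counts 10 and 40 should map to similar PACs
  fit <- structure(list(
    W = matrix(c(0.5, -0.5), 2, 1, dimnames = list(c("s1", "s2"), "W1")),
    alpha = matrix(c(-log(4) / 1, 0), 1, 2,
                   dimnames = list("W1", c("tx", "bg"))),
    beta = matrix(0, 1, 2, dimnames = list("G1", c("tx", "bg"))),
    zeta = c(tx = log(20), bg = log(20)),
    phi = c(tx = 0.1, bg = 0.1),
    M = matrix(1L, 2, 1, dimnames = list(c("s1", "s2"), "G1")),
    k = 1L), class = "ruv_fit")
  # mu_hat: s1 = 20*exp(-0.5*log4) = 10, s2 = 20*exp(+0.5*log4) = 40
  cm <- matrix(c(10L, 20L, 40L, 20L), 2, 2,
               dimnames = list(c("tx", "bg"), c("s1", "s2")))
  adj <- percentile_adjusted_counts(fit, cm)
  expect_lte(abs(adj$pac["tx", "s1"] - adj$pac["tx", "s2"]), 2)
})

test_that("PAC preserves zeros when the reference mean is not larger", {
  sf <- small_fit()
  fit <- sf$fit
  cm <- sf$sim$counts
  adj <- percentile_adjusted_counts(fit, cm)
  mu_hat <- ruv_fitted_mean(fit)
  mu_ref <- ruv_fitted_mean(fit, W_ref = matrix(0, nrow(fit$W), fit$k))
  zero_dir <- cm == 0 & mu_ref <= mu_hat
  expect_true(all(adj$pac[zero_dir] == 0))
})

test_that("randomized mode requires a seed and mid mode is deterministic", {
  sf <- small_fit()
  expect_error(percentile_adjusted_counts(sf$fit, sf$sim$counts,
                                          mode = "randomized"),
               "seed")
  a <- percentile_adjusted_counts(sf$fit, sf$sim$counts)
  b <- percentile_adjusted_counts(sf$fit, sf$sim$counts)
  expect_identical(a$pac, b$pac)
})

test_that("control-set sensitivity is ordered by exclusion size", {
  sf <- small_fit()
  sim <- sf$sim
  ctrl <- scenario_controls(sim)$taxa_ids
  fit_full <- sf$fit
  drop2 <- control_set(setdiff(ctrl, ctrl[1:2]), "empirical")
  drop_many <- control_set(ctrl[1:8], "empirical")   # keeps only 8
  f2 <- suppressWarnings(fit_ruv3nb(sim$counts, scenario_M(sim), drop2,
                                    k = 3, seed = 5L, max_iter = 30))
  fm <- suppressWarnings(fit_ruv3nb(sim$counts, scenario_M(sim), drop_many,
                                    k = 3, seed = 5L, max_iter = 30))
  d_small <- sum((1 - cancor(fit_full$W, f2$W)$cor)^2)
  d_large <- sum((1 - cancor(fit_full$W, fm$W)$cor)^2)
  expect_lt(d_small, d_large)
})

test_that("ruv_fit serialization round-trips through TSV + JSON", {
  sf <- small_fit()
  out <- withr::local_tempdir()
  write_ruv_fit(sf$fit, out)
  W <- as.matrix(read.table(file.path(out, "W.tsv"), header = TRUE,
                            sep = "\t", row.names = 1, check.names = FALSE))
  expect_equal(unname(W), unname(sf$fit$W), tolerance = 1e-12)
  fj <- jsonlite::read_json(file.path(out, "fit.json"))
  expect_equal(fj$k, 3)
  adj <- percentile_adjusted_counts(sf$fit, sf$sim$counts)
  write_adjusted_counts(adj, out)
  pac <- read_counts(file.path(out, "pac.tsv"))
  expect_identical(pac, adj$pac)
})
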