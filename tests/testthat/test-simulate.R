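test_that("Rice sampler matches closed-form moments", {
  set.seed(1)
  # nu = 0 reduces to Rayleigh: mean sigma * sqrt(pi/2)
  x <- rrice(1e6, 0, 2)
  expect_equal(mean(x), 2 * sqrt(pi / 2), tolerance = 0.005)
  # second moment is exact for any nu: E[X^2] = nu^2 + 2 sigma^2
  y <- rrice(1e6, 3, 1.5)
  expect_equal(mean(y^2), 3^2 + 2 * 1.5^2, tolerance = 0.01)
  expect_true(all(y >= 0))
  expect_error(rrice(10, 1, -1), "sigma")
})

test_that("generator draws match the stated distributions", {
  ds <- suppressWarnings(simulate_dataset(
    simulation_config("normal", n_proteins = 1e5, n_per_group = 2, seed = 3)))
  tr <- ds$truth
  expect_equal(mean(tr$mu), 15, tolerance = 3 * sqrt(3) / sqrt(1e5) * 4)
  expect_equal(sd(tr$mu), sqrt(3), tolerance = 0.02)
  expect_equal(mean(tr$lambda), 0.5, tolerance = 0.01)
  expect_equal(mean(tr$delta), 0, tolerance = 0.02)
  expect_equal(mean(tr$tau), 5, tolerance = 0.03)       # Gamma(10, scale .5)
  expect_true(all(tr$tau > 0))

  dg <- suppressWarnings(simulate_dataset(
    simulation_config("gamma", n_proteins = 1e5, n_per_group = 2, seed = 4)))
  expect_equal(mean(dg$truth$mu), 56.25 * 0.2667, tolerance = 0.03)
  expect_equal(sd(dg$truth$mu), sqrt(56.25) * 0.2667, tolerance = 0.02)
  # moment matching at a near-zero treatment mean gives an extremely skewed
  # Gamma whose draws can underflow to numeric 0, hence >= not >
  expect_true(all(dg$matrix$values[dg$matrix$observed] >= 0))

  dr <- simulate_dataset(
    simulation_config("rician", n_proteins = 5000, n_per_group = 2, seed = 5))
  expect_true(all(dr$matrix$values[dr$matrix$observed] >= 0))
})

test_that("detection-limit censoring removes exactly the smallest values", {
  ds <- simulate_dataset(simulation_config(n_proteins = 1000, n_per_group = 5,
                                           seed = 6))
  x <- ds$matrix
  cen <- censor_detection_limit(x, 0.1)
  expect_identical(sum(!cen$observed), as.integer(0.1 * length(x$values)))
  expect_identical(censor_detection_limit(x, 0), x)
  cen3 <- censor_detection_limit(x, 0.3)
  expect_gte(min(cen3$values[cen3$observed]), max(x$values[!cen3$observed]))
  expect_true(all(cen3$values[!cen3$observed] == 0))    # sentinel
  expect_error(censor_detection_limit(cen3, 0.1), "already has missing")
  expect_error(censor_detection_limit(x, 1), "missing_fraction")
})

test_that("the factorial grid enumerates the full design deterministically", {
  g <- generate_benchmark_grid()
  expect_equal(nrow(g), 10800)
  expect_equal(sum(g$family == "normal"), 3600)
  expect_equal(sum(g$family == "gamma"), 3600)
  expect_true(all(g$seed >= 0 & g$seed < 2^31))
  # per-cell seeds differ, replicates differ
  expect_equal(anyDuplicated(g[c("family", "sigma", "missing_fraction",
                                 "n_per_group", "replicate")]), 0L)
  g1 <- generate_benchmark_grid(families = "normal", sigmas = 2,
                                missing_fractions = 0.3, sample_sizes = 5,
                                n_replicates = 1)
  expect_equal(nrow(g1), 1)
  expect_identical(generate_benchmark_grid(base_seed = 9),
                   generate_benchmark_grid(base_seed = 9))
  expect_error(generate_benchmark_grid(families = character(0)), "non-empty")
})

test_that("datasets are bit-reproducible from their config", {
  cfg <- simulation_config("gamma", n_proteins = 50, n_per_group = 5,
                           sigma = 2, missing_fraction = 0.2, seed = 77)
  d1 <- suppressWarnings(simulate_dataset(cfg))
  d2 <- suppressWarnings(simulate_dataset(cfg))
  expect_identical(d1$matrix$values, d2$matrix$values)
  expect_identical(d1$matrix$observed, d2$matrix$observed)
  expect_identical(d1$truth, d2$truth)
})

test_that("model-matched generator honours its hyperparameters", {
  hp <- hyperparams(mu0 = 1, alpha = 4, beta = 3, kappa = 0.5)
  ds <- simulate_from_model(20000, 3, hp, prob_h1 = 0.3, seed = 13)
  expect_equal(mean(ds$truth$lambda), 0.3, tolerance = 0.02)
  expect_equal(mean(ds$truth$mu), 1, tolerance = 0.05)
  # E[sigma^2] = beta/(alpha-1) = 1; pooled within-group residual variance
  v <- ds$matrix$values
  expect_equal(mean((v[, 1] - ds$truth$mu)^2), 1, tolerance = 0.05)
})
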