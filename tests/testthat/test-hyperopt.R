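test_that("standardize centres and scales observed entries per protein", {
  v <- rbind(c(2, 4, 6, NA), c(1, 1, 1, 1), c(5, NA, NA, NA))
  im <- intensity_matrix(v, groups = c("CTRL", "CTRL", "TRT", "TRT"))
  expect_warning(std <- standardize(im), "not \\(fully\\) standardized")
  expect_equal(std$values[1, 1:3], c(-1, 0, 1), ignore_attr = TRUE)
  # zero-variance protein: centred only
  expect_equal(std$values[2, ], rep(0, 4), ignore_attr = TRUE)
  # <2 observations: untouched
  expect_equal(std$values[3, 1], 5, ignore_attr = TRUE)
  expect_setequal(attr(std, "flagged"), c(2L, 3L))
  expect_identical(std$observed, im$observed)

  x <- toy_matrix(n_proteins = 30, seed = 2, missing_fraction = 0.1)
  std <- standardize(x)
  w <- ifelse(std$observed, 1, NA)
  m <- rowMeans(std$values * w, na.rm = TRUE)
  s <- apply(std$values * w, 1, sd, na.rm = TRUE)
  expect_true(all(abs(m) < 1e-10))
  expect_true(all(abs(s - 1) < 1e-10))
  # idempotence
  std2 <- standardize(std)
  expect_equal(std2$values, std$values, tolerance = 1e-12)
})

test_that("total_log_marginal is the sum of per-protein mixture logs", {
  x <- standardize(toy_matrix(n_proteins = 10, seed = 4, missing_fraction = 0.2))
  hp <- random_hp(3)
  ev <- protein_evidence(x, hp, "polynomial")
  manual <- sum(log(ev$prior_h1 * exp(ev$log_ml_h1) +
                      (1 - ev$prior_h1) * exp(ev$log_ml_h0)))
  expect_equal(total_log_marginal(x, hp, "polynomial"), manual,
               tolerance = 1e-10)
  # single protein, p = 0.5, ML_H1 = ML_H0: mixture collapses to L
  one <- intensity_matrix(matrix(c(0.5, -0.5, 0.2, -0.2), 1),
                          groups = c("CTRL", "CTRL", "TRT", "TRT"))
  hp0 <- hyperparams(kappa = 1e-12)
  obs <- group_observations(c(0.5, -0.5), c(0.2, -0.2))
  expect_equal(total_log_marginal(one, hp0), log_marginal_h0(obs, hp0),
               tolerance = 1e-6)
})

test_that("objective is finite across random admissible hyperparameters", {
  x <- standardize(toy_matrix(n_proteins = 15, seed = 6, missing_fraction = 0.3))
  b <- default_bounds()
  set.seed(10)
  for (i in 1:100) {
    par <- b$lower + runif(5) * (b$upper - b$lower)
    hp <- hyperparams(mu0 = par[1], alpha = par[2], beta = par[3],
                      kappa = par[4], phi = par[5])
    expect_true(is.finite(total_log_marginal(x, hp)))
  }
})

test_that("fit_hyperparameters improves the objective deterministically", {
  x <- suppressWarnings(standardize(
    simulate_dataset(simulation_config(n_proteins = 120, seed = 8,
                                       missing_fraction = 0.2))$matrix))
  f1 <- fit_hyperparameters(x)
  f2 <- fit_hyperparameters(x)
  expect_gte(f1$objective_value, f1$initial_value)
  expect_identical(f1$hyperparams, f2$hyperparams)      # bit-identical rerun
  expect_identical(f1$objective_value, f2$objective_value)
  expect_identical(f1$hyperparams$tau0, 0)
  # standardization keeps the fitted baseline mean near zero
  expect_gt(f1$hyperparams$mu0, -0.5)
  expect_lt(f1$hyperparams$mu0, 0.5)
})

test_that("with no missing values the objective is invariant to phi", {
  set.seed(12)
  v <- matrix(rnorm(60 * 8), 60)
  x <- standardize(intensity_matrix(v, groups = rep(c("CTRL", "TRT"), each = 4)))
  hp <- hyperparams(phi = 0.05)
  base <- total_log_marginal(x, hp)
  for (phi in c(0.2, 1, 7, 90)) {
    hp2 <- hyperparams(phi = phi)
    expect_equal(total_log_marginal(x, hp2), base, tolerance = 1e-8)
  }
})

test_that("moderate-scale fits recover the generating variance scale", {
  hp_true <- hyperparams(mu0 = 0, alpha = 3, beta = 2, kappa = 2, phi = 1)
  ds <- simulate_from_model(500, 25, hp_true, seed = 21)
  fit <- fit_hyperparameters(ds$matrix)
  # broad recovery band on the implied sigma^2 scale beta/(alpha-1)
  scale_true <- hp_true$beta / (hp_true$alpha - 1)
  scale_fit <- fit$hyperparams$beta / (fit$hyperparams$alpha - 1)
  expect_lt(abs(scale_fit - scale_true) / scale_true, 0.5)
  expect_lt(abs(fit$hyperparams$kappa - hp_true$kappa) / hp_true$kappa, 0.5)
})
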