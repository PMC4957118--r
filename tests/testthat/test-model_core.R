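test_that("missing frequencies are the per-group missing/total ratios", {
  cases <- list(
    list(obs = group_observations(rnorm(3), rnorm(5), 2, 0), want = c(0.4, 0.0)),
    list(obs = group_observations(numeric(0), rnorm(5), 5, 0), want = c(1.0, 0.0)),
    list(obs = group_observations(rnorm(4), rnorm(2), 1, 3), want = c(0.2, 0.6)))
  for (cs in cases)
    expect_equal(unname(missing_frequencies(cs$obs)), cs$want)
  expect_error(missing_frequencies(group_observations(numeric(0), rnorm(2), 0, 1)),
               "at least one sample")
})

test_that("prior_h1 respects its bounds, symmetry and limits", {
  for (form in c("polynomial", "exponential")) {
    # equal frequencies -> exactly 1/2, including phi < 1 (0^phi guard)
    expect_identical(prior_h1(0.3, 0.3, 0.4, form), 0.5)
    expect_identical(prior_h1(0, 0, 2, form), 0.5)
    # limits at intermediate |df|
    expect_equal(prior_h1(0.5, 0, 1e6, form), 0.5, tolerance = 1e-4)
    expect_equal(prior_h1(0.5, 0, 1e-6, form), 1, tolerance = 1e-4)
    # extreme missingness in one group only
    expect_equal(prior_h1(1, 0, 1e-6, form), 1, tolerance = 1e-4)
    set.seed(7)
    for (i in 1:50) {
      a <- runif(1); b <- runif(1); phi <- runif(1, 0.05, 20)
      p <- prior_h1(a, b, phi, form)
      expect_gte(p, 0.5); expect_lte(p, 1)
      expect_identical(p, prior_h1(b, a, phi, form))   # symmetry
    }
    # monotone in |df| at fixed phi; monotone non-increasing in phi
    d <- seq(0, 1, by = 0.05)
    p <- prior_h1(d, 0, 1.7, form)
    expect_true(all(diff(p) >= 0))
    phis <- c(0.1, 0.5, 1, 5, 50)
    pp <- vapply(phis, function(f) prior_h1(0.6, 0, f, form), 0)
    expect_true(all(diff(pp) <= 0))
  }
  expect_equal(prior_h1(0.4, 0, 1, "polynomial"), 0.7)
  expect_error(prior_h1(0.2, 0.1, -1), "phi")
  expect_error(prior_h1(1.2, 0.1, 1), "frequencies")
})

test_that("closed-form marginal likelihoods match the quadrature oracles", {
  # frozen single-observation case at y = mu0
  hp <- hyperparams(mu0 = 0, alpha = 2, beta = 1, kappa = 1)
  obs1 <- group_observations(0, numeric(0), 0, 0)
  expect_equal(log_marginal_h0(obs1, hp), quad_log_ml_h0(0, hp),
               tolerance = 1e-4)
  # a handful of randomized small fixtures, both hypotheses
  for (s in 1:5) {
    obs <- random_obs(s); hp <- random_hp(s)
    y <- c(obs$values_ctrl, obs$values_trt)
    expect_equal(log_marginal_h0(obs, hp), quad_log_ml_h0(y - 0, hp),
                 tolerance = 1e-4, label = sprintf("h0 fixture %d", s))
    expect_equal(log_marginal_h1(obs, hp),
                 quad_log_ml_h1(obs$values_ctrl, obs$values_trt, hp),
                 tolerance = 1e-4, label = sprintf("h1 fixture %d", s))
  }
})

test_that("degenerate and empty-group cases behave as documented", {
  hp <- hyperparams()
  empty <- group_observations(numeric(0), numeric(0), 3, 3)
  expect_identical(log_marginal_h0(empty, hp), 0)
  expect_identical(log_marginal_h1(empty, hp), 0)
  # H1 -> H0 as kappa -> 0 with tau0 = 0
  set.seed(3)
  obs <- group_observations(rnorm(5), rnorm(5, 1), 1, 0)
  hp_small <- hyperparams(kappa = 1e-8)
  expect_equal(log_marginal_h1(obs, hp_small), log_marginal_h0(obs, hp_small),
               tolerance = 1e-3)
  # one empty group: H1 likelihood from the other group alone
  one <- group_observations(rnorm(4), numeric(0), 0, 5)
  hp2 <- random_hp(9)
  expect_equal(log_marginal_h1(one, hp2),
               quad_log_ml_h0(one$values_ctrl, hp2), tolerance = 1e-4)
  expect_error(group_observations(c(1, NA), 2), "finite")
})

test_that("posterior_h1 is a stable Bayes update with the right fixed points", {
  expect_equal(posterior_h1(0.5, -3.2, -3.2), 0.5)
  expect_equal(posterior_h1(1, -100, 5), 1)
  expect_equal(posterior_h1(0, 5, -100), 0)
  expect_equal(posterior_h1(0.7, log(2), 0), 1.4 / 1.7)
  expect_equal(posterior_h1(0.7, -1000 + log(2), -1000), 1.4 / 1.7)  # stability
  # monotone in prior at fixed LR, and in LR at fixed prior
  pr <- seq(0.05, 0.95, by = 0.1)
  expect_true(all(diff(posterior_h1(pr, 1.3, 0.2)) > 0))
  lr <- seq(-4, 4, by = 0.5)
  expect_true(all(diff(posterior_h1(0.6, lr, 0)) > 0))
  expect_error(posterior_h1(1.2, 0, 0), "prior")
})

test_that("Bayes factors favour the truth on strongly separated data", {
  hp <- hyperparams(mu0 = 0, alpha = 2, beta = 1, kappa = 25)
  bf_h1 <- bf_h0 <- numeric(200)
  set.seed(11)
  for (r in 1:200) {
    # under H1 with tau = 5 sigma
    obs1 <- group_observations(rnorm(5), rnorm(5, 5), 0, 0)
    bf_h1[r] <- log_marginal_h1(obs1, hp) - log_marginal_h0(obs1, hp)
    # under H0
    obs0 <- group_observations(rnorm(5), rnorm(5), 0, 0)
    bf_h0[r] <- log_marginal_h1(obs0, hp) - log_marginal_h0(obs0, hp)
  }
  expect_gte(mean(bf_h1 > 0), 0.95)
  expect_lte(median(bf_h0), 0)
})

test_that("protein_evidence agrees with the scalar API protein by protein", {
  x <- toy_matrix(n_proteins = 12, seed = 5, missing_fraction = 0.2)
  hp <- random_hp(2)
  ev <- protein_evidence(x, hp, "exponential")
  expect_identical(ev$id, rownames(x$values))
  trt <- x$groups == "TRT"
  for (i in seq_len(nrow(x$values))) {
    oc <- x$observed[i, !trt]; ot <- x$observed[i, trt]
    obs <- group_observations(x$values[i, !trt][oc], x$values[i, trt][ot],
                              sum(!oc), sum(!ot))
    f <- missing_frequencies(obs)
    expect_equal(ev$f_ctrl[i], unname(f[1]))
    expect_equal(ev$log_ml_h0[i], log_marginal_h0(obs, hp))
    expect_equal(ev$log_ml_h1[i], log_marginal_h1(obs, hp))
    expect_equal(ev$prior_h1[i], prior_h1(f[1], f[2], hp$phi, "exponential"),
                 ignore_attr = TRUE)
    expect_equal(ev$posterior_h1[i],
                 posterior_h1(ev$prior_h1[i], ev$log_ml_h1[i], ev$log_ml_h0[i]))
  }
})
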