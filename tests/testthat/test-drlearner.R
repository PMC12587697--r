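test_that("pseudo-outcomes match hand evaluation and algebraic identities", {
  expect_equal(pseudo_outcome(y = 1, t = 1, e = 0.5, mu1 = 0.8, mu0 = 0.3),
               0.9, tolerance = 1e-12)
  # zero residual -> plain regression contrast
  expect_equal(pseudo_outcome(y = 0.8, t = 1, e = 0.3, mu1 = 0.8, mu0 = 0.3),
               0.5, tolerance = 1e-12)
  expect_error(pseudo_outcome(1, 1, 1, 0.5, 0.5), "strictly")
  # multi-arm hand example: (0.4 / 0.25) + 0.4 = 2.0
  expect_equal(multiarm_pseudo_outcome(y = 1, t = "a", a = "a", b = "b",
                                       e_a = 0.25, e_b = 0.5,
                                       mu_a = 0.6, mu_b = 0.2),
               2.0, tolerance = 1e-12)
  # t outside the contrast -> regression contrast only
  expect_equal(multiarm_pseudo_outcome(1, "c", "a", "b", 0.3, 0.3, 0.6, 0.2),
               0.4, tolerance = 1e-12)
  expect_equal(multiarm_pseudo_outcome(0.6, "a", "a", "b", 0.3, 0.3,
                                       0.6, 0.2),
               0.4, tolerance = 1e-12)
})

test_that("the multi-arm contrast reduces to the binary formula", {
  set.seed(1)
  for (i in 1:1000) {
    y <- rbinom(1, 1, 0.5)
    t <- rbinom(1, 1, 0.5)
    e <- runif(1, 0.05, 0.95)
    mu1 <- runif(1); mu0 <- runif(1)
    expect_equal(
      multiarm_pseudo_outcome(y, t, a = 1, b = 0, e_a = e, e_b = 1 - e,
                              mu_a = mu1, mu_b = mu0),
      pseudo_outcome(y, t, e, mu1, mu0), tolerance = 1e-10)
  }
})

test_that("pseudo-outcomes are unbiased under correct nuisances", {
  set.seed(2)
  n <- 1e5
  e <- 0.4; mu1 <- 0.7; mu0 <- 0.45
  t <- rbinom(n, 1, e)
  y <- rbinom(n, 1, ifelse(t == 1, mu1, mu0))
  psi <- pseudo_outcome(y, t, rep(e, n), rep(mu1, n), rep(mu0, n))
  se <- sd(psi) / sqrt(n)
  expect_lt(abs(mean(psi) - (mu1 - mu0)), 3 * se)
})

test_that("cross-fitting honors the fold contract and clips propensities", {
  study <- simulate_study(sim_config(n = 1200, seed = 8))
  obs <- study$observed
  x <- as.matrix(obs[, c("X0", "X2", "X4")])
  nf <- fit_nuisances(x, obs$T, obs$Y, k = 4, seed = 5)
  expect_equal(sort(unique(nf$fold)), 1:4)
  # every arm present in every training fold
  for (f in 1:4) {
    expect_setequal(unique(obs$T[nf$fold != f]), c(0, 1))
  }
  expect_true(all(nf$e >= 0.01 & nf$e <= 0.99))
  expect_equal(rowSums(nf$e)[nf$e[, 1] > 0.01 & nf$e[, 1] < 0.99],
               rep(1, sum(nf$e[, 1] > 0.01 & nf$e[, 1] < 0.99)),
               tolerance = 1e-6)
  # calibration sanity: mean propensity close to the treated fraction
  expect_lt(abs(mean(nf$e[, 2]) - mean(obs$T)), 0.02)
  # the per-unit predictions really come from out-of-fold models: refitting
  # with a different fold seed changes them, but the fold bookkeeping is
  # intact by construction (predictions filled only where fold == f)
  expect_false(anyNA(nf$mu))
})

test_that("effect estimation recovers the oracle ATE and smooths the ITE", {
  study <- simulate_study(sim_config(n = 5000, seed = 42))
  obs <- study$observed
  truth_contrast <- study$truth$p1 - study$truth$p0
  x <- scale(as.matrix(obs[, c("X0", "X2", "X4")]))
  nf <- fit_nuisances(x, obs$T, obs$Y, seed = 11)
  eff <- estimate_effects(nf, x, obs$T, obs$Y)
  # ATE is exactly the mean pseudo-outcome
  expect_equal(eff$ate, mean(eff$pseudo), tolerance = 1e-12)
  expect_lt(abs(eff$ate - mean(truth_contrast)), 0.05)
  # smoothing reduces the error of individual effects
  mse_smooth <- mean((eff$tau_smooth - truth_contrast)^2)
  mse_raw <- mean((eff$pseudo - truth_contrast)^2)
  expect_lt(mse_smooth, mse_raw)
  # constant pseudo-outcomes -> constant smoothed function (regression on a
  # constant target)
  psi_const <- rep(0.3, 200)
  s2 <- ranger::ranger(y = psi_const,
                       x = data.frame(x = rnorm(200)), num.trees = 20,
                       min.node.size = 50, num.threads = 1, seed = 1)
  expect_equal(unique(round(predict(s2, data.frame(x = rnorm(10)),
                                    num.threads = 1)$predictions, 10)),
               0.3)
})

test_that("the estimator is doubly robust to single-nuisance misspecification", {
  errs_out <- errs_prop <- numeric(10)
  for (s in 1:10) {
    study <- simulate_study(sim_config(n = 5000, seed = 40 + s))
    obs <- study$observed
    x <- scale(as.matrix(obs[, c("X0", "X2", "X4")]))
    oracle <- mean(study$truth$p1 - study$truth$p0)
    # deliberately misspecified outcome model, correct propensity
    nf1 <- fit_nuisances(x, obs$T, obs$Y, outcome_learner = "linear",
                         seed = s)
    errs_out[s] <- abs(estimate_effects(nf1, x, obs$T, obs$Y)$ate - oracle)
    # correct outcome model, deliberately misspecified propensity
    nf2 <- fit_nuisances(x, obs$T, obs$Y, propensity_learner = "uniform",
                         seed = s)
    errs_prop[s] <- abs(estimate_effects(nf2, x, obs$T, obs$Y)$ate - oracle)
  }
  expect_lte(median(errs_out), 0.05)
  expect_lte(median(errs_prop), 0.05)
})

test_that("multi-arm nuisances give sum-to-one generalized propensities", {
  set.seed(6)
  n <- 900
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  t <- sample(0:2, n, replace = TRUE, prob = c(0.4, 0.35, 0.25))
  y <- rbinom(n, 1, plogis(0.5 * x[, 1] + 0.3 * (t == 2)))
  nf <- fit_nuisances(x, t, y, k = 3, seed = 7)
  expect_equal(length(nf$arms), 3L)
  expect_equal(unname(rowSums(nf$e)), rep(1, n), tolerance = 0.05)
  eff <- estimate_effects(nf, x, t, y, contrast = c(2, 0))
  expect_true(is.finite(eff$ate))
  expect_equal(eff$contrast, c(2, 0))
})
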