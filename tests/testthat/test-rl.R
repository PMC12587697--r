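test_that("states carry the seven declared components and the overlap rule", {
  s <- build_state(titan_out = c(0.6, 0.7), dr_out = c(0.5, 0.4),
                   u_titan = c(0.1, 0.2), u_dr = c(0.05, 0.1),
                   propensity = c(0.01, 0.5), balance_score = 0.3,
                   eta = 0.05)
  expect_equal(ncol(s), 7L)
  expect_equal(unname(s[, "overlap"]), c(0, 1))
  expect_error(build_state(0.5, 0.5, -1, 0, 0.5, 0), "nonnegative")
})

test_that("blending is the declared convex combination", {
  expect_equal(blend(1, 0.8, 0.3), 0.8)
  expect_equal(blend(0, 0.8, 0.3), 0.3)
  expect_equal(blend(0.6, 0.8, 0.3), 0.6, tolerance = 1e-12)
  expect_warning(out <- blend(1.2, 0.8, 0.3), "clipping")
  expect_equal(out, 0.8)
  # convexity property
  set.seed(1)
  for (i in 1:50) {
    a <- runif(1); y1 <- runif(1); y0 <- runif(1)
    b <- blend(a, y1, y0)
    expect_true(b >= min(y1, y0) - 1e-12 && b <= max(y1, y0) + 1e-12)
  }
})

test_that("reward decomposes into its weighted components", {
  # pure cross-entropy reward on 1000 random pairs
  set.seed(2)
  for (i in 1:1000) {
    p <- runif(1, 0.01, 0.99); y <- rbinom(1, 1, 0.5)
    expect_equal(reward(p, y, weights = c(w_bce = 1, w_dr = 0,
                                          w_balance = 0)),
                 y * log(p) + (1 - y) * log(1 - p), tolerance = 1e-12)
  }
  expect_equal(reward(0.5, 1, weights = c(w_bce = 1, w_dr = 0,
                                          w_balance = 0)),
               -log(2), tolerance = 1e-12)
  # DR term is maximal (zero) when the estimate equals the true effect
  expect_equal(reward(0.5, 1, dr_pseudo = 0.3, tau_true = 0.3,
                      weights = c(w_bce = 0, w_dr = 1, w_balance = 0)), 0)
  expect_equal(reward(0.5, 1, dr_pseudo = 0.8, tau_true = 0.3,
                      weights = c(w_bce = 0, w_dr = 1, w_balance = 0)),
               -0.25, tolerance = 1e-12)
  # balanced covariates give zero penalty
  x <- matrix(rep(c(1, 2), each = 4), 8, 1)
  t <- rep(c(0, 1), 4)
  expect_equal(balance_score(x, t, rep(0.5, 8)), 0, tolerance = 1e-12)
})

test_that("Ornstein-Uhlenbeck steps follow the recursion and revert to the mean", {
  expect_equal(ou_step(0.5, theta = 0.3, mu = 0.5, sigma = 0), 0.5)
  expect_equal(ou_step(1, theta = 0.5, mu = 0, sigma = 0, dt = 1), 0.5)
  set.seed(3)
  n_steps <- 1e5
  x <- numeric(n_steps)
  for (i in 2:n_steps) {
    x[i] <- ou_step(x[i - 1], theta = 0.15, mu = 0.7, sigma = 0.2, dt = 1)
  }
  # stationary mean mu, stationary sd sigma/sqrt(2 theta / dt)
  stat_sd <- 0.2 / sqrt(2 * 0.15)
  expect_lt(abs(mean(x[-(1:1000)]) - 0.7),
            3 * stat_sd / sqrt(n_steps / 50))  # conservative ESS
})

test_that("Polyak updates interpolate parameters elementwise", {
  expect_equal(polyak_update(1, 0, 0.001), 0.001, tolerance = 1e-15)
  cur <- list(a = matrix(1, 2, 2), b = rep(1, 3))
  tgt <- list(a = matrix(0, 2, 2), b = rep(0, 3))
  expect_equal(polyak_update(cur, tgt, 1), cur)
  expect_equal(polyak_update(cur, tgt, 0), tgt)
  half <- polyak_update(cur, tgt, 0.5)
  expect_equal(half$a, matrix(0.5, 2, 2))
  expect_error(polyak_update(list(a = 1:2), list(a = 1:3), 0.5), "shape")
})

test_that("the agent moves the blend weight toward the reward-bearing branch", {
  # asymmetric toy: the first branch is always right, the second always
  # wrong; across seeds the held-out mean blend weight must favor branch 1
  mean_alphas <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 300
    y <- rbinom(n, 1, 0.5)
    titan_p <- ifelse(y == 1, 0.9, 0.1)     # always correct
    dr_p <- ifelse(y == 1, 0.1, 0.9)        # always wrong
    states <- build_state(titan_p, dr_p, u_titan = rep(0.1, n),
                          u_dr = rep(0.1, n), propensity = rep(0.5, n),
                          balance_score = 0)
    rc <- list(titan1 = titan_p, titan0 = titan_p, dr1 = dr_p, dr0 = dr_p,
               t_fact = rep(1, n))
    agent <- train_agent(states, y, rc,
                         agent_config(epochs = 12, actor_lr = 1e-3,
                                      batch_size = 64, seed = s))
    pred <- predict_ensemble(agent, states,
                             list(p1 = titan_p, p0 = titan_p),
                             list(p1 = dr_p, p0 = dr_p))
    mean(pred$alpha)
  })
  expect_gt(median(mean_alphas), 0.5)
})

test_that("agent training is reproducible and inference is deterministic", {
  set.seed(9)
  n <- 120
  y <- rbinom(n, 1, 0.5)
  p1 <- runif(n, 0.2, 0.8); p2 <- runif(n, 0.2, 0.8)
  states <- build_state(p1, p2, rep(0.1, n), rep(0.1, n), rep(0.5, n), 0)
  rc <- list(titan1 = p1, titan0 = p1, dr1 = p2, dr0 = p2,
             t_fact = rep(1, n))
  cfg <- agent_config(epochs = 3, batch_size = 32, seed = 4)
  a1 <- train_agent(states, y, rc, cfg)
  a2 <- train_agent(states, y, rc, cfg)
  expect_identical(a1$alpha_trace, a2$alpha_trace)
  o1 <- predict_ensemble(a1, states, list(p1 = p1, p0 = p1),
                         list(p1 = p2, p0 = p2))
  o2 <- predict_ensemble(a1, states, list(p1 = p1, p0 = p1),
                         list(p1 = p2, p0 = p2))
  expect_identical(o1, o2)
  expect_true(all(o1$alpha >= 0 & o1$alpha <= 1))
  # blended effect equals the difference of the blended arm probabilities
  expect_equal(o1$ite, o1$p1 - o1$p0, tolerance = 1e-12)
  # blended probabilities lie between the branch probabilities
  expect_true(all(o1$p1 >= pmin(p1, p2) - 1e-12 &
                    o1$p1 <= pmax(p1, p2) + 1e-12))
})
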