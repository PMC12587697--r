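test_that("attention weights are row-stochastic with the right limits", {
  set.seed(1)
  Q <- matrix(rnorm(12), 4, 3)
  K <- matrix(rnorm(12), 4, 3)
  A <- attention_weights(Q, K, 3)
  expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-7)
  expect_true(all(A > 0 & A <= 1))
  # zero queries -> uniform weights
  A0 <- attention_weights(matrix(0, 4, 3), K, 3)
  expect_equal(A0, matrix(0.25, 4, 4), tolerance = 1e-12)
  # sequence length 1 -> weight exactly 1
  A1 <- attention_weights(matrix(1, 1, 3), matrix(2, 1, 3), 3)
  expect_equal(as.numeric(A1), 1, tolerance = 1e-12)
  expect_error(attention_weights(Q, K, 0), "positive")
})

test_that("gated memory updates are convex combinations", {
  d <- 6
  gp <- list(W_g = diag(d) * 0, b_g = rep(0, d))
  z <- rep(0.6, d); m <- rep(0.2, d)
  # zero gate logits -> g = 0.5 -> midpoint
  up <- memory_update(z, m, gp)
  expect_equal(up$g, rep(0.5, d))
  expect_equal(up$M_new, rep(0.4, d), tolerance = 1e-12)
  # saturated gates
  gp$b_g <- rep(100, d)
  expect_equal(memory_update(z, m, gp)$M_new, m, tolerance = 1e-10)
  gp$b_g <- rep(-100, d)
  expect_equal(memory_update(z, m, gp)$M_new, z, tolerance = 1e-10)
  # convexity on random draws
  set.seed(2)
  for (i in 1:20) {
    gp <- list(W_g = matrix(rnorm(d * d), d), b_g = rnorm(d))
    z <- rnorm(d); m <- rnorm(d)
    out <- memory_update(z, m, gp)$M_new
    expect_true(all(out >= pmin(z, m) - 1e-12 & out <= pmax(z, m) + 1e-12))
  }
})

test_that("encoder output has the configured width and layer norms are exact", {
  cfg <- tiny_titan_config()
  params <- causalblend:::titan_init_params(cfg, 4)
  x <- matrix(rnorm(12), 3, 4)
  fwd <- causalblend:::titan_encode_batch(params, cfg, x, training = FALSE,
                                          keep_cache = TRUE)
  expect_equal(ncol(fwd$zbar), cfg$hidden)
  expect_equal(nrow(fwd$zbar), 3)
  # the final representation rows are layer-normalized: zero mean, unit var
  Z <- fwd$Z
  expect_lt(max(abs(rowMeans(Z))), 1e-5)
  expect_lt(max(abs(apply(Z, 1, function(r) mean(r^2)) - 1)), 1e-4)
  # eval-mode determinism
  fwd2 <- causalblend:::titan_encode_batch(params, cfg, x, training = FALSE)
  expect_identical(fwd$zbar, fwd2$zbar)
})

test_that("prediction bounds, monotonicity in the output bias, dropout modes", {
  cfg <- tiny_titan_config()
  params <- causalblend:::titan_init_params(cfg, 3)
  model <- structure(list(params = params, memory = numeric(cfg$hidden),
                          config = cfg, feature_names = c("a", "b", "T"),
                          treatment_col = "T"),
                     class = "titan_model")
  x <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "T")))
  p <- titan_predict(model, x)
  expect_true(all(p > 0 & p < 1))
  # zero output weights -> exactly 0.5
  m0 <- model
  m0$params$w_out <- m0$params$w_out * 0
  m0$params$b_out <- 0
  expect_equal(titan_predict(m0, x), rep(0.5, 5))
  # increasing the output bias strictly increases every probability
  m1 <- model
  m1$params$b_out <- model$params$b_out + 1
  expect_true(all(titan_predict(m1, x) > p))
  # eval mode deterministic, dropout mode stochastic
  expect_identical(titan_predict(model, x), p)
  set.seed(1); d1 <- titan_predict(model, x, dropout = TRUE)
  set.seed(2); d2 <- titan_predict(model, x, dropout = TRUE)
  expect_false(identical(d1, d2))
})

test_that("training fits a separable toy and the loss trace decreases", {
  set.seed(3)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("x1", "x2", "T")))
  y <- as.integer(x[, 1] > 0)
  cfg <- titan_config(hidden = 16, layers = 1, heads = 2, epochs = 40,
                      batch_size = 32, lr = 3e-3, patience = 40,
                      profile = "reduced", seed = 11)
  m <- titan_train(x, y, cfg, treatment_col = "T")
  acc <- mean((titan_predict(m, x) > 0.5) == y)
  expect_gt(acc, 0.95)
  expect_lt(m$loss_trace$train_bce[5], m$loss_trace$train_bce[1])
  # per-sample BCE at 0.5 is ln 2
  expect_equal(causalblend:::bce(0.5, 1), log(2), tolerance = 1e-12)
})

test_that("early stopping halts after `patience` non-improving epochs", {
  set.seed(4)
  n <- 120
  x <- matrix(rnorm(n * 2), n, 2, dimnames = list(NULL, c("a", "T")))
  y <- rbinom(n, 1, 0.5)   # pure noise: validation cannot keep improving
  cfg <- titan_config(hidden = 8, layers = 1, heads = 2, epochs = 50,
                      batch_size = 64, lr = 5e-3, patience = 3,
                      profile = "reduced", seed = 2)
  m <- titan_train(x, y, cfg, treatment_col = "T")
  expect_lt(nrow(m$loss_trace), 50)
})

test_that("counterfactual prediction overrides only the treatment input", {
  set.seed(5)
  n <- 80
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "T")))
  x[, "T"] <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(x[, 1] + x[, "T"]))
  m <- titan_train(x, y, tiny_titan_config(seed = 3), treatment_col = "T")
  p_fact <- titan_predict(m, x)
  p_arm <- titan_counterfactual(m, x, 1)
  # factual-arm override reproduces the factual prediction exactly
  treated <- x[, "T"] == 1
  expect_equal(p_arm[treated], p_fact[treated], tolerance = 1e-12)
  expect_true(all(p_arm > 0 & p_arm < 1))
  expect_true(all(titan_counterfactual(m, x, 0) > 0))
})
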