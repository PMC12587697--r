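#' Monte-Carlo dropout sampling of a stochastic predictor
#'
#' Runs `t_mc` stochastic forward passes (dropout active) and returns the
#' per-unit sample matrix, predictive mean, and total variance (second
#' moment minus squared mean, the population form).
#'
#' @param model a `titan_model` (or any object for which `predict_fun` is
#'   supplied).
#' @param x input rows.
#' @param t_mc number of passes (>= 2, default 50).
#' @param seed integer RNG seed for the dropout masks.
#' @param predict_fun function `(model, x)` performing one stochastic pass;
#'   defaults to a dropout-active [titan_predict()].
#' @return list with `samples` (units x t_mc), `mean`, `variance`.
#' @export
mc_dropout <- function(model, x, t_mc = 50, seed = 1L,
                       predict_fun = NULL) {
  assert_that(t_mc >= 2, "`t_mc` must be at least 2")
  predict_fun <- predict_fun %||%
    function(m, xx) titan_predict(m, xx, dropout = TRUE)
  set.seed(seed)
  samples <- vapply(seq_len(t_mc), function(i) predict_fun(model, x),
                    numeric(nrow(as.matrix(x))))
  samples <- matrix(samples, ncol = t_mc)
  m <- rowMeans(samples)
  v <- rowMeans(samples^2) - m^2
  list(samples = samples, mean = m, variance = pmax(v, 0))
}

#' Decompose predictive variance into aleatoric and epistemic parts
#'
#' Aleatoric = mean of the per-pass variances; epistemic = variance of the
#' per-pass means (population form); total = their sum, exactly.
#'
#' @param mu_samples per-pass predictive means (vector, or matrix with one
#'   row per unit).
#' @param sigma2_samples per-pass aleatoric variances, same shape.  When the
#'   model has no aleatoric output head, the Bernoulli variance
#'   `mu (1 - mu)` of each pass is the conventional default.
#' @return tibble with columns `aleatoric`, `epistemic`, `total`.
#' @export
decompose_uncertainty <- function(mu_samples, sigma2_samples = NULL) {
  mu <- if (is.matrix(mu_samples)) mu_samples else matrix(mu_samples, 1)
  if (is.null(sigma2_samples)) sigma2_samples <- mu * (1 - mu)
  s2 <- if (is.matrix(sigma2_samples)) sigma2_samples
        else matrix(sigma2_samples, 1)
  assert_that(all(dim(mu) == dim(s2)), "sample shapes must agree")
  ale <- rowMeans(s2)
  epi <- rowMeans(mu^2) - rowMeans(mu)^2
  tibble::tibble(aleatoric = ale, epistemic = pmax(epi, 0),
                 total = ale + pmax(epi, 0))
}

#' Calibrate the drift threshold from training data
#'
#' Bootstrap-resamples the training rows and takes the 99th percentile of
#' the distance between the training mean vector and the bootstrap mean
#' vectors (on standardized features): a batch whose mean shifts further
#' than sampling noise plausibly allows is flagged.
#'
#' @param train numeric training table.
#' @param n_boot number of bootstrap resamples (default 500).
#' @param prob percentile of the null distances used as threshold.
#' @param batch_size size of the bootstrap batches; must match the size of
#'   the batches that will be screened (defaults to the training size).
#' @param seed integer RNG seed.
#' @return list with `mu`, `sd` (standardization statistics), `delta`.
#' @export
calibrate_drift <- function(train, n_boot = 500, prob = 0.99,
                            batch_size = NULL, seed = 1L) {
  x <- as.matrix(train)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, s, "/")
  batch_size <- batch_size %||% nrow(xs)
  set.seed(seed)
  # null: an independent batch of the deployment size versus an independent
  # resample of the training set (variance 1/batch + 1/n per coordinate)
  d0 <- vapply(seq_len(n_boot), function(b) {
    i1 <- sample.int(nrow(xs), batch_size, replace = TRUE)
    i2 <- sample.int(nrow(xs), nrow(xs), replace = TRUE)
    sqrt(sum((colMeans(xs[i1, , drop = FALSE]) -
                colMeans(xs[i2, , drop = FALSE]))^2))
  }, numeric(1))
  list(mu = mu, sd = s, delta = as.numeric(quantile(d0, prob)))
}

#' Detect concept drift by the mean-vector rule
#'
#' Flags drift when the Euclidean distance between the standardized training
#' mean vector and the batch mean vector exceeds the threshold `delta`.
#' The report carries an adaptation hint (the caller may refresh the
#' blending agent); the default action is logging only.
#'
#' @param train_summary either a numeric training table or a
#'   [calibrate_drift()] result.
#' @param batch nonempty numeric table with the same columns.
#' @param delta drift threshold; defaults to the calibrated value when
#'   `train_summary` comes from [calibrate_drift()], else 1.
#' @return an object of class `drift_report`: tibble row with `distance`,
#'   `delta`, `drift`.
#' @export
detect_drift <- function(train_summary, batch, delta = NULL) {
  if (!is.list(train_summary) || is.data.frame(train_summary)) {
    train_summary <- calibrate_drift(train_summary)
  }
  b <- as.matrix(batch)
  assert_that(nrow(b) > 0, "`batch` must be nonempty")
  assert_that(ncol(b) == length(train_summary$mu), "feature mismatch")
  delta <- delta %||% train_summary$delta %||% 1
  mu_test <- (colMeans(b) - train_summary$mu) / train_summary$sd
  dist <- sqrt(sum(mu_test^2))
  out <- tibble::tibble(distance = dist, delta = delta,
                        drift = dist > delta)
  class(out) <- c("drift_report", class(out))
  out
}
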