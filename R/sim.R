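#' Configuration for the simulated HIV-like causal study
#'
#' Bundles the sample size, seed, latent noise scales and coefficient blocks
#' of the data-generating process.  With the default coefficients and
#' `confound_scale = 1` the generating equations are exactly the benchmark
#' ones: ten exogenous covariates (age-like `X0` through `X9`, with `X7` a
#' latent health factor withheld from the observed table), a geography-driven
#' binary instrument `Z`, a logistic treatment assignment with measured
#' confounding, a viral-load-like post-treatment mediator `M`, an
#' age-modulated individual effect `tau`, and a logistic binary outcome `Y`.
#'
#' @param n positive integer number of units (default 5000).
#' @param seed integer RNG seed (default 42).
#' @param noise_sd_t,noise_sd_y nonnegative Gaussian noise scales added to the
#'   treatment and outcome logits (default 0.5 each).
#' @param noise_sd_m nonnegative mediator noise scale (default 1).
#' @param confound_scale nonnegative multiplier on the confounder coefficients
#'   of the treatment equation, used for robustness sweeps (default 1).
#' @param instrument_coef,treatment_coef,mediator_coef,effect_coef,outcome_coef
#'   named numeric coefficient blocks; defaults reproduce the printed
#'   equations.
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n = 5000, seed = 42,
                       noise_sd_t = 0.5, noise_sd_y = 0.5, noise_sd_m = 1,
                       confound_scale = 1,
                       instrument_coef = c(x8 = 0.8, intercept = -0.5),
                       treatment_coef = c(x0 = 0.02, x2 = 0.6, x4 = 0.5, z = 1.5),
                       mediator_coef = c(intercept = 2, t = -1.5, x3 = 0.5),
                       effect_coef = c(intercept = -1.5, x0 = 0.08),
                       outcome_coef = c(x0 = 0.03, x2 = -0.8, x4 = 0.7,
                                        m = 0.5, x7 = 0.4)) {
  assert_that(length(n) == 1 && is.finite(n) && n >= 1,
              "`n` must be a positive integer")
  assert_that(noise_sd_t >= 0 && noise_sd_y >= 0 && noise_sd_m >= 0,
              "noise scales must be nonnegative")
  assert_that(confound_scale >= 0, "`confound_scale` must be nonnegative")
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         noise_sd_t = noise_sd_t, noise_sd_y = noise_sd_y,
         noise_sd_m = noise_sd_m, confound_scale = confound_scale,
         instrument_coef = instrument_coef, treatment_coef = treatment_coef,
         mediator_coef = mediator_coef, effect_coef = effect_coef,
         outcome_coef = outcome_coef),
    class = "sim_config")
}

#' Draw the exogenous covariates of the simulated study
#'
#' Marginals: `X0 ~ N(50, 10^2)`, `X1 ~ Bern(0.5)`, `X2, X3, X9 ~ N(0, 1)`,
#' `X4 ~ Bern(0.2)`, `X5 ~ Unif(0, 1)`, `X6 ~ Poisson(2)`,
#' `X7 ~ N(0, 1)` (latent), `X8 ~ Bern(0.6)`.
#'
#' @param config a [sim_config()].
#' @return a tibble with columns `X0` through `X9` (including the latent `X7`).
#' @export
draw_covariates <- function(config = sim_config()) {
  n <- config$n
  tibble::tibble(
    X0 = rnorm(n, 50, 10),
    X1 = rbinom(n, 1, 0.5),
    X2 = rnorm(n),
    X3 = rnorm(n),
    X4 = rbinom(n, 1, 0.2),
    X5 = runif(n),
    X6 = rpois(n, 2),
    X7 = rnorm(n),
    X8 = rbinom(n, 1, 0.6),
    X9 = rnorm(n)
  )
}

#' Draw the geography-driven instrument
#'
#' `Pr(Z = 1 | X) = sigmoid(0.8 X8 - 0.5)`; the instrument has no direct path
#' to the outcome.
#'
#' @param x8 binary vector (geography indicator).
#' @param config a [sim_config()] carrying the instrument coefficients.
#' @return tibble with columns `Z` (0/1 draw) and `prob_z` (its probability).
#' @export
assign_instrument <- function(x8, config = sim_config()) {
  assert_that(all(x8 %in% c(0, 1)), "`x8` must be binary")
  b <- config$instrument_coef
  p <- sigmoid(b[["x8"]] * x8 + b[["intercept"]])
  tibble::tibble(Z = rbinom(length(x8), 1, p), prob_z = p)
}

#' Assign treatment from the confounded logistic model
#'
#' Treatment logit: `0.02 (X0 - 50) + s * (0.6 X2 + 0.5 X4) + 1.5 Z + eps_T`,
#' where `s` is `confound_scale` and `eps_T ~ N(0, noise_sd_t^2)`.  The
#' recorded propensity is the sigmoid of the realized logit actually used to
#' draw `T` (so it conditions on the latent logit noise).
#'
#' @param covariates tibble with at least `X0`, `X2`, `X4`.
#' @param z binary instrument vector.
#' @param config a [sim_config()].
#' @return tibble with columns `T` and `propensity`.
#' @export
assign_treatment <- function(covariates, z, config = sim_config()) {
  b <- config$treatment_coef
  s <- config$confound_scale
  n <- nrow(covariates)
  eps_t <- rnorm(n, 0, config$noise_sd_t)
  lin <- b[["x0"]] * (covariates$X0 - 50) +
    s * (b[["x2"]] * covariates$X2 + b[["x4"]] * covariates$X4) +
    b[["z"]] * z + eps_t
  e <- sigmoid(lin)
  tibble::tibble(T = rbinom(n, 1, e), propensity = e)
}

#' Generate the post-treatment mediator
#'
#' `M = 2 - 1.5 T + 0.5 X3 + eps_M`, `eps_M ~ N(0, noise_sd_m^2)`; treatment
#' reduces the mediator (viral-load-like) on average.
#'
#' @param t binary treatment vector.
#' @param x3 numeric covariate.
#' @param config a [sim_config()].
#' @param eps_m optional pre-drawn noise vector (used internally so potential
#'   outcomes share the unit's realized noise).
#' @return numeric mediator vector.
#' @export
generate_mediator <- function(t, x3, config = sim_config(), eps_m = NULL) {
  assert_that(all(t %in% c(0, 1)), "`t` must be binary")
  b <- config$mediator_coef
  if (is.null(eps_m)) eps_m <- rnorm(length(t), 0, config$noise_sd_m)
  b[["intercept"]] + b[["t"]] * t + b[["x3"]] * x3 + eps_m
}

#' Ground-truth individual effect on the outcome logit
#'
#' `tau = -1.5 + 0.08 (X0 - 50)`: the effect is age-modulated, negative on
#' average (treatment lowers the outcome logit at the population center).
#'
#' @param x0 numeric age-like covariate.
#' @param config a [sim_config()].
#' @return numeric vector of logit-scale effects.
#' @export
true_ite <- function(x0, config = sim_config()) {
  b <- config$effect_coef
  b[["intercept"]] + b[["x0"]] * (x0 - 50)
}

#' Generate the binary outcome and both potential-outcome probabilities
#'
#' Outcome logit: `0.03 (X0 - 50) - 0.8 X2 + 0.7 X4 + 0.5 M + 0.4 X7 +
#' T * tau + eps_Y`.  The potential-outcome probability `p(t)` is computed by
#' setting the treatment to `t` *and propagating it through the mediator
#' equation*, holding each unit's realized noise draws (`eps_M`, `eps_Y`)
#' fixed, so `p(1) - p(0)` is the unit's total effect on the probability
#' scale.
#'
#' @param covariates tibble with `X0`, `X2`, `X3`, `X4`, `X7`.
#' @param t binary treatment vector.
#' @param tau logit-scale individual effects (see [true_ite()]).
#' @param config a [sim_config()].
#' @param eps_m,eps_y optional pre-drawn noise vectors.
#' @return tibble with columns `M`, `Y`, `p1`, `p0`.
#' @export
generate_outcome <- function(covariates, t, tau, config = sim_config(),
                             eps_m = NULL, eps_y = NULL) {
  n <- nrow(covariates)
  if (is.null(eps_m)) eps_m <- rnorm(n, 0, config$noise_sd_m)
  if (is.null(eps_y)) eps_y <- rnorm(n, 0, config$noise_sd_y)
  b <- config$outcome_coef
  base <- b[["x0"]] * (covariates$X0 - 50) + b[["x2"]] * covariates$X2 +
    b[["x4"]] * covariates$X4 + b[["x7"]] * covariates$X7 + eps_y
  logit_arm <- function(arm) {
    m_arm <- generate_mediator(rep(arm, n), covariates$X3, config, eps_m = eps_m)
    base + b[["m"]] * m_arm + arm * tau
  }
  p0 <- sigmoid(logit_arm(0))
  p1 <- sigmoid(logit_arm(1))
  m_fact <- generate_mediator(t, covariates$X3, config, eps_m = eps_m)
  p_fact <- ifelse(t == 1, p1, p0)
  tibble::tibble(M = m_fact, Y = rbinom(n, 1, p_fact), p1 = p1, p0 = p0)
}

#' Simulate the benchmark study with known ground truth
#'
#' Returns the pair of tables the benchmark releases: the *observed* dataset
#' (latent `X7` withheld) and the *ground-truth* table carrying the
#' logit-scale effect `tau`, the realized treatment propensity, and the
#' potential-outcome probabilities `p1`, `p0`.  All benchmark metrics in this
#' package compare predicted effects with the probability-scale contrast
#' `p1 - p0` (negative on average under the default coefficients); the sign
#' convention is fixed and documented rather than folded into magnitudes.
#'
#' @param config a [sim_config()].
#' @return an object of class `sim_study`: list with tibbles `observed`
#'   (columns `X0,X1,X2,X3,X4,X5,X6,X8,X9,Z,M,T,Y`) and `truth`
#'   (columns `tau`, `propensity`, `p1`, `p0`).
#' @examples
#' study <- simulate_study(sim_config(n = 200, seed = 1))
#' names(study$observed)
#' mean(study$truth$p1 - study$truth$p0)
#' @export
simulate_study <- function(config = sim_config()) {
  set.seed(config$seed)
  x <- draw_covariates(config)
  inst <- assign_instrument(x$X8, config)
  trt <- assign_treatment(x, inst$Z, config)
  tau <- true_ite(x$X0, config)
  # draw all per-unit noise before any derived quantity so that unit order
  # can never affect values
  eps_m <- rnorm(config$n, 0, config$noise_sd_m)
  eps_y <- rnorm(config$n, 0, config$noise_sd_y)
  out <- generate_outcome(x, trt$T, tau, config, eps_m = eps_m, eps_y = eps_y)
  observed <- dplyr::bind_cols(
    dplyr::select(x, -"X7"),
    tibble::tibble(Z = inst$Z, M = out$M, T = trt$T, Y = out$Y)
  )
  observed <- observed[, c("X0", "X1", "X2", "X3", "X4", "X5", "X6", "X8",
                           "X9", "Z", "M", "T", "Y")]
  truth <- tibble::tibble(tau = tau, propensity = trt$propensity,
                          p1 = out$p1, p0 = out$p0)
  structure(list(observed = observed, truth = truth, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated causal study: n =", nrow(x$observed),
      "(seed", x$config$seed, ")\n")
  cat("  observed columns:", paste(names(x$observed), collapse = ", "), "\n")
  cat("  oracle probability-scale ATE:",
      format(mean(x$truth$p1 - x$truth$p0), digits = 4), "\n")
  invisible(x)
}

#' Write the two study tables as CSV files
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the two file paths.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(observed = file.path(dir, "observed.csv"),
             truth = file.path(dir, "truth.csv"))
  utils::write.csv(study$observed, paths[["observed"]], row.names = FALSE)
  utils::write.csv(study$truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}
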