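#' Cross-fitted nuisance models for doubly robust estimation
#'
#' Fits, per treatment arm, a random-forest outcome regression (100 trees,
#' depth 5, minimum leaf 50, bootstrap resampling) and an L2-regularized
#' logistic propensity model (ridge penalty equivalent to C = 1, multinomial
#' for more than two arms), all under K-fold cross-fitting: each unit's
#' nuisance predictions come from models that never saw its fold.  Folds are
#' stratified by arm so every arm is present in every training fold.
#'
#' @param x numeric matrix/data frame of adjustment covariates (confounders;
#'   post-treatment variables must not be included).
#' @param t treatment vector with two or more levels (coded 0, 1, ... or any
#'   factor-like values).
#' @param y binary outcome vector.
#' @param k number of cross-fitting folds (default 5).
#' @param clip propensity clipping bound eta: stored propensities lie in
#'   `[eta, 1 - eta]` (default 0.01).
#' @param num_trees,max_depth,min_node random-forest hyperparameters
#'   (defaults 100, 5, 50).
#' @param outcome_learner `"forest"` (default) or `"linear"`; the linear
#'   option deliberately misspecifies the outcome regressions (plain
#'   main-effects logistic fit) for robustness experiments.
#' @param propensity_learner `"logistic"` (default) or `"uniform"`; the
#'   uniform option deliberately misspecifies the propensity as the marginal
#'   arm frequency.
#' @param seed integer RNG seed (fold assignment, forests).
#' @return an object of class `nuisance_fit` with per-unit cross-fitted
#'   `mu` (matrix, one column per arm), `e` (clipped propensities, one
#'   column per arm), `fold` assignments, the per-fold fitted models, and
#'   `arms` (sorted unique treatment levels).
#' @export
fit_nuisances <- function(x, t, y, k = 5, clip = 0.01,
                          num_trees = 100, max_depth = 5, min_node = 50,
                          outcome_learner = c("forest", "linear"),
                          propensity_learner = c("logistic", "uniform"),
                          seed = 1L) {
  outcome_learner <- match.arg(outcome_learner)
  propensity_learner <- match.arg(propensity_learner)
  x <- as.matrix(x)
  n <- nrow(x)
  arms <- sort(unique(t))
  n_arms <- length(arms)
  assert_that(n_arms >= 2, "treatment must have at least 2 levels")
  set.seed(seed)
  # arm-stratified fold assignment
  fold <- integer(n)
  for (a in arms) {
    ia <- which(t == a)
    fold[ia] <- sample(rep_len(seq_len(k), length(ia)))
  }
  mu <- matrix(NA_real_, n, n_arms, dimnames = list(NULL, paste0("mu_", arms)))
  e <- matrix(NA_real_, n, n_arms, dimnames = list(NULL, paste0("e_", arms)))
  models <- vector("list", k)
  xdf <- as.data.frame(x)
  for (f in seq_len(k)) {
    tr <- fold != f
    te <- !tr
    fold_models <- list(outcome = list(), propensity = NULL)
    for (ai in seq_len(n_arms)) {
      a <- arms[ai]
      ia <- tr & t == a
      if (outcome_learner == "forest") {
        fit <- ranger::ranger(
          y = y[ia], x = xdf[ia, , drop = FALSE],
          num.trees = num_trees, max.depth = max_depth,
          min.node.size = min_node, replace = TRUE,
          seed = child_seed(seed, paste0("rf", f, a)), num.threads = 1)
        mu[te, ai] <- predict(fit, xdf[te, , drop = FALSE],
                              num.threads = 1)$predictions
      } else {
        fit <- stats::glm.fit(cbind(1, x[ia, , drop = FALSE]), y[ia],
                              family = stats::binomial())
        co <- fit$coefficients
        co[is.na(co)] <- 0
        mu[te, ai] <- sigmoid(as.numeric(cbind(1, x[te, , drop = FALSE]) %*% co))
        fit <- co
      }
      fold_models$outcome[[as.character(a)]] <- fit
    }
    if (propensity_learner == "logistic") {
      if (n_arms == 2) {
        pf <- glmnet::glmnet(x[tr, , drop = FALSE],
                             as.integer(t[tr] == arms[2]),
                             family = "binomial", alpha = 0,
                             lambda = 1 / sum(tr), standardize = TRUE,
                             maxit = 1000, thresh = 1e-4)
        p1 <- as.numeric(predict(pf, x[te, , drop = FALSE],
                                 type = "response"))
        e[te, ] <- cbind(1 - p1, p1)
      } else {
        pf <- glmnet::glmnet(x[tr, , drop = FALSE], factor(t[tr]),
                             family = "multinomial", alpha = 0,
                             lambda = 1 / sum(tr), standardize = TRUE,
                             maxit = 1000, thresh = 1e-4)
        pr <- predict(pf, x[te, , drop = FALSE], type = "response")[, , 1]
        e[te, ] <- pr[, match(as.character(arms), colnames(pr))]
      }
    } else {
      pf <- vapply(arms, function(a) mean(t[tr] == a), numeric(1))
      e[te, ] <- matrix(pf, sum(te), n_arms, byrow = TRUE)
    }
    fold_models$propensity <- pf
    models[[f]] <- fold_models
  }
  e <- clip(e, clip, 1 - clip)
  structure(list(mu = mu, e = e, fold = fold, models = models, arms = arms,
                 clip = clip, outcome_learner = outcome_learner,
                 propensity_learner = propensity_learner,
                 feature_names = colnames(xdf), seed = seed,
                 rf_pars = list(num_trees = num_trees, max_depth = max_depth,
                                min_node = min_node)),
            class = "nuisance_fit")
}

#' @export
print.nuisance_fit <- function(x, ...) {
  cat("nuisance_fit:", length(x$fold), "units,", length(x$arms), "arms,",
      max(x$fold), "folds |", x$outcome_learner, "outcome /",
      x$propensity_learner, "propensity\n")
  invisible(x)
}

# nuisance predictions for new rows: average over the K fold models
predict_nuisances <- function(nf, x_new) {
  xdf <- as.data.frame(as.matrix(x_new))
  colnames(xdf) <- nf$feature_names
  n <- nrow(xdf)
  n_arms <- length(nf$arms)
  mu <- matrix(0, n, n_arms)
  e <- matrix(0, n, n_arms)
  for (f in seq_along(nf$models)) {
    fm <- nf$models[[f]]
    for (ai in seq_len(n_arms)) {
      om <- fm$outcome[[as.character(nf$arms[ai])]]
      mu[, ai] <- mu[, ai] + if (inherits(om, "ranger")) {
        predict(om, xdf, num.threads = 1)$predictions
      } else {
        sigmoid(as.numeric(cbind(1, as.matrix(xdf)) %*% om))
      }
    }
    if (is.numeric(fm$propensity) && !inherits(fm$propensity, "glmnet")) {
      e <- e + matrix(fm$propensity, n, n_arms, byrow = TRUE)
    } else if (n_arms == 2) {
      p1 <- as.numeric(predict(fm$propensity, as.matrix(xdf),
                               type = "response"))
      e <- e + cbind(1 - p1, p1)
    } else {
      pr <- predict(fm$propensity, as.matrix(xdf), type = "response")[, , 1]
      e <- e + pr[, match(as.character(nf$arms), colnames(pr))]
    }
  }
  mu <- mu / length(nf$models)
  e <- clip(e / length(nf$models), nf$clip, 1 - nf$clip)
  dimnames(mu) <- list(NULL, paste0("mu_", nf$arms))
  dimnames(e) <- list(NULL, paste0("e_", nf$arms))
  list(mu = mu, e = e)
}

#' Doubly robust pseudo-outcome (binary treatment)
#'
#' `tau = (t - e) / (e (1 - e)) * (y - mu_t) + mu_1 - mu_0`.  Unbiased for
#' the individual effect when either nuisance is correct; the propensity `e`
#' must already be clipped away from 0 and 1.
#'
#' @param y observed binary outcome.
#' @param t binary treatment (0/1).
#' @param e propensity of treatment 1, strictly inside (0, 1).
#' @param mu1,mu0 outcome-regression predictions under each arm.
#' @return numeric vector of pseudo-outcomes.
#' @export
pseudo_outcome <- function(y, t, e, mu1, mu0) {
  assert_that(all(e > 0 & e < 1), "`e` must lie strictly in (0, 1)")
  assert_that(all(t %in% c(0, 1)), "`t` must be binary")
  mu_t <- ifelse(t == 1, mu1, mu0)
  (t - e) / (e * (1 - e)) * (y - mu_t) + mu1 - mu0
}

#' Doubly robust pseudo-outcome for a multi-arm contrast
#'
#' `tau(a,b) = 1[t=a]/e_a (y - mu_a) - 1[t=b]/e_b (y - mu_b) + mu_a - mu_b`.
#' With two arms and `e_b = 1 - e_a` this reduces algebraically to the
#' binary formula.
#'
#' @param y observed outcome.
#' @param t treatment values.
#' @param a,b the two arms of the contrast (`a != b`).
#' @param e_a,e_b generalized propensities for arms a and b, in (0, 1).
#' @param mu_a,mu_b outcome regressions for arms a and b.
#' @return numeric vector of contrast pseudo-outcomes.
#' @export
multiarm_pseudo_outcome <- function(y, t, a, b, e_a, e_b, mu_a, mu_b) {
  assert_that(!identical(a, b), "`a` and `b` must differ")
  assert_that(all(e_a > 0 & e_a < 1) && all(e_b > 0 & e_b < 1),
              "propensities must lie strictly in (0, 1)")
  (t == a) / e_a * (y - mu_a) - (t == b) / e_b * (y - mu_b) + mu_a - mu_b
}

#' Doubly robust effect estimates
#'
#' Builds the per-unit pseudo-outcomes for the requested contrast, the ATE
#' (their mean, exactly), and a smoothed effect function `tau(x)`: a
#' second-stage random-forest regression of the pseudo-outcomes on the
#' covariates, reusing the outcome-model hyperparameters.  The smoothed
#' function is the default individual-effect estimate; the raw
#' pseudo-outcomes are retained (they are unbiased but high-variance).
#'
#' @param nuisances a [fit_nuisances()] result.
#' @param x covariate matrix used for the second stage (same rows as the fit).
#' @param t,y treatment and outcome vectors (same rows).
#' @param contrast length-2 vector `c(a, b)`; default the two first arms
#'   reversed, i.e. treated-vs-control for a binary treatment.
#' @return an object of class `effect_estimate`: list with `pseudo`
#'   (per-unit pseudo-outcomes), `tau_smooth` (second-stage fitted values),
#'   `ate`, `contrast`, and the fitted `stage2` forest.
#' @export
estimate_effects <- function(nuisances, x, t, y, contrast = NULL) {
  arms <- nuisances$arms
  contrast <- contrast %||% c(arms[2], arms[1])
  a <- contrast[1]; b <- contrast[2]
  ai <- match(a, arms); bi <- match(b, arms)
  assert_that(!any(is.na(c(ai, bi))), "contrast arms must be fitted arms")
  if (length(arms) == 2 && identical(sort(contrast), sort(arms))) {
    sgn <- if (a == arms[2]) 1 else -1
    psi <- sgn * pseudo_outcome(y, as.integer(t == arms[2]),
                                nuisances$e[, 2],
                                nuisances$mu[, 2], nuisances$mu[, 1])
  } else {
    psi <- multiarm_pseudo_outcome(y, t, a, b,
                                   nuisances$e[, ai], nuisances$e[, bi],
                                   nuisances$mu[, ai], nuisances$mu[, bi])
  }
  xdf <- as.data.frame(as.matrix(x))
  rp <- nuisances$rf_pars
  stage2 <- ranger::ranger(
    y = psi, x = xdf, num.trees = rp$num_trees, max.depth = rp$max_depth,
    min.node.size = rp$min_node, replace = TRUE,
    seed = child_seed(nuisances$seed, "stage2"), num.threads = 1)
  tau_smooth <- predict(stage2, xdf, num.threads = 1)$predictions
  structure(list(pseudo = psi, tau_smooth = tau_smooth, ate = mean(psi),
                 contrast = contrast, stage2 = stage2,
                 feature_names = colnames(xdf)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("effect_estimate: contrast", paste(x$contrast, collapse = " vs "),
      "| ATE =", format(x$ate, digits = 4), "\n")
  invisible(x)
}

# smoothed effect (and optionally per-tree draws) for new rows
predict_effect <- function(eff, x_new, all_trees = FALSE) {
  xdf <- as.data.frame(as.matrix(x_new))
  colnames(xdf) <- eff$feature_names
  if (all_trees) {
    pr <- predict(eff$stage2, xdf, predict.all = TRUE,
                  num.threads = 1)$predictions
    list(mean = rowMeans(pr), trees = pr)
  } else {
    predict(eff$stage2, xdf, num.threads = 1)$predictions
  }
}
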