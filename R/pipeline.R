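#' Configuration for a full study run
#'
#' @param data optional list with data frames `observed` and (optionally)
#'   `truth`, or paths to the two CSV files.  When NULL the built-in
#'   simulator supplies the study (`sim`).
#' @param sim a [sim_config()] used in simulation mode.
#' @param treatment,outcome column names (defaults `"T"`, `"Y"`).
#' @param dag_source `"expert"`, `"discover"`, or `"auto"` (stability-based
#'   selection between the two when an expert DAG is available, else the
#'   discovered DAG).
#' @param expert_dag a `causal_dag`, a path to an edge-list file, or NULL.
#'   In simulation mode NULL defaults to the packaged ground-truth graph of
#'   the simulated system (which doubles as the expert graph there).
#' @param split train/validation/test fractions, positive, summing to 1
#'   (default `c(0.64, 0.16, 0.20)`).
#' @param variant component toggle: `"full"`, `"no_rl"` (fixed equal-weight
#'   blend), `"no_titan"` / `"dr_only"`, `"no_dr"` / `"titan_only"`,
#'   `"no_graph"` (all non-outcome columns used, no role selection),
#'   `"mlp"` (single-layer perceptron baseline in place of the attention
#'   predictor).
#' @param titan a [titan_config()]; reduced profile by default.
#' @param agent an [agent_config()].
#' @param discovery a [discovery_config()].
#' @param k_folds nuisance cross-fitting folds (default 5).
#' @param clip propensity clipping bound (default 0.01).
#' @param misspecify `"none"`, `"outcome"` (linear outcome regressions) or
#'   `"propensity"` (marginal propensity), for robustness runs.
#' @param t_mc MC-dropout passes (default 50).
#' @param use_uncertainty,use_drift toggles for the two reporting modules.
#' @param balanced_resampling if TRUE the training split is class-balanced
#'   by resampling the rarer treatment arm (off by default).
#' @param seed master seed; branch-specific seeds are derived from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(data = NULL, sim = sim_config(),
                       treatment = "T", outcome = "Y",
                       dag_source = c("expert", "discover", "auto"),
                       expert_dag = NULL,
                       split = c(0.64, 0.16, 0.20),
                       variant = "full",
                       titan = titan_config(profile = "reduced"),
                       agent = agent_config(),
                       discovery = discovery_config(),
                       k_folds = 5, clip = 0.01,
                       misspecify = c("none", "outcome", "propensity"),
                       t_mc = 50, use_uncertainty = TRUE, use_drift = TRUE,
                       balanced_resampling = FALSE, seed = 1L) {
  dag_source <- match.arg(dag_source)
  misspecify <- match.arg(misspecify)
  assert_that(all(split > 0) && abs(sum(split) - 1) < 1e-8,
              "`split` fractions must be positive and sum to 1")
  assert_that(variant %in% c("full", "no_rl", "no_titan", "no_dr",
                             "titan_only", "dr_only", "no_graph", "mlp"),
              "unknown `variant`")
  structure(list(data = data, sim = sim, treatment = treatment,
                 outcome = outcome, dag_source = dag_source,
                 expert_dag = expert_dag, split = split, variant = variant,
                 titan = titan, agent = agent, discovery = discovery,
                 k_folds = k_folds, clip = clip, misspecify = misspecify,
                 t_mc = as.integer(t_mc), use_uncertainty = use_uncertainty,
                 use_drift = use_drift,
                 balanced_resampling = balanced_resampling,
                 seed = as.integer(seed)),
            class = "run_config")
}

default_expert_dag <- function() {
  read_dag(system.file("extdata", "sim_ground_truth_dag.tsv",
                       package = "causalblend"),
           provenance = "expert")
}

load_run_data <- function(config) {
  if (is.null(config$data)) {
    study <- simulate_study(config$sim)
    return(list(observed = study$observed, truth = study$truth))
  }
  d <- config$data
  obs <- if (is.character(d$observed)) {
    tibble::as_tibble(utils::read.csv(d$observed))
  } else tibble::as_tibble(d$observed)
  tr <- if (is.null(d$truth)) NULL
  else if (is.character(d$truth)) tibble::as_tibble(utils::read.csv(d$truth))
  else tibble::as_tibble(d$truth)
  list(observed = obs, truth = tr)
}

split_indices <- function(n, split, seed) {
  set.seed(seed)
  ord <- sample.int(n)
  n_train <- floor(split[1] * n)
  n_val <- floor(split[2] * n)
  list(train = sort(ord[seq_len(n_train)]),
       val = sort(ord[n_train + seq_len(n_val)]),
       test = sort(ord[(n_train + n_val + 1):n]))
}

# per-arm branch probabilities for the DR branch: anchored at the control
# regression and shifted by the doubly robust smoothed effect, so the
# branch's implied effect equals its DR estimate exactly (up to clipping)
dr_arm_probs <- function(mu0, tau_smooth, eps = 1e-6) {
  p0 <- clip(mu0, eps, 1 - eps)
  p1 <- clip(mu0 + tau_smooth, eps, 1 - eps)
  list(p1 = p1, p0 = p0)
}

#' Run the full estimation study
#'
#' Orchestrates the whole stack on one dataset: preprocessing, causal-graph
#' selection and role-based feature selection (post-treatment variables are
#' excluded from all model inputs), the attention-branch fit, the
#' cross-fitted doubly robust fit, agent training on the validation split,
#' and blended inference with MC-dropout uncertainty, drift check and
#' metrics on the untouched test split.
#'
#' @param config a [run_config()].
#' @return an object of class `causal_study`: list with `predictions`
#'   (one tibble row per test unit), `dag`, `roles`, `metrics` (list of
#'   `causal`, `interval`, `classification` tibbles; causal/interval are
#'   NULL without ground truth), `drift`, `uncertainty`, `alpha_trace`,
#'   `loss_trace`, and a config echo.
#' @examples
#' \donttest{
#' cfg <- run_config(sim = sim_config(n = 800, seed = 7),
#'                   titan = titan_config(profile = "reduced", epochs = 2,
#'                                        hidden = 16, layers = 1, heads = 2,
#'                                        batch_size = 256),
#'                   agent = agent_config(epochs = 2), t_mc = 5, seed = 7)
#' study <- run_study(cfg)
#' study$metrics$causal
#' }
#' @export
run_study <- function(config = run_config()) {
  fits <- fit_branches(config)
  finalize_study(fits, config)
}

# everything up to (and including) branch fits and agent training; shared by
# run_study and run_benchmark so ablation variants reuse identical fits
fit_branches <- function(config) {
  dat <- load_run_data(config)
  obs <- dat$observed
  truth <- dat$truth
  tcol <- config$treatment
  ycol <- config$outcome
  assert_that(all(c(tcol, ycol) %in% names(obs)),
              "declared treatment/outcome columns missing from the data")
  assert_that(length(unique(obs[[tcol]])) >= 2,
              "treatment column is degenerate")
  n <- nrow(obs)
  idx <- split_indices(n, config$split, child_seed(config$seed, "split"))

  # --- preprocessing: continuous columns robust-scaled on the training split
  covar_names <- setdiff(names(obs), c(tcol, ycol))
  is_cont <- vapply(obs[covar_names], function(col) {
    is.numeric(col) && length(unique(col)) > 10
  }, logical(1))
  schema <- stats::setNames(rep("continuous", sum(is_cont)),
                            covar_names[is_cont])
  train_proc <- preprocess(obs[idx$train, ], schema = schema)
  recipe <- attr(train_proc, "recipe")
  proc <- preprocess(obs, recipe = recipe)

  # --- causal graph and roles
  if (config$variant == "no_graph") {
    dag <- NULL
    roles <- list(confounders = covar_names, mediators = character(),
                  instruments = character())
    adj_features <- covar_names
  } else {
    expert <- config$expert_dag
    if (is.character(expert)) expert <- read_dag(expert)
    if (is.null(expert) && is.null(config$data)) expert <- default_expert_dag()
    disc_cfg <- config$discovery
    disc_cfg$seed <- child_seed(config$seed, "discover")
    discovered <- if (config$dag_source %in% c("discover", "auto")) {
      discover_dag(proc[idx$train, ], disc_cfg)
    } else NULL
    dag <- switch(config$dag_source,
      expert = expert %||% abort("`dag_source = 'expert'` needs an expert DAG"),
      discover = discovered,
      auto = if (is.null(expert)) discovered
             else select_dag(expert, discovered, tcol, ycol))
    roles <- extract_roles(dag, tcol, ycol)
    adj_features <- roles$confounders
    if (length(adj_features) == 0) {
      warn("no confounders identified; falling back to all pre-treatment columns")
      adj_features <- setdiff(covar_names, c(roles$mediators))
    }
  }
  model_features <- unique(c(adj_features,
                             if (!config$variant == "no_graph")
                               roles$instruments))
  model_features <- intersect(model_features, names(proc))

  tr <- idx$train
  if (config$balanced_resampling) {
    set.seed(child_seed(config$seed, "rebalance"))
    tab <- table(obs[[tcol]][tr])
    target <- max(tab)
    extra <- unlist(lapply(names(tab), function(a) {
      ia <- tr[obs[[tcol]][tr] == a]
      if (length(ia) < target) sample(ia, target - length(ia), replace = TRUE)
      else integer()
    }))
    tr <- c(tr, extra)
  }

  x_all <- as.matrix(proc[, model_features, drop = FALSE])
  t_all <- obs[[tcol]]
  y_all <- obs[[ycol]]

  # --- attention branch (treatment appended to the inputs)
  titan <- NULL
  if (!config$variant %in% c("no_titan", "dr_only")) {
    tcfg <- config$titan
    tcfg$seed <- child_seed(config$seed, "titan")
    if (config$variant == "mlp") {
      tcfg$layers <- 0L   # conv + memory + readout only: perceptron baseline
    }
    xt <- cbind(x_all, T = t_all)
    colnames(xt) <- c(model_features, "T")
    titan <- titan_train(xt[tr, , drop = FALSE], y_all[tr], tcfg,
                         treatment_col = "T",
                         x_val = xt[idx$val, , drop = FALSE],
                         y_val = y_all[idx$val])
  }

  # --- doubly robust branch (adjustment covariates only)
  nuis <- eff <- NULL
  if (!config$variant %in% c("no_dr", "titan_only")) {
    x_adj <- as.matrix(proc[, adj_features, drop = FALSE])
    nuis <- fit_nuisances(
      x_adj[tr, , drop = FALSE], t_all[tr], y_all[tr],
      k = config$k_folds, clip = config$clip,
      outcome_learner = if (config$misspecify == "outcome") "linear"
                        else "forest",
      propensity_learner = if (config$misspecify == "propensity") "uniform"
                           else "logistic",
      seed = child_seed(config$seed, "nuisance"))
    eff <- estimate_effects(nuis, x_adj[tr, , drop = FALSE],
                            t_all[tr], y_all[tr])
  }

  list(idx = idx, proc = proc, obs = obs, truth = truth, dag = dag,
       roles = roles, adj_features = adj_features,
       model_features = model_features, titan = titan, nuis = nuis,
       eff = eff, x_all = x_all, t_all = t_all, y_all = y_all)
}

# branch outputs (per-arm probabilities, uncertainties, states) for a set of
# row indices
branch_outputs <- function(fits, config, rows, mc_seed_label) {
  tcol <- config$treatment
  x <- fits$x_all[rows, , drop = FALSE]
  t_fact <- fits$t_all[rows]
  out <- list(t_fact = t_fact, y = fits$y_all[rows])
  if (!is.null(fits$titan)) {
    xt <- cbind(x, T = t_fact)
    colnames(xt) <- c(fits$model_features, "T")
    out$titan_p1 <- titan_counterfactual(fits$titan, xt, 1)
    out$titan_p0 <- titan_counterfactual(fits$titan, xt, 0)
    mc <- mc_dropout(fits$titan, xt, t_mc = max(10L, config$t_mc %/% 5L),
                     seed = child_seed(config$seed, mc_seed_label))
    out$u_titan <- sqrt(mc$variance)
  }
  if (!is.null(fits$nuis)) {
    x_adj <- as.matrix(fits$proc[rows, fits$adj_features, drop = FALSE])
    np <- predict_nuisances(fits$nuis, x_adj)
    pe <- predict_effect(fits$eff, x_adj, all_trees = TRUE)
    out$mu0 <- np$mu[, 1]; out$mu1 <- np$mu[, 2]
    out$e1 <- np$e[, 2]
    out$tau_dr <- pe$mean
    out$u_dr <- apply(pe$trees, 1, sd)
    out$dr_trees <- pe$trees
    dp <- dr_arm_probs(out$mu0, out$tau_dr)
    out$dr_p1 <- dp$p1; out$dr_p0 <- dp$p0
    out$dr_pseudo <- pseudo_outcome(out$y, as.integer(t_fact == fits$nuis$arms[2]),
                                    out$e1, out$mu1, out$mu0)
  }
  out
}

# states for the agent (single-branch variants never reach this)
states_from_outputs <- function(bo, balance, eta) {
  build_state(
    titan_out = ifelse(bo$t_fact == 1, bo$titan_p1, bo$titan_p0),
    dr_out = ifelse(bo$t_fact == 1, bo$dr_p1, bo$dr_p0),
    u_titan = bo$u_titan, u_dr = bo$u_dr,
    propensity = bo$e1, balance_score = balance, eta = eta)
}

finalize_study <- function(fits, config) {
  idx <- fits$idx
  has_truth <- !is.null(fits$truth)
  tau_truth_all <- if (has_truth) fits$truth$p1 - fits$truth$p0 else NULL

  balance <- if (!is.null(fits$nuis)) {
    x_tr <- as.matrix(fits$proc[idx$train, fits$adj_features, drop = FALSE])
    np_tr <- list(e1 = predict_nuisances(fits$nuis, x_tr)$e[, 2])
    balance_score(x_tr, fits$t_all[idx$train], np_tr$e1)
  } else 0

  bo_test <- branch_outputs(fits, config, idx$test, "mc-test")
  agent <- NULL
  alpha_trace <- NULL
  both <- !is.null(fits$titan) && !is.null(fits$nuis)
  if (config$variant == "full" && both) {
    bo_val <- branch_outputs(fits, config, idx$val, "mc-val")
    s_val <- states_from_outputs(bo_val, balance, config$agent$overlap_eta)
    acfg <- config$agent
    acfg$seed <- child_seed(config$seed, "agent")
    rc <- list(titan1 = bo_val$titan_p1, titan0 = bo_val$titan_p0,
               dr1 = bo_val$dr_p1, dr0 = bo_val$dr_p0,
               t_fact = bo_val$t_fact, dr_pseudo = bo_val$dr_pseudo,
               tau_true = if (has_truth) tau_truth_all[idx$val] else NULL,
               balance_penalty = balance)
    agent <- train_agent(s_val, bo_val$y, rc, acfg)
    alpha_trace <- agent$alpha_trace
  }

  n_test <- length(idx$test)
  if (both) {
    if (!is.null(agent)) {
      s_test <- states_from_outputs(bo_test, balance, config$agent$overlap_eta)
      pred <- predict_ensemble(agent, s_test,
                               list(p1 = bo_test$titan_p1, p0 = bo_test$titan_p0),
                               list(p1 = bo_test$dr_p1, p0 = bo_test$dr_p0))
      alpha <- pred$alpha
    } else {
      alpha <- rep(0.5, n_test)   # RL ablated: fixed equal-weight blend
    }
    p1 <- blend(alpha, bo_test$titan_p1, bo_test$dr_p1)
    p0 <- blend(alpha, bo_test$titan_p0, bo_test$dr_p0)
  } else if (!is.null(fits$titan)) {
    alpha <- rep(1, n_test)
    p1 <- bo_test$titan_p1; p0 <- bo_test$titan_p0
  } else {
    alpha <- rep(0, n_test)
    p1 <- bo_test$dr_p1; p0 <- bo_test$dr_p0
  }
  ite <- p1 - p0
  y_fact_prob <- ifelse(bo_test$t_fact == 1, p1, p0)

  # --- MC samples of the blended effect: dropout passes on the attention
  # branch, bootstrap tree draws on the DR branch.  The ensemble's
  # predictive distribution is the alpha-weighted *mixture* of the branch
  # sample distributions (the deep-ensemble convention): per pass each
  # unit's sample comes from one branch, drawn with probability alpha.
  # The mixture keeps the branches' disagreement as epistemic spread,
  # whereas averaging the samples pass-by-pass would shrink it away, and it
  # reduces exactly to the single branch at alpha = 0 or 1.
  unc <- NULL
  lower <- upper <- rep(NA_real_, n_test)
  if (config$use_uncertainty) {
    t_mc <- config$t_mc
    set.seed(child_seed(config$seed, "mc-ite"))
    titan_ite_s <- matrix(0, n_test, t_mc)
    dr_ite_smp <- matrix(0, n_test, t_mc)
    fact_samples <- matrix(0, n_test, t_mc)
    xt <- if (!is.null(fits$titan)) {
      m <- cbind(fits$x_all[idx$test, , drop = FALSE], T = bo_test$t_fact)
      colnames(m) <- c(fits$model_features, "T")
      m
    } else NULL
    n_trees <- if (!is.null(fits$nuis)) ncol(bo_test$dr_trees) else 0L
    for (s in seq_len(t_mc)) {
      if (!is.null(fits$titan)) {
        tc1 <- titan_counterfactual(fits$titan, xt, 1, dropout = TRUE)
        tc0 <- titan_counterfactual(fits$titan, xt, 0, dropout = TRUE)
      } else tc1 <- tc0 <- 0
      if (!is.null(fits$nuis)) {
        dr_s <- bo_test$dr_trees[, sample.int(n_trees, 1)]
        dr_s1 <- clip(bo_test$mu0 + dr_s, 1e-6, 1 - 1e-6)
        dr_ite_s <- dr_s1 - bo_test$dr_p0
        dr_fact_s <- ifelse(bo_test$t_fact == 1, dr_s1, bo_test$dr_p0)
      } else {
        dr_ite_s <- dr_fact_s <- rep(0, n_test)
      }
      titan_ite_s[, s] <- tc1 - tc0
      dr_ite_smp[, s] <- dr_ite_s
      fact_samples[, s] <- blend(alpha,
                                 ifelse(bo_test$t_fact == 1, tc1, tc0),
                                 dr_fact_s)
    }
    pick_titan <- matrix(runif(n_test * t_mc), n_test, t_mc) < alpha
    ite_samples <- ifelse(pick_titan, titan_ite_s, dr_ite_smp)
    lower <- apply(ite_samples, 1, quantile, 0.025)
    upper <- apply(ite_samples, 1, quantile, 0.975)
    dec <- decompose_uncertainty(fact_samples)
    unc <- dplyr::bind_cols(
      tibble::tibble(pred_mean = rowMeans(fact_samples),
                     total_variance = rowMeans(fact_samples^2) -
                       rowMeans(fact_samples)^2),
      dec[, c("aleatoric", "epistemic")])
    unc$t_mc <- config$t_mc
  }

  drift <- if (config$use_drift) {
    detect_drift(calibrate_drift(fits$proc[idx$train, fits$model_features],
                                 batch_size = length(idx$test),
                                 seed = child_seed(config$seed, "drift")),
                 fits$proc[idx$test, fits$model_features])
  } else NULL

  metrics <- list(
    classification = classification_metrics(bo_test$y, y_fact_prob),
    causal = if (has_truth) causal_metrics(ite, tau_truth_all[idx$test])
             else NULL,
    interval = if (has_truth && config$use_uncertainty) {
      interval_metrics(lower, upper, tau_truth_all[idx$test])
    } else NULL)

  predictions <- tibble::tibble(
    unit = idx$test,
    t = bo_test$t_fact, y = bo_test$y,
    titan_p1 = if (!is.null(fits$titan)) bo_test$titan_p1 else NA_real_,
    titan_p0 = if (!is.null(fits$titan)) bo_test$titan_p0 else NA_real_,
    dr_p1 = if (!is.null(fits$nuis)) bo_test$dr_p1 else NA_real_,
    dr_p0 = if (!is.null(fits$nuis)) bo_test$dr_p0 else NA_real_,
    alpha = alpha, p1 = p1, p0 = p0, ite = ite,
    ite_lower = lower, ite_upper = upper)
  if (!is.null(unc)) predictions <- dplyr::bind_cols(predictions, unc)

  structure(list(predictions = predictions, dag = fits$dag,
                 roles = fits$roles, metrics = metrics, drift = drift,
                 alpha_trace = alpha_trace,
                 loss_trace = if (!is.null(fits$titan))
                   fits$titan$loss_trace else NULL,
                 split = idx, config = config),
            class = "causal_study")
}

#' @export
print.causal_study <- function(x, ...) {
  cat("causal_study (variant ", x$config$variant, "): ",
      nrow(x$predictions), " test units\n", sep = "")
  if (!is.null(x$metrics$causal)) {
    cm <- x$metrics$causal
    cat("  PEHE ", format(cm$pehe, digits = 4),
        " | ATE error ", format(cm$ate_error, digits = 4),
        " | ITE R2 ", format(cm$ite_r2, digits = 4), "\n", sep = "")
  }
  cm <- x$metrics$classification
  cat("  accuracy ", format(cm$accuracy, digits = 4),
      " | F1 ", format(cm$f1, digits = 4),
      " | AUC ", format(cm$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Benchmark component variants on one simulated study
#'
#' Fits the shared branches once per seed and evaluates the requested
#' variants from those identical fits (so ablating one component can never
#' change another component's fitted parameters), then aggregates the
#' metric tables across seeds.
#'
#' @param config a [run_config()]; its `variant` field is ignored.
#' @param variants character vector of variants to evaluate (see
#'   [run_config()]).
#' @param seeds integer vector of master seeds.
#' @return a tibble with one row per (variant, seed) and the metric columns.
#' @export
run_benchmark <- function(config = run_config(),
                          variants = c("full", "no_rl", "titan_only",
                                       "dr_only"),
                          seeds = 1:3) {
  rows <- list()
  for (sd in seeds) {
    cfg <- config
    cfg$seed <- as.integer(sd)
    cfg$variant <- "full"
    fits <- fit_branches(cfg)
    for (v in variants) {
      cfg_v <- cfg
      cfg_v$variant <- v
      if (v %in% c("no_titan", "dr_only")) {
        fits_v <- fits; fits_v$titan <- NULL
      } else if (v %in% c("no_dr", "titan_only")) {
        fits_v <- fits; fits_v$nuis <- NULL; fits_v$eff <- NULL
      } else fits_v <- fits
      st <- finalize_study(fits_v, cfg_v)
      row <- dplyr::bind_cols(
        tibble::tibble(variant = v, seed = sd),
        st$metrics$classification[, c("accuracy", "f1", "auc")])
      if (!is.null(st$metrics$causal)) {
        row <- dplyr::bind_cols(row, st$metrics$causal)
      }
      if (!is.null(st$metrics$interval)) {
        row <- dplyr::bind_cols(
          row, st$metrics$interval[, c("coverage", "calibration_error")])
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  dplyr::bind_rows(rows)
}
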