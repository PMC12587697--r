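#' Configuration for data-driven causal graph discovery
#'
#' @param bootstrap number of bootstrap resamples `B` per target (default 20).
#' @param tau_sel parent-selection frequency threshold in `(0, 1]`
#'   (default 0.5, a bootstrap majority).
#' @param dbscan_eps,dbscan_min_samples DBSCAN parameters for clustering
#'   features in attribution-summary space (defaults 0.5 and 2; the summary
#'   space is the standardized pair (mean |attribution|, attribution sd)).
#' @param hsic_tol relative tie tolerance for the two directional HSIC values
#'   (default 1e-3); edges within tolerance are flagged ambiguous.
#' @param hsic_max_n orientation subsample cap: HSIC Gram matrices are
#'   quadratic in n, so orientation uses at most this many rows (default 500).
#' @param n_perm permutations used to calibrate each directional HSIC
#'   against its independence null during orientation (default 20).
#' @param seed integer RNG seed.
#' @return an object of class `discovery_config`.
#' @export
discovery_config <- function(bootstrap = 20, tau_sel = 0.5,
                             dbscan_eps = 0.5, dbscan_min_samples = 2,
                             hsic_tol = 1e-3, hsic_max_n = 500,
                             n_perm = 20, seed = 1L) {
  assert_that(bootstrap >= 1, "`bootstrap` must be >= 1")
  assert_that(tau_sel > 0 && tau_sel <= 1, "`tau_sel` must be in (0, 1]")
  assert_that(dbscan_eps > 0, "`dbscan_eps` must be > 0")
  structure(list(bootstrap = as.integer(bootstrap), tau_sel = tau_sel,
                 dbscan_eps = dbscan_eps,
                 dbscan_min_samples = as.integer(dbscan_min_samples),
                 hsic_tol = hsic_tol, hsic_max_n = as.integer(hsic_max_n),
                 n_perm = as.integer(n_perm), seed = as.integer(seed)),
            class = "discovery_config")
}

# plain DBSCAN on a small point matrix (Euclidean); returns integer labels,
# 0 = noise.  min_samples counts the point itself, matching the common
# convention.  Hand-rolled: the point sets here are one row per feature
# (tens of points), so the quadratic scan is trivial.
dbscan_labels <- function(pts, eps, min_samples) {
  n <- nrow(pts)
  d <- as.matrix(dist(pts))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, function(nb) length(nb) >= min_samples, logical(1))
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(neighbors[[i]], i)
    while (length(frontier)) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- union(frontier, setdiff(neighbors[[j]],
                                                         which(labels != 0L)))
      }
    }
  }
  labels
}

#' Bootstrap parent-candidate frequencies for one target variable
#'
#' For each bootstrap resample, a linear model of the target on the remaining
#' features is fitted and each feature's exact linear Shapley attributions
#' are computed.  Features are then clustered by DBSCAN in the standardized
#' (mean |attribution|, attribution sd) summary space — noise points count as
#' singleton clusters — and every member of the cluster with the highest mean
#' absolute attribution is marked as a candidate parent.  The returned
#' frequency is marks / B.
#'
#' @param x numeric data frame or matrix (columns = variables, `p >= 2`,
#'   `n >= 10`).
#' @param target_index column index of the target variable.
#' @param config a [discovery_config()].
#' @return numeric vector of length `p` with selection frequencies in
#'   `[0, 1]`; the self-frequency is 0.
#' @export
bootstrap_parent_candidates <- function(x, target_index,
                                        config = discovery_config()) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  assert_that(p >= 2, "need at least 2 columns")
  assert_that(n >= 10, "need at least 10 rows")
  freq <- stats::setNames(numeric(p), colnames(x))
  if (sd(x[, target_index]) == 0) {
    warn("constant target column: returning all-zero parent frequencies")
    return(freq)
  }
  others <- setdiff(seq_len(p), target_index)
  marks <- numeric(length(others))
  for (b in seq_len(config$bootstrap)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx, others, drop = FALSE]
    yb <- x[idx, target_index]
    fit <- lm.fit(cbind(1, xb), yb)
    beta <- fit$coefficients[-1]
    beta[is.na(beta)] <- 0
    # coefficient t-statistics: a feature can only be marked when its slope
    # clears the Bonferroni-corrected 5% critical value (screening any of
    # p candidates as a parent should control the family-wise error)
    rdf <- max(n - length(beta) - 1L, 1L)
    sigma2 <- sum(fit$residuals^2) / rdf
    xtx_inv <- try(solve(crossprod(cbind(1, xb))), silent = TRUE)
    tstat <- if (inherits(xtx_inv, "try-error")) rep(Inf, length(beta)) else {
      se <- sqrt(pmax(sigma2 * diag(xtx_inv)[-1], 1e-300))
      abs(beta) / se
    }
    t_crit <- stats::qt(1 - 0.025 / length(beta), rdf)
    phi <- linear_shap(beta, fit$coefficients[1], colMeans(xb), xb)
    summ <- cbind(colMeans(abs(phi)), apply(phi, 2, sd))
    summ_std <- scale(summ)
    summ_std[is.na(summ_std)] <- 0
    if (length(others) == 1L) {
      # a single candidate feature cannot be clustered; it is the only
      # possible parent
      marks <- marks + 1
      next
    }
    labels <- dbscan_labels(summ_std, config$dbscan_eps,
                            config$dbscan_min_samples)
    # parent evidence requires the attribution space to separate into
    # groups: if DBSCAN finds no core cluster at all, nothing is marked;
    # otherwise noise points become singleton clusters so an isolated
    # dominant parent can still be selected
    if (max(labels) == 0L) next
    noise <- labels == 0L
    labels[noise] <- max(labels) + seq_len(sum(noise))
    cluster_mean <- tapply(summ[, 1], labels, mean)
    best <- as.integer(names(cluster_mean)[which.max(cluster_mean)])
    sel <- labels == best & tstat >= t_crit
    marks[sel] <- marks[sel] + 1
  }
  freq[others] <- marks / config$bootstrap
  freq
}

#' Orient one undirected edge with the additive-noise / HSIC rule
#'
#' Each variable is regressed on the other (a smoothing spline, falling back
#' to a straight line when the predictor has too few distinct values) and
#' the dependence of each residual on its predictor is measured with HSIC.
#' The direction whose residual is most independent of its predictor wins.
#' Each directional statistic is also calibrated against its own permutation
#' null: when neither residual shows dependence (as in the non-identifiable
#' linear-Gaussian case), or when the two statistics agree within the
#' relative tie tolerance, the edge is flagged ambiguous.
#'
#' @param x_i,x_j equal-length numeric vectors.
#' @param config a [discovery_config()].
#' @return list with `direction` (`"i->j"`, `"j->i"` or `"ambiguous"`) and
#'   the two HSIC values `hsic_ij` (for i -> j, i.e. residual of j given i)
#'   and `hsic_ji`.
#' @export
orient_edge <- function(x_i, x_j, config = discovery_config()) {
  if (sd(x_i) == 0 || sd(x_j) == 0) {
    return(list(direction = "ambiguous", hsic_ij = NA_real_,
                hsic_ji = NA_real_))
  }
  n <- length(x_i)
  if (n > config$hsic_max_n) {
    idx <- seq(1, n, length.out = config$hsic_max_n)
    x_i <- x_i[idx]; x_j <- x_j[idx]
  }
  fit_resid <- function(pred, resp) {
    if (length(unique(pred)) >= 8) {
      sp <- try(stats::smooth.spline(pred, resp, cv = FALSE), silent = TRUE)
      if (!inherits(sp, "try-error")) {
        return(resp - predict(sp, pred)$y)
      }
    }
    stats::residuals(lm(resp ~ pred))
  }
  r_j_given_i <- fit_resid(x_i, x_j)
  r_i_given_j <- fit_resid(x_j, x_i)
  fwd <- hsic_with_null(x_i, r_j_given_i, config$n_perm)
  bwd <- hsic_with_null(x_j, r_i_given_j, config$n_perm)
  h_ij <- fwd$stat   # supports i -> j
  h_ji <- bwd$stat   # supports j -> i
  dep_ij <- h_ij > fwd$null_q   # forward residual still dependent
  dep_ji <- h_ji > bwd$null_q
  tol <- config$hsic_tol * max(h_ij, h_ji, .Machine$double.eps)
  direction <- if (!dep_ij && dep_ji) "i->j"
  else if (dep_ij && !dep_ji) "j->i"
  else if (!dep_ij && !dep_ji) "ambiguous"   # no evidence either way
  else if (h_ij < h_ji - tol) "i->j"
  else if (h_ji < h_ij - tol) "j->i"
  else "ambiguous"
  list(direction = direction, hsic_ij = h_ij, hsic_ji = h_ji)
}

#' Shapley discrepancy of an oriented edge
#'
#' `delta = 1 - R^2(phi_j, x_i)` where `R^2` is the squared Pearson
#' correlation between the parent's attributions and the child's values, so
#' `delta` always lies in `[0, 1]`; weak edges have high discrepancy.
#'
#' @param phi_j attribution vector of the parent feature across samples.
#' @param x_i child values across the same samples.
#' @return a scalar in `[0, 1]`.
#' @export
shap_discrepancy <- function(phi_j, x_i) {
  assert_that(length(phi_j) == length(x_i), "inputs must have equal length")
  if (sd(phi_j) == 0 || sd(x_i) == 0) {
    warn("zero-variance input in shap_discrepancy: returning 1")
    return(1)
  }
  1 - cor(phi_j, x_i)^2
}

#' Discover a causal DAG from a numeric table
#'
#' Pipeline: bootstrap/Shapley/DBSCAN skeleton over all targets, thresholded
#' at `tau_sel`; ANM-HSIC edge orientation (ambiguous edges dropped);
#' discrepancy-guided cycle removal.  Deterministic given the config seed.
#'
#' @param data numeric data frame (`p >= 2` columns for a nonempty result).
#' @param config a [discovery_config()].
#' @return a `causal_dag` with provenance `"discovered"`.
#' @export
discover_dag <- function(data, config = discovery_config()) {
  x <- as.matrix(data)
  p <- ncol(x)
  vars <- colnames(x)
  if (p < 2) return(causal_dag(NULL, nodes = vars, provenance = "discovered"))
  set.seed(config$seed)
  freq <- t(vapply(seq_len(p), function(i) {
    bootstrap_parent_candidates(x, i, config)
  }, numeric(p)))           # freq[i, j]: j selected as parent of target i
  adj_und <- (freq >= config$tau_sel) | t(freq >= config$tau_sel)
  edges <- list()
  delta <- numeric()
  for (i in seq_len(p - 1)) {
    for (j in seq((i + 1), p)) {
      if (!adj_und[i, j]) next
      o <- orient_edge(x[, i], x[, j], config)
      if (o$direction == "ambiguous") next
      if (o$direction == "i->j") { from <- vars[i]; to <- vars[j] }
      else { from <- vars[j]; to <- vars[i] }
      # discrepancy of the oriented edge from the full-sample linear fit
      others <- setdiff(seq_len(p), match(to, vars))
      fit <- lm.fit(cbind(1, x[, others, drop = FALSE]), x[, match(to, vars)])
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      phi <- linear_shap(beta, fit$coefficients[1],
                         colMeans(x[, others, drop = FALSE]),
                         x[, others, drop = FALSE])
      phi_parent <- phi[, match(match(from, vars), others)]
      suppressWarnings(
        delta[paste0(from, "->", to)] <- shap_discrepancy(phi_parent,
                                                          x[, match(to, vars)])
      )
      edges[[length(edges) + 1]] <- tibble::tibble(from = from, to = to)
    }
  }
  g <- causal_dag(dplyr::bind_rows(edges), nodes = vars,
                  provenance = "discovered", acyclic = FALSE)
  remove_cycles(g, delta)
}
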