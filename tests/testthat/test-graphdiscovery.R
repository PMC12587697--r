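test_that("linear Shapley attributions satisfy the closed form and efficiency", {
  beta <- c(2, 3)
  means <- c(1, -1)
  expect_equal(linear_shap(beta, 0.5, means, means), c(0, 0))
  expect_equal(linear_shap(beta, 0.5, means, means + c(1, 0)), c(2, 0))
  # efficiency on random points
  set.seed(1)
  for (i in 1:20) {
    p <- sample(2:5, 1)
    b <- rnorm(p); m <- rnorm(p); x <- rnorm(p); b0 <- rnorm(1)
    phi <- linear_shap(b, b0, m, x)
    expect_equal(sum(phi), sum(b * x) - sum(b * m), tolerance = 1e-10)
  }
})

test_that("linear Shapley equals brute-force subset enumeration for p <= 6", {
  set.seed(2)
  for (i in 1:10) {
    p <- sample(2:6, 1)
    b <- rnorm(p); m <- rnorm(p); x <- rnorm(p); b0 <- rnorm(1)
    expect_equal(linear_shap(b, b0, m, x),
                 shapley_enumeration(b, b0, m, x), tolerance = 1e-10)
  }
})

test_that("bootstrap parent frequencies behave on null and dominant signals", {
  cfg <- discovery_config(bootstrap = 20, seed = 1)
  # dominant parent: X_target = 5 * X_j + tiny noise
  set.seed(3)
  n <- 200
  xj <- rnorm(n)
  x <- cbind(a = rnorm(n), b = rnorm(n), j = xj,
             target = 5 * xj + rnorm(n, 0, 0.01))
  freq <- bootstrap_parent_candidates(x, 4, cfg)
  expect_gte(freq[["j"]], 0.9)
  expect_equal(freq[["target"]], 0)
  expect_true(all(freq >= 0 & freq <= 1))
  # null signal: independent noise columns rarely clear the threshold
  hits <- 0
  for (s in 1:10) {
    set.seed(100 + s)
    xn <- matrix(rnorm(200 * 5), 200, 5,
                 dimnames = list(NULL, letters[1:5]))
    f <- bootstrap_parent_candidates(xn, 1,
                                     discovery_config(bootstrap = 20,
                                                      seed = s))
    if (all(f < 0.5)) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # constant target column warns and returns zeros
  xc <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_warning(fz <- bootstrap_parent_candidates(xc, 2, cfg), "constant")
  expect_equal(unname(fz), c(0, 0))
})

test_that("HSIC detects dependence and vanishes on constants", {
  set.seed(4)
  u <- rnorm(200)
  expect_equal(hsic_statistic(u, rep(1, 200)), 0)
  h_dep <- hsic_statistic(u, u)
  h_perm <- hsic_statistic(u, sample(u))
  expect_gt(h_dep, h_perm)
  expect_gte(hsic_statistic(rnorm(50), rnorm(50)), 0)
  # independent inputs: statistic below its own permutation 95th percentile
  # in most trials
  ok <- 0
  for (s in 1:10) {
    set.seed(200 + s)
    a <- rnorm(100); b <- rnorm(100)
    h0 <- hsic_statistic(a, b)
    null <- vapply(1:39, function(i) hsic_statistic(a, sample(b)),
                   numeric(1))
    if (h0 <= quantile(null, 0.95)) ok <- ok + 1
  }
  expect_gte(ok, 9)
})

test_that("ANM orientation recovers nonlinear directions, flags Gaussian ties", {
  correct <- 0
  for (s in 1:20) {
    set.seed(300 + s)
    x <- runif(400)
    y <- x^3 + 0.1 * runif(400)
    o <- orient_edge(x, y)
    if (o$direction == "i->j") correct <- correct + 1
  }
  expect_gte(correct / 20, 0.8)
  # linear-Gaussian pairs are not identifiable: ambiguous allowed, and the
  # two HSIC values must be close
  set.seed(5)
  a <- rnorm(400)
  b <- 0.8 * a + rnorm(400, 0, 0.6)
  o <- orient_edge(a, b, discovery_config(hsic_tol = 0.2))
  expect_equal(o$direction, "ambiguous")
  expect_equal(orient_edge(rep(1, 50), rnorm(50))$direction, "ambiguous")
})

test_that("shap discrepancy is 1 - squared correlation, bounded in [0, 1]", {
  set.seed(6)
  x <- rnorm(100)
  expect_equal(shap_discrepancy(2 * x + 1, x), 0, tolerance = 1e-12)
  big <- rnorm(10000)
  expect_lt(abs(shap_discrepancy(rnorm(10000), big) - 1), 0.02)
  for (i in 1:10) {
    d <- shap_discrepancy(rnorm(30), rnorm(30))
    expect_true(d >= 0 && d <= 1)
  }
  expect_warning(d1 <- shap_discrepancy(rep(1, 10), rnorm(10)), "variance")
  expect_equal(d1, 1)
})

test_that("cycle removal deletes the highest-discrepancy edge, output acyclic", {
  tri <- causal_dag(tibble::tibble(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")), acyclic = FALSE)
  out <- remove_cycles(tri, c("a->b" = 0.1, "b->c" = 0.2, "c->a" = 0.3))
  expect_false(causalblend:::has_edge(out, "c", "a"))
  expect_true(causalblend:::has_edge(out, "a", "b"))
  expect_true(dag_is_acyclic(out))
  # acyclic input unchanged
  chain <- causal_dag(tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  expect_equal(remove_cycles(chain)$edges, chain$edges)
  # random cyclic graphs always end acyclic
  set.seed(7)
  for (i in 1:5) {
    nodes <- letters[1:5]
    e <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
    e <- e[e$from != e$to, ]
    e <- e[sample(nrow(e), 10), ]
    d <- stats::setNames(runif(10), paste0(e$from, "->", e$to))
    out <- remove_cycles(causal_dag(e, acyclic = FALSE), d)
    expect_true(dag_is_acyclic(out))
  }
})

test_that("role extraction matches the ground-truth graph and definitions", {
  g <- ground_truth_dag()
  roles <- extract_roles(g, "T", "Y")
  expect_equal(roles$confounders, c("X0", "X2", "X4"))
  expect_equal(roles$mediators, "M")
  expect_equal(roles$instruments, "Z")
  # chain T -> M -> Y
  chain <- causal_dag(tibble::tibble(from = c("T", "M"), to = c("M", "Y")))
  r2 <- extract_roles(chain, "T", "Y")
  expect_equal(r2$mediators, "M")
  expect_length(r2$confounders, 0)
  expect_length(r2$instruments, 0)
  # Z -> T, T -> Y
  iv <- causal_dag(tibble::tibble(from = c("Z", "T"), to = c("T", "Y")))
  r3 <- extract_roles(iv, "T", "Y")
  expect_equal(r3$instruments, "Z")
  expect_error(extract_roles(chain, "T", "missing"), "nodes")
})

test_that("stability scoring and selection follow the declared rules", {
  g <- ground_truth_dag()
  expect_equal(stability_score(causalblend:::drop_edge(g, "T", "Y"),
                               "T", "Y"), 1)
  s <- stability_score(g, "T", "Y")
  expect_true(s >= 0 && s <= 1)
  # hand-built DAG where deleting T->Y reclassifies the roles: X -> T -> Y
  # with X -> Y only via T; before deletion X is a confounder? enumerate:
  h <- causal_dag(tibble::tibble(from = c("X", "X", "T", "T", "W"),
                                 to = c("T", "Y", "Y", "M", "T")))
  # before: confounders {X}; mediators {} (M does not reach Y);
  # instruments {W}
  rb <- extract_roles(h, "T", "Y")
  expect_equal(rb$confounders, "X")
  expect_equal(rb$instruments, "W")
  # after deleting T->Y the outcome is only reachable from X directly:
  # confounders {} (no path to Y not through T? X->Y direct stays), so
  # enumerate via the function and compare with the hand mean Jaccard
  ra <- extract_roles(causalblend:::drop_edge(h, "T", "Y"), "T", "Y")
  hand <- mean(c(
    causalblend:::jaccard(rb$confounders, ra$confounders),
    causalblend:::jaccard(rb$mediators, ra$mediators),
    causalblend:::jaccard(rb$instruments, ra$instruments)))
  expect_equal(stability_score(h, "T", "Y"), hand, tolerance = 1e-12)
  # selection: argmax with ties to the expert graph
  d1 <- ground_truth_dag()
  d2 <- causal_dag(tibble::tibble(from = c("Z", "T"), to = c("T", "Y")),
                   provenance = "discovered")
  sel <- select_dag(d1, d2, "T", "Y")
  expect_equal(attr(sel, "source"),
               names(which.max(attr(sel, "scores")[c("expert",
                                                     "discovered")])))
  # equal scores -> expert
  sel2 <- select_dag(d1, d1, "T", "Y")
  expect_equal(attr(sel2, "source"), "expert")
  expect_equal(sel2$edges, d1$edges)
})

test_that("discovery returns a deterministic acyclic DAG on simulated data", {
  study <- simulate_study(sim_config(n = 600, seed = 11))
  dat <- as.data.frame(scale(study$observed))
  cfg <- discovery_config(bootstrap = 10, seed = 21, hsic_max_n = 200)
  g1 <- discover_dag(dat, cfg)
  g2 <- discover_dag(dat, cfg)
  expect_true(dag_is_acyclic(g1))
  expect_identical(g1$edges, g2$edges)
  expect_setequal(g1$nodes, names(dat))
  # single column -> empty graph
  g0 <- discover_dag(dat[, 1, drop = FALSE])
  expect_equal(nrow(g0$edges), 0L)
})

test_that("DAG edge lists round-trip through files", {
  dir <- withr::local_tempdir()
  g <- ground_truth_dag()
  path <- file.path(dir, "dag.tsv")
  write_dag(g, path, graphml = file.path(dir, "dag.graphml"))
  back <- read_dag(path)
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(g$edges$from, g$edges$to))
  expect_true(file.exists(file.path(dir, "dag.graphml")))
  # the packaged fixture carries the same graph
  pkg <- read_dag(system.file("extdata", "sim_ground_truth_dag.tsv",
                              package = "causalblend"))
  expect_setequal(paste(pkg$edges$from, pkg$edges$to),
                  paste(g$edges$from, g$edges$to))
})
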