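#' Directed acyclic causal graph
#'
#' Lightweight container for a causal DAG: a node set, a tibble of directed
#' edges (with optional weights) and a provenance tag.  Acyclicity is
#' enforced at construction and after every mutation.
#'
#' @param edges a data frame with columns `from`, `to` (and optionally
#'   `weight`), or NULL for an edgeless graph.
#' @param nodes character vector of node names; defaults to the union of edge
#'   endpoints.
#' @param provenance one of `"expert"`, `"discovered"`, `"selected"`.
#' @param acyclic if TRUE (default) an error is raised when the edge set
#'   contains a cycle; internal callers that de-cycle afterwards pass FALSE.
#' @return an object of class `causal_dag`.
#' @export
causal_dag <- function(edges = NULL, nodes = NULL, provenance = "expert",
                       acyclic = TRUE) {
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble::tibble(from = character(), to = character(),
                            weight = numeric())
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    edges <- edges[, c("from", "to", "weight")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    assert_that(!any(edges$from == edges$to), "self-loops are not allowed")
  }
  nodes <- sort(unique(c(nodes %||% character(), edges$from, edges$to)))
  assert_that(all(c(edges$from, edges$to) %in% nodes),
              "edge endpoints must be nodes")
  g <- structure(list(nodes = nodes, edges = edges, provenance = provenance),
                 class = "causal_dag")
  if (acyclic) {
    assert_that(dag_is_acyclic(g), "graph contains a cycle")
  }
  g
}

as_igraph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges[, c("from", "to")],
                                directed = TRUE,
                                vertices = data.frame(name = dag$nodes))
}

#' Test whether a directed graph is acyclic
#' @param dag a [causal_dag()] (possibly built with `acyclic = FALSE`).
#' @return TRUE if a topological order exists.
#' @export
dag_is_acyclic <- function(dag) {
  igraph::is_dag(as_igraph(dag))
}

#' @export
print.causal_dag <- function(x, ...) {
  cat("causal_dag (", x$provenance, "): ", length(x$nodes), " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

has_edge <- function(dag, from, to) {
  any(dag$edges$from == from & dag$edges$to == to)
}

drop_edge <- function(dag, from, to) {
  keep <- !(dag$edges$from == from & dag$edges$to == to)
  causal_dag(dag$edges[keep, ], nodes = dag$nodes,
             provenance = dag$provenance, acyclic = FALSE)
}

# nodes reachable from `from` by directed paths, optionally with a node
# removed from the graph (used for "path not through treatment" queries)
reachable <- function(dag, from, exclude = NULL) {
  edges <- dag$edges
  if (!is.null(exclude)) {
    edges <- edges[edges$from != exclude & edges$to != exclude, ]
  }
  out <- character()
  frontier <- from
  while (length(frontier)) {
    nxt <- unique(edges$to[edges$from %in% frontier])
    nxt <- setdiff(nxt, c(out, from))
    out <- c(out, nxt)
    frontier <- nxt
  }
  out
}

#' Remove cycles by deleting the highest-discrepancy edge of each cycle
#'
#' While a directed cycle exists, the cycle edge with the maximal Shapley
#' discrepancy `delta` is deleted (ties broken lexicographically by
#' `(from, to)`).  Cycles are located deterministically starting from the
#' lexicographically smallest node.
#'
#' @param dag a `causal_dag` (may contain cycles, built with
#'   `acyclic = FALSE`).
#' @param delta named numeric vector of per-edge discrepancies; names are
#'   `"from->to"`.  Edges missing from `delta` get discrepancy 0.
#' @return an acyclic `causal_dag`.
#' @export
remove_cycles <- function(dag, delta = numeric()) {
  edge_key <- function(e) paste0(e$from, "->", e$to)
  repeat {
    cyc <- find_cycle(dag)
    if (is.null(cyc)) break
    keys <- paste0(cyc$from, "->", cyc$to)
    d <- delta[keys]
    d[is.na(d)] <- 0
    ord <- order(-d, cyc$from, cyc$to)
    worst <- cyc[ord[1], ]
    dag <- drop_edge(dag, worst$from, worst$to)
  }
  causal_dag(dag$edges, nodes = dag$nodes, provenance = dag$provenance)
}

# return the edges of one directed cycle (tibble from/to) or NULL; DFS from
# the lexicographically smallest node for determinism
find_cycle <- function(dag) {
  edges <- dag$edges
  if (nrow(edges) == 0) return(NULL)
  adj <- split(edges$to, edges$from)
  adj <- lapply(adj, sort)
  state <- stats::setNames(rep(0L, length(dag$nodes)), dag$nodes) # 0 new 1 open 2 done
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    state[[v]] <<- 1L
    path <<- c(path, v)
    for (w in adj[[v]] %||% character()) {
      if (!is.null(found)) break
      if (state[[w]] == 1L) {
        cyc_nodes <- c(path[which(path == w):length(path)], w)
        found <<- tibble::tibble(from = cyc_nodes[-length(cyc_nodes)],
                                 to = cyc_nodes[-1])
      } else if (state[[w]] == 0L) {
        visit(w)
      }
    }
    state[[v]] <<- 2L
    path <<- path[-length(path)]
  }
  for (v in sort(dag$nodes)) {
    if (state[[v]] == 0L) visit(v)
    if (!is.null(found)) break
  }
  found
}

#' Derive variable roles for a declared treatment/outcome pair
#'
#' Confounders are nodes with a directed path to the treatment and a directed
#' path to the outcome that does not pass through the treatment.  Mediators
#' are nodes on a directed treatment-to-outcome path.  Instruments are direct
#' parents of the treatment with no path to the outcome except through the
#' treatment.
#'
#' @param dag a `causal_dag`.
#' @param treatment,outcome node names.
#' @return an object of class `role_assignment`: list with character vectors
#'   `confounders`, `mediators`, `instruments` (pairwise disjoint, excluding
#'   the treatment and the outcome).
#' @export
extract_roles <- function(dag, treatment, outcome) {
  assert_that(all(c(treatment, outcome) %in% dag$nodes),
              "treatment and outcome must be nodes of the DAG")
  others <- setdiff(dag$nodes, c(treatment, outcome))
  to_trt <- vapply(others, function(v) treatment %in% reachable(dag, v),
                   logical(1))
  to_out_not_thru <- vapply(others, function(v) {
    outcome %in% reachable(dag, v, exclude = treatment)
  }, logical(1))
  confounders <- others[to_trt & to_out_not_thru]

  downstream_t <- reachable(dag, treatment)
  mediators <- intersect(others, downstream_t)
  mediators <- mediators[vapply(mediators, function(v) {
    outcome %in% reachable(dag, v)
  }, logical(1))]

  parents_t <- unique(dag$edges$from[dag$edges$to == treatment])
  instruments <- setdiff(parents_t, c(outcome, confounders))
  instruments <- instruments[!vapply(instruments, function(v) {
    outcome %in% reachable(dag, v, exclude = treatment)
  }, logical(1))]

  structure(list(confounders = sort(confounders),
                 mediators = sort(setdiff(mediators, confounders)),
                 instruments = sort(setdiff(instruments, mediators))),
            class = "role_assignment")
}

#' @export
print.role_assignment <- function(x, ...) {
  cat("confounders:", paste(x$confounders, collapse = ", "), "\n")
  cat("mediators:  ", paste(x$mediators, collapse = ", "), "\n")
  cat("instruments:", paste(x$instruments, collapse = ", "), "\n")
  invisible(x)
}

jaccard <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) return(1)
  length(intersect(a, b)) / length(union(a, b))
}

#' Sensitivity-based stability score of a candidate DAG
#'
#' Deletes the direct treatment-to-outcome edge (if present), recomputes the
#' variable roles, and returns the mean Jaccard similarity of the
#' confounder/mediator/instrument sets before versus after the perturbation.
#' A DAG whose causal roles do not depend on that single edge scores 1.
#'
#' @inheritParams extract_roles
#' @return a scalar in `[0, 1]`.
#' @export
stability_score <- function(dag, treatment, outcome) {
  before <- extract_roles(dag, treatment, outcome)
  if (!has_edge(dag, treatment, outcome)) return(1)
  after <- extract_roles(drop_edge(dag, treatment, outcome),
                         treatment, outcome)
  mean(c(jaccard(before$confounders, after$confounders),
         jaccard(before$mediators, after$mediators),
         jaccard(before$instruments, after$instruments)))
}

#' Select the final DAG by stability
#'
#' Returns whichever of the expert and the discovered DAG has the higher
#' [stability_score()]; ties go to the expert DAG (the epidemiological
#' reference).  The returned object is one of the two inputs, unmodified
#' except for its provenance tag.
#'
#' @param expert_dag,discovered_dag two `causal_dag` objects.
#' @inheritParams extract_roles
#' @return the selected `causal_dag` with provenance `"selected"` and
#'   attributes `scores` (named numeric) and `source`.
#' @export
select_dag <- function(expert_dag, discovered_dag, treatment, outcome) {
  s_e <- stability_score(expert_dag, treatment, outcome)
  s_d <- stability_score(discovered_dag, treatment, outcome)
  pick <- if (s_d > s_e) discovered_dag else expert_dag
  out <- pick
  out$provenance <- "selected"
  attr(out, "scores") <- c(expert = s_e, discovered = s_d)
  attr(out, "source") <- if (s_d > s_e) "discovered" else "expert"
  out
}

#' Read a DAG from a 2-column tab-separated edge list
#'
#' Lines starting with `#` are comments; columns are source and target.
#'
#' @param path file path.
#' @param provenance provenance tag for the resulting DAG.
#' @return a `causal_dag`.
#' @export
read_dag <- function(path, provenance = "expert") {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(causal_dag(NULL, provenance = provenance))
  parts <- strsplit(lines, "\t")
  assert_that(all(lengths(parts) >= 2), "edge list rows need 2 columns")
  causal_dag(tibble::tibble(from = vapply(parts, `[`, "", 1),
                            to = vapply(parts, `[`, "", 2)),
             provenance = provenance)
}

#' Write a DAG as an edge list (and optionally GraphML)
#'
#' @param dag a `causal_dag`.
#' @param path output path for the tab-separated edge list.
#' @param graphml optional path for a GraphML export.
#' @return invisibly, `path`.
#' @export
write_dag <- function(dag, path, graphml = NULL) {
  writeLines(c("# source\ttarget",
               paste(dag$edges$from, dag$edges$to, sep = "\t")), path)
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(dag), graphml, format = "graphml")
  }
  invisible(path)
}
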