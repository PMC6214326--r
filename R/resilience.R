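# Node-based resilience measures and their greedy / exact minimization.

MEASURES <- c("vat", "integrity", "tenacity")

# Component summary of the graph after deleting attack set `s` (names).
survivor_components <- function(graph, s) {
  g2 <- igraph::delete_vertices(graph, s)
  if (igraph::vcount(g2) == 0L) {
    return(list(members = list(), sizes = integer(0), cmax = 0L, ncomp = 0L))
  }
  comp <- igraph::components(g2)
  members <- split(igraph::V(g2)$name, comp$membership)
  list(members = unname(members), sizes = as.integer(comp$csize),
       cmax = max(as.integer(comp$csize)), ncomp = comp$no)
}

# Objective from summary statistics; n = |V| of the original graph.
measure_value <- function(measure, n, s_size, cmax, ncomp) {
  switch(measure,
    vat       = s_size / (n - s_size - cmax + 1),
    integrity = (s_size + cmax) / n,
    tenacity  = (s_size + cmax) / ncomp,
    abort(paste0("Unknown measure '", measure, "'."))
  )
}

check_attack_set <- function(graph, s) {
  s <- as.character(s)
  if (anyDuplicated(s)) abort("Attack set has duplicate nodes.")
  if (!all(s %in% igraph::V(graph)$name)) abort("Attack set contains unknown nodes.")
  s
}

#' Resilience objectives for a given attack set
#'
#' Evaluate a node-based resilience objective on graph `G = (V, E)` for an
#' attack set `S`: vertex attack tolerance (VAT)
#' `|S| / (|V - S - Cmax(V - S)| + 1)`, normalized integrity
#' `(|S| + Cmax(V - S)) / |V|`, and tenacity
#' `(|S| + Cmax(V - S)) / omega(V - S)`, where `Cmax` is the size of the
#' largest surviving connected component and `omega` counts surviving
#' components.  VAT requires a non-empty `S`; integrity admits any
#' `S` (with `Cmax = 0` when `S = V`); tenacity requires `S` proper.
#'
#' @param graph An igraph with named vertices (connected, for VAT).
#' @param s Attack set: character vector of vertex names (order irrelevant
#'   for the objective value).
#' @return The objective value, a single number.
#' @examples
#' g <- toy_graph("star", 6)
#' vat_objective(g, "0")
#' @name resilience_objectives
NULL

#' @rdname resilience_objectives
#' @export
vat_objective <- function(graph, s) {
  s <- check_attack_set(graph, s)
  if (length(s) == 0L) abort("VAT requires a non-empty attack set.")
  n <- igraph::vcount(graph)
  if (length(s) >= n) abort("VAT requires a proper attack set.")
  cs <- survivor_components(graph, s)
  measure_value("vat", n, length(s), cs$cmax, cs$ncomp)
}

#' @rdname resilience_objectives
#' @export
integrity_objective <- function(graph, s) {
  s <- check_attack_set(graph, s)
  n <- igraph::vcount(graph)
  if (length(s) == n) return(1)   # Cmax(V - V) = 0
  cs <- survivor_components(graph, s)
  measure_value("integrity", n, length(s), cs$cmax, cs$ncomp)
}

#' @rdname resilience_objectives
#' @export
tenacity_objective <- function(graph, s) {
  s <- check_attack_set(graph, s)
  n <- igraph::vcount(graph)
  if (length(s) >= n) abort("Tenacity requires a proper attack set (omega >= 1).")
  cs <- survivor_components(graph, s)
  measure_value("tenacity", n, length(s), cs$cmax, cs$ncomp)
}

#' Weighted betweenness centrality
#'
#' Unnormalized betweenness over unordered vertex pairs with edge weights
#' interpreted as path lengths (smaller = closer, matching kNN distance
#' weights).  Unweighted graphs use unit lengths.  Zero-weight edges (from
#' duplicate points) are floored at a tiny positive epsilon, since shortest
#' path counting requires positive lengths.
#'
#' @param graph An igraph with >= 2 vertices.
#' @return Named numeric vector of centralities.
#' @examples
#' weighted_betweenness(toy_graph("path", 3))
#' @export
weighted_betweenness <- function(graph) {
  if (igraph::vcount(graph) < 2L) abort("Need at least two vertices.")
  w <- igraph::E(graph)$weight
  if (!is.null(w)) {
    if (any(w < 0)) abort("Negative edge weights are not allowed.")
    w <- pmax(w, 1e-12)
  }
  bc <- igraph::betweenness(graph, weights = w, directed = FALSE)
  setNames(as.numeric(bc), igraph::V(graph)$name)
}

new_resilience_eval <- function(measure, attack_set, objective, components,
                                trace, method, n) {
  structure(
    list(measure = measure,
         attack_set = attack_set,
         objective = objective,
         components = components,
         cmax = if (length(components)) max(lengths(components)) else 0L,
         n_components = length(components),
         trace = trace,
         method = method,
         n = n),
    class = "resilience_eval")
}

#' Greedy betweenness-centrality minimization of a resilience measure
#'
#' The Greedy-BC heuristic: repeatedly remove the current highest-betweenness
#' node (recomputing weighted betweenness after every removal; ties go to the
#' lowest vertex index), evaluate the measure's objective on each removal
#' prefix `S_1 < S_2 < ...`, and return the prefix with the minimal objective
#' (ties prefer the smallest attack set).
#'
#' @param graph A connected igraph with named vertices.
#' @param measure One of `"vat"`, `"integrity"`, `"tenacity"`.
#' @param budget Maximum number of removals; defaults to `|V| - 2`.
#' @return A `resilience_eval` object: the chosen attack set (in removal
#'   order), its objective, the surviving components, and the full greedy
#'   trace as a tibble (`step`, `node`, `objective`, `cmax`, `n_components`).
#' @examples
#' greedy_bc_minimize(toy_graph("star", 6), "integrity")
#' @export
greedy_bc_minimize <- function(graph, measure = MEASURES, budget = NULL) {
  measure <- match.arg(measure)
  n <- igraph::vcount(graph)
  if (n < 3L) abort("Graph too small to attack (need >= 3 vertices).")
  if (!igraph::is_connected(graph)) {
    abort("Graph is disconnected; cluster its components separately.")
  }
  budget <- as.integer(budget %||% (n - 2L))
  budget <- min(budget, n - 2L)
  g <- graph
  order_removed <- character(0)
  steps <- vector("list", budget)
  best_obj <- Inf; best_size <- 0L
  for (step in seq_len(budget)) {
    bc <- weighted_betweenness(g)
    pick <- which_max_first(bc)          # lowest index on ties
    node <- igraph::V(g)$name[pick]
    g <- igraph::delete_vertices(g, node)
    order_removed <- c(order_removed, node)
    comp <- igraph::components(g)
    cmax <- max(comp$csize)
    obj <- measure_value(measure, n, step, cmax, comp$no)
    steps[[step]] <- tibble(step = step, node = node, objective = obj,
                            cmax = as.integer(cmax),
                            n_components = as.integer(comp$no))
    if (obj < best_obj) { best_obj <- obj; best_size <- step }
  }
  s <- order_removed[seq_len(best_size)]
  cs <- survivor_components(graph, s)
  new_resilience_eval(measure, s, best_obj, cs$members,
                      bind_rows(steps), "greedy", n)
}

# --- exact minimization by subset enumeration (bitmask) -------------------

# Component sizes of the kept-node set `keep_mask` given neighbour bitmasks.
bitmask_component_sizes <- function(nbr, keep_mask) {
  sizes <- integer(0)
  remaining <- keep_mask
  while (remaining > 0) {
    seed <- bitwAnd(remaining, -remaining)        # lowest set bit
    comp <- 0; frontier <- seed
    while (frontier > 0) {
      comp <- bitwOr(comp, frontier)
      nxt <- 0
      bits <- frontier
      while (bits > 0) {
        b <- bitwAnd(bits, -bits)
        nxt <- bitwOr(nxt, nbr[[as.character(b)]])
        bits <- bitwAnd(bits, bits - 1)
      }
      frontier <- bitwAnd(bitwAnd(nxt, remaining), bitwNot(comp))
    }
    sizes <- c(sizes, sum(bitwAnd(comp, 2^(0:30)) > 0))
    remaining <- bitwAnd(remaining, bitwNot(comp))
  }
  sizes
}

#' Exact resilience by brute-force subset enumeration
#'
#' Enumerates every admissible attack set (non-empty proper subsets for VAT;
#' proper subsets including the empty set for integrity and tenacity) and
#' returns the global minimizer.  Exponential in `|V|`, hence refused above
#' `max_nodes`.
#'
#' @inheritParams greedy_bc_minimize
#' @param max_nodes Enumeration cap (default 15).
#' @return A `resilience_eval` object with `method = "exact"`.
#' @examples
#' exact_resilience(toy_graph("star", 6), "vat")$objective
#' @export
exact_resilience <- function(graph, measure = MEASURES, max_nodes = 15) {
  measure <- match.arg(measure)
  n <- igraph::vcount(graph)
  if (n > max_nodes) {
    abort(paste0("Refusing exhaustive search on ", n, " > ", max_nodes, " nodes."))
  }
  ids <- igraph::V(graph)$name
  adj <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  nbr <- list()
  for (i in seq_len(n)) {
    nbr[[as.character(2^(i - 1))]] <- sum(2^(which(adj[i, ]) - 1))
  }
  full <- 2^n - 1
  s_min <- if (measure == "vat") 1L else 0L
  best_obj <- Inf; best_mask <- NA; best_size <- n
  bits <- 2^(0:(n - 1))
  for (mask in 0:(full - 1)) {           # proper subsets of V
    s_size <- sum(bitwAnd(mask, bits) > 0)
    if (s_size < s_min) next
    sizes <- bitmask_component_sizes(nbr, bitwAnd(full, bitwNot(mask)))
    obj <- measure_value(measure, n, s_size, max(sizes), length(sizes))
    if (obj < best_obj || (obj == best_obj && s_size < best_size)) {
      best_obj <- obj; best_mask <- mask; best_size <- s_size
    }
  }
  s <- ids[bitwAnd(best_mask, 2^(0:(n - 1))) > 0]
  cs <- survivor_components(graph, s)
  new_resilience_eval(measure, s, best_obj, cs$members, NULL, "exact", n)
}

#' @export
print.resilience_eval <- function(x, ...) {
  cat("<resilience_eval> measure:", x$measure, " method:", x$method, "\n")
  cat("  |S| =", length(x$attack_set), " objective =", format(x$objective), "\n")
  cat("  components:", x$n_components, " (largest ", x$cmax, ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.resilience_eval <- function(x, ...) {
  x$trace %||% tibble(step = integer(), node = character(),
                      objective = double(), cmax = integer(),
                      n_components = integer())
}

#' @export
glance.resilience_eval <- function(x, ...) {
  tibble(measure = x$measure, method = x$method, n = x$n,
         attack_size = length(x$attack_set), objective = x$objective,
         cmax = x$cmax, n_components = x$n_components)
}
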