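# Clusters from attack-set removal, reassignment, and merge/split adjustment.

# Constructor; labels is a named integer vector (0-based contiguous ids).
new_nbr_clustering <- function(labels, mode, unassigned = character(0),
                               provenance = list()) {
  structure(
    list(labels = labels,
         k = length(unique(labels)),
         mode = mode,
         unassigned = unassigned,
         provenance = provenance),
    class = "nbr_clustering")
}

# Relabel to contiguous 0-based ids in order of first appearance.
relabel_contiguous <- function(labels) {
  ids <- unique(labels)
  setNames(match(labels, ids) - 1L, names(labels))
}

#' Clusters from the components surviving an attack
#'
#' Deletes the attack set from the graph; each connected component of the
#' remainder becomes a cluster (ids contiguous from 0, in order of first
#' vertex appearance).  The attack set itself is left unassigned
#' (`mode = "no_reassignment"`).
#'
#' @param graph An igraph with named vertices.
#' @param s Attack set (character vector of vertex names), possibly empty.
#' @return An `nbr_clustering` object.
#' @examples
#' components_after_removal(toy_graph("star", 6), "0")
#' @export
components_after_removal <- function(graph, s) {
  s <- check_attack_set(graph, s)
  if (length(s) >= igraph::vcount(graph)) abort("Attack set must be proper.")
  g2 <- igraph::delete_vertices(graph, s)
  comp <- igraph::components(g2)
  labels <- relabel_contiguous(setNames(as.integer(comp$membership),
                                        igraph::V(g2)$name))
  new_nbr_clustering(labels, "no_reassignment", unassigned = s,
                     provenance = list(attack_set = s))
}

#' Fold attack-set nodes back into the clusters
#'
#' Iterated neighbour plurality: in rounds, every unassigned node adjacent to
#' at least one labelled node joins the cluster holding the plurality of its
#' labelled neighbours (ties prefer the larger cluster, then the lower
#' cluster id), until the whole attack set is labelled.
#'
#' @param graph The original (pre-removal) igraph.
#' @param clustering An `nbr_clustering` with `mode = "no_reassignment"`.
#' @return The clustering with `mode = "reassigned"` and no unassigned nodes.
#' @export
reassign_attack_set <- function(graph, clustering) {
  stopifnot(inherits(clustering, "nbr_clustering"))
  if (clustering$mode != "no_reassignment") {
    abort("Clustering is already reassigned.")
  }
  labels <- clustering$labels
  pending <- clustering$unassigned
  while (length(pending) > 0L) {
    sizes <- table(labels)
    assigned_now <- character(0)
    new_labels <- integer(0)
    for (node in pending) {
      nb <- igraph::V(graph)$name[igraph::neighbors(graph, node)]
      nb_lab <- labels[intersect(nb, names(labels))]
      if (length(nb_lab) == 0L) next
      tab <- table(nb_lab)
      cand <- as.integer(names(tab)[tab == max(tab)])
      if (length(cand) > 1L) {
        csz <- as.integer(sizes[as.character(cand)])
        csz[is.na(csz)] <- 0L
        cand <- cand[csz == max(csz)]
        cand <- min(cand)                       # lower cluster id last
      }
      assigned_now <- c(assigned_now, node)
      new_labels <- c(new_labels, cand[1])
    }
    if (length(assigned_now) == 0L) {
      abort("Unassigned node(s) unreachable from any labelled node.")
    }
    labels[assigned_now] <- new_labels          # simultaneous per round
    pending <- setdiff(pending, assigned_now)
  }
  out <- clustering
  out$labels <- labels
  out$mode <- "reassigned"
  out$unassigned <- character(0)
  out$k <- length(unique(labels))
  out
}

# Inter-cluster edge count matrix and sizes for the labelled nodes.
cluster_edge_counts <- function(graph, labels) {
  ids <- sort(unique(labels))
  k <- length(ids)
  pos <- setNames(seq_len(k), ids)
  e_mat <- matrix(0, k, k)
  el <- igraph::as_edgelist(graph)
  keep <- el[, 1] %in% names(labels) & el[, 2] %in% names(labels)
  el <- el[keep, , drop = FALSE]
  if (nrow(el) > 0L) {
    a <- pos[as.character(labels[el[, 1]])]
    b <- pos[as.character(labels[el[, 2]])]
    for (r in seq_along(a)) {
      e_mat[a[r], b[r]] <- e_mat[a[r], b[r]] + 1
      if (a[r] != b[r]) e_mat[b[r], a[r]] <- e_mat[b[r], a[r]] + 1
    }
  }
  sizes <- as.integer(table(factor(labels, levels = ids)))
  list(ids = ids, e = e_mat, sizes = sizes)
}

#' Merge clusters down to a requested count
#'
#' Repeatedly merges the cluster pair maximizing the normalized-cut quantity
#' `E(C1, C2) / (|C1| * |C2|)` (inter-cluster edge count over size product),
#' breaking ties by the lexicographically smallest cluster-id pair, until
#' `k_target` clusters remain.
#'
#' @inheritParams reassign_attack_set
#' @param k_target Desired cluster count, `1 <= k_target <= k`.
#' @return The adjusted clustering; merges are appended to
#'   `provenance$adjustments`.
#' @export
merge_to_k <- function(graph, clustering, k_target) {
  stopifnot(inherits(clustering, "nbr_clustering"), k_target >= 1)
  if (clustering$k < k_target) abort("k_target exceeds current k; use split_to_k().")
  labels <- clustering$labels
  trace <- list()
  cc <- cluster_edge_counts(graph, labels)
  ids <- cc$ids; e <- cc$e; sizes <- cc$sizes
  while (length(ids) > k_target) {
    score <- e / outer(sizes, sizes)
    diag(score) <- -Inf
    best <- max(score)
    hit <- which(score == best, arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]                 # smallest id pair on ties
    trace[[length(trace) + 1L]] <-
      tibble(action = "merge", from = ids[j], into = ids[i], score = best)
    labels[labels == ids[j]] <- ids[i]
    intra <- e[i, i] + e[j, j] + e[i, j]           # internal edges of the union
    e[i, ] <- e[i, ] + e[j, ]
    e[, i] <- e[i, ]
    e[i, i] <- intra
    sizes[i] <- sizes[i] + sizes[j]
    e <- e[-j, -j, drop = FALSE]; sizes <- sizes[-j]; ids <- ids[-j]
  }
  out <- clustering
  out$labels <- relabel_contiguous(labels)
  out$k <- length(unique(out$labels))
  out$provenance$adjustments <- bind_rows(out$provenance$adjustments,
                                          bind_rows(trace))
  out
}

# Best disconnecting prefix of a greedy run; NULL when no prefix disconnects.
best_disconnecting_prefix <- function(eval) {
  tr <- eval$trace
  ok <- tr$n_components >= 2L
  if (!any(ok)) return(NULL)
  best <- which(ok)[which.min(tr$objective[ok])]
  tr$node[seq_len(best)]
}

#' Split clusters up to a requested count
#'
#' While below `k_target`, scores each cluster of size >= 3 by the greedy
#' resilience objective of its induced subgraph, picks the lowest-scoring
#' (least resilient) cluster, and divides it by its greedy attack set:
#' surviving components become new clusters and the attack nodes are
#' reassigned (or left unassigned, matching the clustering's mode).  When no
#' prefix of the greedy removal disconnects the subgraph (e.g. a complete
#' cluster), the cluster is dissolved into singletons so every step
#' increases k.
#'
#' @inheritParams merge_to_k
#' @param measure Resilience measure used inside the split.
#' @return The adjusted clustering.
#' @export
split_to_k <- function(graph, clustering, k_target, measure = MEASURES) {
  measure <- match.arg(measure)
  stopifnot(inherits(clustering, "nbr_clustering"))
  if (clustering$k > k_target) abort("k_target below current k; use merge_to_k().")
  labels <- clustering$labels
  trace <- list()
  k_now <- length(unique(labels))
  while (k_now < k_target) {
    ids <- sort(unique(labels))
    sizes <- table(factor(labels, levels = ids))
    splittable <- ids[sizes >= 3L]
    if (length(splittable) == 0L) {
      abort(paste0("No splittable cluster remains; achievable k = ", k_now, "."))
    }
    evals <- map(splittable, function(cid) {
      sub <- igraph::induced_subgraph(graph, names(labels)[labels == cid])
      greedy_bc_minimize(sub, measure)
    })
    pick <- which.min(map_dbl(evals, "objective"))   # lowest id on ties
    cid <- splittable[pick]
    ev <- evals[[pick]]
    sub_nodes <- names(labels)[labels == cid]
    sub <- igraph::induced_subgraph(graph, sub_nodes)
    s <- best_disconnecting_prefix(ev)
    if (is.null(s)) {
      # indivisible cluster (no attack set disconnects it): dissolve
      new_sub_labels <- setNames(seq_along(sub_nodes) - 1L, sub_nodes)
      trace[[length(trace) + 1L]] <-
        tibble(action = "dissolve", from = cid, into = NA_integer_,
               score = NA_real_)
    } else {
      sub_cl <- components_after_removal(sub, s)
      if (clustering$mode == "reassigned") {
        sub_cl <- reassign_attack_set(sub, sub_cl)
      } else {
        clustering$unassigned <- union(clustering$unassigned, s)
      }
      clustering$provenance$attack_set <-
        union(clustering$provenance$attack_set, s)
      new_sub_labels <- sub_cl$labels
      trace[[length(trace) + 1L]] <-
        tibble(action = "split", from = cid, into = NA_integer_,
               score = ev$objective)
    }
    offset <- max(labels) + 1L
    labels <- labels[setdiff(names(labels), sub_nodes)]
    labels[names(new_sub_labels)] <- new_sub_labels + offset
    k_now <- length(unique(labels))
  }
  out <- clustering
  out$labels <- relabel_contiguous(labels)
  out$k <- length(unique(out$labels))
  out$provenance$adjustments <- bind_rows(out$provenance$adjustments,
                                          bind_rows(trace))
  out
}

#' Node-based resilience clustering (end to end)
#'
#' Runs the full NBR-Clust pipeline on a connected graph: (i) minimize the
#' chosen resilience measure with the Greedy-BC heuristic, (ii) take the
#' surviving components as base clusters, (iii) fold the attack set back in
#' when `mode = "reassigned"`, and (iv) merge (normalized cut) or split
#' (recursive attack) to exactly `k_target` clusters.
#'
#' @param graph A connected igraph with named vertices and distance weights.
#' @param measure `"vat"`, `"integrity"`, or `"tenacity"`.
#' @param k_target Desired number of clusters (>= 2).
#' @param mode `"reassigned"` (complete clustering) or `"no_reassignment"`
#'   (attack-set nodes stay unassigned as candidate outliers).
#' @param budget Optional greedy removal budget (see [greedy_bc_minimize()]).
#' @param eval Optional precomputed `resilience_eval` for this graph and
#'   measure (lets callers share one greedy run across several `k_target`s).
#' @return An `nbr_clustering`; provenance records the measure, attack set,
#'   objective and every merge/split.
#' @examples
#' sim <- gaussian_mixture_table(n = 60, d = 2, k_true = 2,
#'                               separation = 8, seed = 1)
#' g <- knn_graph(sim$data, min_connectivity(sim$data))
#' nbr_clust(g, "integrity", k_target = 2)
#' @export
nbr_clust <- function(graph, measure = MEASURES, k_target = 2,
                      mode = c("reassigned", "no_reassignment"),
                      budget = NULL, eval = NULL) {
  measure <- match.arg(measure)
  mode <- match.arg(mode)
  stopifnot(k_target >= 2)
  ev <- eval %||% greedy_bc_minimize(graph, measure, budget)
  stopifnot(inherits(ev, "resilience_eval"), ev$measure == measure)
  cl <- components_after_removal(graph, ev$attack_set)
  if (mode == "reassigned") cl <- reassign_attack_set(graph, cl)
  if (cl$k > k_target) cl <- merge_to_k(graph, cl, k_target)
  if (cl$k < k_target) cl <- split_to_k(graph, cl, k_target, measure)
  cl$provenance$measure <- measure
  cl$provenance$objective <- ev$objective
  cl$provenance$graph_tag <- igraph::graph_attr(graph, "tag")
  cl
}

#' @export
print.nbr_clustering <- function(x, ...) {
  cat("<nbr_clustering> k =", x$k, " mode:", x$mode, "\n")
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  if (length(x$unassigned)) cat("  unassigned:", length(x$unassigned), "nodes\n")
  invisible(x)
}

#' @export
tidy.nbr_clustering <- function(x, ...) {
  attack <- x$provenance$attack_set %||% character(0)
  assigned <- tibble(node = names(x$labels),
                     cluster = as.integer(x$labels))
  out <- bind_rows(assigned,
                   tibble(node = x$unassigned, cluster = NA_integer_))
  out$was_attack_node <- as.integer(out$node %in% union(attack, x$unassigned))
  arrange(out, .data$node)
}

#' @export
glance.nbr_clustering <- function(x, ...) {
  tibble(k = x$k, mode = x$mode,
         measure = x$provenance$measure %||% NA_character_,
         n_assigned = length(x$labels),
         n_unassigned = length(x$unassigned),
         objective = x$provenance$objective %||% NA_real_)
}
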