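#' Euclidean distance matrix of a feature table
#'
#' @param data A complete (no missing values) feature table; typically
#'   normalized to `[0, 1]` first.
#' @return A symmetric N x N matrix with zero diagonal, dimnames = sample ids.
#' @examples
#' pairwise_distances(data.frame(x = c(0, 3), y = c(0, 4)))
#' @export
pairwise_distances <- function(data) {
  m <- as_feature_matrix(data)
  if (anyNA(m)) abort("`data` has missing values; impute before building graphs.")
  as.matrix(dist(m))
}

# Core builder from a precomputed distance matrix.
knn_graph_from_dist <- function(d, k, mode = c("union", "mutual")) {
  mode <- match.arg(mode)
  n <- nrow(d)
  stopifnot(k >= 1, k <= n - 1)
  ids <- rownames(d) %||% as.character(seq_len(n))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    # stable order: distance, then node index, self excluded
    ord <- order(d[i, ], seq_len(n))
    ord <- ord[ord != i]
    adj[i, ord[seq_len(k)]] <- TRUE
  }
  sym <- if (mode == "union") adj | t(adj) else adj & t(adj)
  sym[lower.tri(sym, diag = TRUE)] <- FALSE
  idx <- which(sym, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- ids
  if (nrow(idx) > 0L) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- d[idx]
  }
  g <- igraph::set_graph_attr(g, "knn_k", as.integer(k))
  igraph::set_graph_attr(g, "knn_mode", mode)
}

#' Symmetrized k-nearest-neighbour graph
#'
#' Builds the undirected kNN graph: with `mode = "union"` an edge \{u, v\}
#' exists iff v is among the k nearest neighbours of u *or* vice versa
#' (`"mutual"` requires both).  Edge weights are Euclidean distances;
#' distance ties are broken by node index so builds are reproducible.
#' Duplicate points are allowed and yield zero-weight edges.
#'
#' @inheritParams pairwise_distances
#' @param k Number of nearest neighbours, `1 <= k <= N - 1`.
#' @param mode Symmetrization rule, `"union"` (default) or `"mutual"`.
#' @return An [igraph::igraph] with vertex names = sample ids, edge attribute
#'   `weight`, and graph attributes `knn_k` and `knn_mode`.
#' @examples
#' g <- knn_graph(data.frame(x = c(0, 1, 100, 101)), k = 1)
#' igraph::ecount(g)
#' @export
knn_graph <- function(data, k, mode = c("union", "mutual")) {
  knn_graph_from_dist(pairwise_distances(data), k, mode)
}

#' Smallest k at which the kNN graph is connected (min-conn)
#'
#' Edge sets are nested in k, so connectivity is monotone and located by
#' binary search.  `k = N - 1` (the complete graph) always connects.
#'
#' @inheritParams knn_graph
#' @return The minimal connecting k, a positive integer.
#' @examples
#' min_connectivity(data.frame(x = c(0, 1, 100, 101)))
#' @export
min_connectivity <- function(data, mode = c("union", "mutual")) {
  mode <- match.arg(mode)
  d <- pairwise_distances(data)
  n <- nrow(d)
  stopifnot(n >= 2)
  lo <- 1L; hi <- n - 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (igraph::is_connected(knn_graph_from_dist(d, mid, mode))) hi <- mid else lo <- mid + 1L
  }
  lo
}

#' Build the grid of base graphs
#'
#' For each supplied feature set and each connectivity offset o, builds the
#' kNN graph at `min_connectivity + o`.  Offsets 0, 1, 2 are labelled kNN2,
#' kNN3, kNN4 (minimal connectivity and one/two levels above it).  With the
#' full and the correlation-filtered feature set this yields the canonical
#' six base graphs.
#'
#' @param full Complete, normalized feature table (full feature set).
#' @param filtered Optional second table, e.g. after [correlation_filter()].
#' @param offsets Non-negative integer offsets above min-conn; default `0:2`.
#' @param mode Symmetrization rule passed to [knn_graph()].
#' @return A named list of igraphs; each carries graph attributes `tag`
#'   (e.g. `"all_kNN2"`), `feature_set`, `knn_k` and `knn_offset`.
#' @export
base_graph_grid <- function(full, filtered = NULL, offsets = 0:2,
                            mode = c("union", "mutual")) {
  mode <- match.arg(mode)
  stopifnot(all(offsets >= 0))
  sets <- list(all = full)
  if (!is.null(filtered)) sets$corr <- filtered
  out <- list()
  for (set_name in names(sets)) {
    d <- pairwise_distances(sets[[set_name]])
    n <- nrow(d)
    lo <- 1L; hi <- n - 1L
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (igraph::is_connected(knn_graph_from_dist(d, mid, mode))) hi <- mid else lo <- mid + 1L
    }
    for (o in offsets) {
      k <- min(lo + o, n - 1L)
      g <- knn_graph_from_dist(d, k, mode)
      tag <- paste0(set_name, "_kNN", 2L + o)
      g <- igraph::set_graph_attr(g, "tag", tag)
      g <- igraph::set_graph_attr(g, "feature_set", set_name)
      g <- igraph::set_graph_attr(g, "knn_offset", as.integer(o))
      out[[tag]] <- g
    }
  }
  out
}

#' Read / write weighted graphs
#'
#' Thin wrappers over igraph's GraphML reader/writer and a tab-separated
#' weighted edge list (`node_u  node_v  weight`).
#'
#' @param graph An igraph object with named vertices and a `weight` edge
#'   attribute.
#' @param path File path.
#' @name graph_io
#' @export
write_graph_file <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    w <- igraph::E(graph)$weight %||% rep(1, igraph::ecount(graph))
    utils::write.table(data.frame(el[, 1], el[, 2], w), path,
                       sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname graph_io
#' @export
read_graph_file <- function(path) {
  if (grepl("\\.graphml$", path)) {
    igraph::read_graph(path, format = "graphml")
  } else {
    el <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(el[, 1:2], directed = FALSE)
    igraph::E(g)$weight <- as.numeric(el[, 3])
    g
  }
}
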