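# Internal cluster validation indices, graph quality measures, and the
# majority-vote configuration selector.

INDEX_DIRECTIONS <- c(SI = "max", CH = "max", DB = "min", Dunn = "max",
                      XB = "min", SD = "min", S_Dbw = "min", I = "max",
                      CVNN = "min")

# Integer labels aligned to rows of `points`, named by sample id.
# Accepts an nbr_clustering (unassigned nodes are excluded from scoring)
# or a plain / named vector.
resolve_labels <- function(points, clustering) {
  ids <- sample_ids(points)
  if (inherits(clustering, "nbr_clustering")) {
    labels <- clustering$labels
    if (!all(names(labels) %in% ids)) {
      abort("Clustering refers to nodes absent from `points`.")
    }
    return(labels)
  }
  if (is.null(names(clustering))) {
    stopifnot(length(clustering) == nrow(points))
    return(setNames(as.integer(as.factor(clustering)) - 1L, ids))
  }
  setNames(as.integer(as.factor(clustering)), names(clustering)) - 1L
}

# Geometry shared by the indices.
cluster_stats <- function(points, clustering) {
  labels <- resolve_labels(points, clustering)
  x <- as_feature_matrix(points)[names(labels), , drop = FALSE]
  ids <- sort(unique(labels))
  k <- length(ids)
  centers <- t(vapply(ids, function(c0) colMeans(x[labels == c0, , drop = FALSE]),
                      numeric(ncol(x))))
  global <- colMeans(x)
  sizes <- as.integer(table(factor(labels, levels = ids)))
  d_all <- as.matrix(dist(x))
  center_d <- as.matrix(dist(centers))
  # per-point distance to own center
  own <- sqrt(rowSums((x - centers[match(labels, ids), , drop = FALSE])^2))
  # norms of the per-dimension population variance vectors
  popvar <- function(m) colMeans(m^2) - colMeans(m)^2
  sigma_norms <- vapply(ids, function(c0)
    sqrt(sum(popvar(x[labels == c0, , drop = FALSE])^2)), numeric(1))
  list(x = x, labels = labels, ids = ids, k = k, n = nrow(x),
       centers = centers, global = global, sizes = sizes,
       d_all = d_all, center_d = center_d, own_center_d = own,
       sigma_norms = sigma_norms, sigma_data = sqrt(sum(popvar(x)^2)))
}

check_k2 <- function(st) {
  if (st$k < 2L) abort("Index requires at least two clusters.")
}

#' Internal cluster validation indices
#'
#' Label-free scores of clustering quality over the point geometry.  All use
#' Euclidean distance and the conventions: cluster center = mean vector,
#' singleton silhouette contribution = 0, population (divide-by-n) cluster
#' variances.
#'
#' * `silhouette_index()` — mean over clusters of the mean silhouette
#'   `(b - a) / max(a, b)` (optimal: max, range \[-1, 1\]).
#' * `calinski_harabasz_index()` — between/within dispersion ratio
#'   (max; `Inf` when within-dispersion is zero).
#' * `davies_bouldin_index()` — mean worst pairwise scatter-to-separation
#'   ratio (min).
#' * `dunn_index()` — min inter-cluster point distance over max cluster
#'   diameter (max).
#' * `xie_beni_index()` — within-scatter over worst center separation (min).
#'
#' @param points Complete feature table whose rows cover the clustered nodes.
#' @param clustering An `nbr_clustering` (unassigned nodes are excluded) or a
#'   label vector aligned with `points`.
#' @return A single numeric value.
#' @name validation_indices
NULL

#' @rdname validation_indices
#' @export
silhouette_index <- function(points, clustering) {
  st <- cluster_stats(points, clustering)
  check_k2(st)
  per_cluster <- vapply(st$ids, function(c0) {
    in_c <- st$labels == c0
    n_i <- sum(in_c)
    s <- vapply(which(in_c), function(p) {
      if (n_i == 1L) return(0)
      a <- sum(st$d_all[p, in_c]) / (n_i - 1)
      b <- min(vapply(setdiff(st$ids, c0), function(c1)
        mean(st$d_all[p, st$labels == c1]), numeric(1)))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, numeric(1))
    mean(s)
  }, numeric(1))
  mean(per_cluster)
}

#' @rdname validation_indices
#' @export
calinski_harabasz_index <- function(points, clustering) {
  st <- cluster_stats(points, clustering)
  check_k2(st)
  if (st$k >= st$n) abort("Requires k < N.")
  between <- sum(st$sizes * rowSums((st$centers -
    matrix(st$global, st$k, ncol(st$centers), byrow = TRUE))^2))
  within <- sum(st$own_center_d^2)
  if (within == 0) {
    inform("Zero within-cluster dispersion; returning Inf.")
    return(Inf)
  }
  (between / (st$k - 1)) / (within / (st$n - st$k))
}

#' @rdname validation_indices
#' @export
davies_bouldin_index <- function(points, clustering) {
  st <- cluster_stats(points, clustering)
  check_k2(st)
  cd <- st$center_d; diag(cd) <- Inf
  if (min(cd) == 0) abort("Coincident cluster centers.")
  s_i <- vapply(seq_along(st$ids), function(i)
    mean(st$own_center_d[st$labels == st$ids[i]]), numeric(1))
  r <- outer(s_i, s_i, `+`) / st$center_d
  diag(r) <- -Inf
  mean(apply(r, 1, max))
}

#' @rdname validation_indices
#' @export
dunn_index <- function(points, clustering) {
  st <- cluster_stats(points, clustering)
  check_k2(st)
  same <- outer(st$labels, st$labels, `==`)
  diam <- max(st$d_all[same])
  if (diam == 0) abort("All clusters are singletons (zero diameter).")
  min(st$d_all[!same]) / diam
}

#' @rdname validation_indices
#' @export
xie_beni_index <- function(points, clustering) {
  st <- cluster_stats(points, clustering)
  check_k2(st)
  cd <- st$center_d; diag(cd) <- Inf
  if (min(cd) == 0) abort("Coincident cluster centers.")
  sum(st$own_center_d^2) / (st$n * min(cd)^2)
}

#' Index parameters
#'
#' Tunables for the SD, S_Dbw, I and CVNN indices.  `dis_kmax`, `max_sep`
#' and `max_com` are the family-wide normalizers (the `Dis` value of the
#' largest-k configuration and the maxima of the raw separation/compactness
#' terms over all compared configurations); when `NULL` the index is
#' self-normalized, which is only meaningful inside a family comparison such
#' as [run_grid()].
#'
#' @param cvnn_nn Neighbour count NN for CVNN (default 10).
#' @param i_exponent Exponent p of the I index (default 2).
#' @param k_max Largest k of the compared family (default 5).
#' @param dis_kmax,max_sep,max_com Optional family normalizers.
#' @return A list of class `index_params`.
#' @export
index_params <- function(cvnn_nn = 10, i_exponent = 2, k_max = 5,
                         dis_kmax = NULL, max_sep = NULL, max_com = NULL) {
  stopifnot(cvnn_nn >= 1, i_exponent >= 1, k_max >= 2)
  structure(list(cvnn_nn = as.integer(cvnn_nn), i_exponent = i_exponent,
                 k_max = as.integer(k_max), dis_kmax = dis_kmax,
                 max_sep = max_sep, max_com = max_com),
            class = "index_params")
}

# Scat(k): mean cluster variance norm over data variance norm.
scat_term <- function(st) mean(st$sigma_norms) / st$sigma_data

# Dis(k): center-distance spread times inverse total center distances.
dis_term <- function(st) {
  cd <- st$center_d
  off <- cd[upper.tri(cd)]
  if (min(off) == 0) abort("Coincident cluster centers in Dis term.")
  (max(off) / min(off)) * sum(1 / rowSums(cd))
}

#' SD, S_Dbw, I and CVNN indices
#'
#' Evaluates the remaining four indices:
#' `SD = Dis(k_max) * Scat(k) + Dis(k)`;
#' `S_Dbw = Scat(k) + Dens_bw(k)` with the density of the midpoint between
#' two centers relative to the denser of the two clusters, counting points
#' within the average cluster standard-deviation norm;
#' `I = [(sum d(x, c)) / (k * sum d(x, c_i)) * max d(c_i, c_j)]^p`;
#' `CVNN = Sep/maxSep + Com/maxCom` where `Sep` is the worst mean fraction
#' of each point's NN nearest neighbours lying outside its cluster and `Com`
#' sums mean pairwise intra-cluster distances.
#'
#' @inheritParams validation_indices
#' @param params An [index_params()] list (supplies NN, p and the
#'   family-wide normalizers).
#' @return Named list with `SD`, `S_Dbw`, `I`, `CVNN` plus the raw terms
#'   `scat`, `dis`, `sep_raw`, `com_raw` used for family normalization.
#' @export
geometric_validity_suite <- function(points, clustering, params = index_params()) {
  st <- cluster_stats(points, clustering)
  check_k2(st)
  scat <- scat_term(st)
  dis <- dis_term(st)
  sd_index <- (params$dis_kmax %||% dis) * scat + dis

  # S_Dbw
  stdev <- mean(st$sigma_norms)
  total <- 0
  for (i in seq_len(st$k - 1)) {
    for (j in (i + 1):st$k) {
      in_ij <- st$labels %in% st$ids[c(i, j)]
      xi <- st$x[in_ij, , drop = FALSE]
      count_at <- function(u) sum(sqrt(rowSums((xi -
        matrix(u, nrow(xi), ncol(xi), byrow = TRUE))^2)) <= stdev)
      u_ij <- (st$centers[i, ] + st$centers[j, ]) / 2
      denom <- max(count_at(st$centers[i, ]), count_at(st$centers[j, ]))
      if (denom > 0) total <- total + 2 * count_at(u_ij) / denom
    }
  }
  s_dbw <- scat + total / (st$k * (st$k - 1))

  # I index
  num <- sum(sqrt(rowSums((st$x -
    matrix(st$global, st$n, ncol(st$x), byrow = TRUE))^2)))
  within <- sum(st$own_center_d)
  max_cd <- max(st$center_d)
  i_index <- if (within == 0) Inf else
    (num / (st$k * within) * max_cd)^params$i_exponent

  # CVNN raw terms
  nn <- min(params$cvnn_nn, st$n - 1L)
  sep_per_cluster <- vapply(seq_along(st$ids), function(i) {
    members <- which(st$labels == st$ids[i])
    q <- vapply(members, function(p) {
      ord <- order(st$d_all[p, ], seq_len(st$n))
      ord <- ord[ord != p][seq_len(nn)]
      sum(st$labels[ord] != st$ids[i])
    }, numeric(1))
    mean(q / nn)
  }, numeric(1))
  sep_raw <- max(sep_per_cluster)
  com_raw <- sum(vapply(seq_along(st$ids), function(i) {
    members <- st$labels == st$ids[i]
    n_i <- sum(members)
    if (n_i < 2L) return(0)
    dm <- st$d_all[members, members]
    (2 / (n_i * (n_i - 1))) * sum(dm[upper.tri(dm)])
  }, numeric(1)))
  max_sep <- params$max_sep %||% sep_raw
  max_com <- params$max_com %||% com_raw
  cvnn <- (if (max_sep > 0) sep_raw / max_sep else 0) +
    (if (max_com > 0) com_raw / max_com else 0)

  list(SD = sd_index, S_Dbw = s_dbw, I = i_index, CVNN = cvnn,
       scat = scat, dis = dis, sep_raw = sep_raw, com_raw = com_raw)
}

#' Graph quality of a clustering: modularity and conductance
#'
#' `graph_modularity()` is Newman modularity `Q` of the cluster partition on
#' the unweighted graph.  `graph_conductance()` reports, per cluster, the
#' fraction of *all* graph edges with exactly one endpoint inside the
#' cluster; the configuration value is the maximum (worst cluster), with the
#' per-cluster values and mean attached as attributes.  Unassigned attack
#' nodes are excluded from both edge tallies.
#'
#' @param graph The igraph that was clustered.
#' @param clustering An `nbr_clustering` or a label vector named by vertex.
#' @return A single number (`graph_conductance()` carries attributes
#'   `per_cluster` and `mean`).
#' @name graph_quality
NULL

labelled_subgraph <- function(graph, clustering) {
  labels <- if (inherits(clustering, "nbr_clustering")) clustering$labels
            else resolve_labels(tibble(sample_id = igraph::V(graph)$name),
                                clustering)
  g2 <- igraph::induced_subgraph(graph, names(labels))
  if (igraph::ecount(g2) == 0L) abort("Graph has no edges among labelled nodes.")
  list(g = g2, labels = labels[igraph::V(g2)$name])
}

#' @rdname graph_quality
#' @export
graph_modularity <- function(graph, clustering) {
  ls <- labelled_subgraph(graph, clustering)
  igraph::modularity(ls$g, membership = ls$labels + 1L)
}

#' @rdname graph_quality
#' @export
graph_conductance <- function(graph, clustering) {
  ls <- labelled_subgraph(graph, clustering)
  m <- igraph::ecount(ls$g)
  el <- igraph::as_edgelist(ls$g)
  la <- ls$labels[el[, 1]]; lb <- ls$labels[el[, 2]]
  ids <- sort(unique(ls$labels))
  per <- vapply(ids, function(c0) sum(xor(la == c0, lb == c0)) / m, numeric(1))
  out <- max(per)
  attr(out, "per_cluster") <- setNames(per, ids)
  attr(out, "mean") <- mean(per)
  out
}

#' Admissibility thresholds for configuration selection
#'
#' @param modularity Minimum modularity for an admissible configuration
#'   (default 0.6).
#' @param conductance Maximum (worst-cluster) conductance (default 0.07).
#' @param size_floor_fraction Smallest admissible cluster as a fraction of
#'   the number of clustered nodes; default 10/2680, the ten-node floor of a
#'   2680-sample study expressed as a rate so it scales to other sizes.
#' @return A list of class `selection_thresholds`.
#' @export
selection_thresholds <- function(modularity = 0.6, conductance = 0.07,
                                 size_floor_fraction = 10 / 2680) {
  structure(list(modularity = modularity, conductance = conductance,
                 size_floor_fraction = size_floor_fraction),
            class = "selection_thresholds")
}

#' Score one clustering configuration
#'
#' Computes all nine validation indices, modularity and conductance, and the
#' admissibility flag for a single clustering.  SD and CVNN are
#' self-normalized unless `params` carries family normalizers; [run_grid()]
#' re-normalizes them across the whole family before ranking.
#'
#' @inheritParams validation_indices
#' @param graph The graph the clustering was computed on.
#' @param params An [index_params()] list.
#' @param thresholds A [selection_thresholds()] list.
#' @return A one-row tibble (a validation report).
#' @export
validate_clustering <- function(points, clustering, graph,
                                params = index_params(),
                                thresholds = selection_thresholds()) {
  st <- cluster_stats(points, clustering)
  geo <- geometric_validity_suite(points, clustering, params)
  mod <- graph_modularity(graph, clustering)
  cond <- graph_conductance(graph, clustering)
  n_total <- igraph::vcount(graph)
  min_size <- min(st$sizes)
  admissible <- mod >= thresholds$modularity &&
    as.numeric(cond) <= thresholds$conductance &&
    min_size >= thresholds$size_floor_fraction * n_total
  gl <- if (inherits(clustering, "nbr_clustering")) glance(clustering) else
    tibble(k = st$k, mode = NA_character_, measure = NA_character_,
           n_assigned = st$n, n_unassigned = 0L, objective = NA_real_)
  tibble(
    graph_tag = igraph::graph_attr(graph, "tag") %||% NA_character_,
    measure = gl$measure, k = gl$k, mode = gl$mode,
    SI = silhouette_index(points, clustering),
    CH = calinski_harabasz_index(points, clustering),
    DB = davies_bouldin_index(points, clustering),
    Dunn = dunn_index(points, clustering),
    XB = xie_beni_index(points, clustering),
    SD = geo$SD, S_Dbw = geo$S_Dbw, I = geo$I, CVNN = geo$CVNN,
    scat = geo$scat, dis = geo$dis, sep_raw = geo$sep_raw,
    com_raw = geo$com_raw,
    modularity = mod, conductance = as.numeric(cond),
    conductance_mean = attr(cond, "mean"),
    min_cluster_size = as.integer(min_size),
    n_scored = st$n, n_total = n_total,
    admissible = admissible)
}

# Re-normalize SD and CVNN across a family of reports (same graph family);
# Dis(k_max) is taken from the largest-k report of each group.
finalize_family_indices <- function(reports, group_vars = c("measure", "mode")) {
  group_vars <- intersect(group_vars, names(reports))
  reports |>
    group_by(across(dplyr::all_of(group_vars))) |>
    mutate(
      SD = .data$dis[which.max(.data$k)] * .data$scat + .data$dis,
      CVNN = ifelse(max(.data$sep_raw) > 0,
                    .data$sep_raw / max(.data$sep_raw), 0) +
             ifelse(max(.data$com_raw) > 0,
                    .data$com_raw / max(.data$com_raw), 0)) |>
    ungroup()
}

#' Majority-vote selection of the optimal configuration
#'
#' Discards reports whose smallest cluster falls below the size floor, lets
#' each of the nine indices cast one vote for the best admissible report in
#' its optimal direction (max for SI/CH/Dunn/I, min for DB/XB/SD/S_Dbw/CVNN;
#' if no report is admissible the vote is over all surviving reports), and
#' ranks reports by votes, then admissibility (modularity and conductance
#' gates), then silhouette.
#'
#' @param reports A tibble of validation reports ([validate_clustering()]
#'   rows).
#' @param thresholds A [selection_thresholds()] list.
#' @return The reports tibble with `votes_won` and `rank` columns, ranked.
#' @export
select_optimal <- function(reports, thresholds = selection_thresholds()) {
  stopifnot(nrow(reports) >= 1)
  floor_n <- thresholds$size_floor_fraction * reports$n_total
  surv <- reports[reports$min_cluster_size >= floor_n, , drop = FALSE]
  if (nrow(surv) == 0L) {
    abort(paste0("All ", nrow(reports), " report(s) fall below the cluster-size ",
                 "floor (", format(thresholds$size_floor_fraction), " of N)."))
  }
  surv$admissible <- surv$modularity >= thresholds$modularity &
    surv$conductance <= thresholds$conductance &
    surv$min_cluster_size >= thresholds$size_floor_fraction * surv$n_total
  pool <- if (any(surv$admissible)) which(surv$admissible) else seq_len(nrow(surv))
  votes <- integer(nrow(surv))
  for (idx in names(INDEX_DIRECTIONS)) {
    vals <- surv[[idx]][pool]
    if (all(!is.finite(vals))) next
    best <- if (INDEX_DIRECTIONS[[idx]] == "max") {
      pool[which.max(vals)]
    } else {
      pool[which.min(vals)]
    }
    votes[best] <- votes[best] + 1L
  }
  surv$votes_won <- votes
  surv <- arrange(surv, desc(.data$votes_won), desc(.data$admissible),
                  desc(.data$SI))
  surv$rank <- seq_len(nrow(surv))
  surv
}
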