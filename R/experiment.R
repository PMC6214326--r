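# Full configuration grid: enumerate, execute, rank.

#' Enumerate the clustering configuration grid
#'
#' Cartesian product of base graphs x resilience measures x cluster counts x
#' attack-set modes, in deterministic order (graphs outer; mode innermost).
#' The canonical study grid — 6 base graphs x 3 measures x k in 2..5 x
#' 2 modes — yields 144 configurations.
#'
#' @param graphs Character vector of base-graph tags (or a named list of
#'   graphs, whose names are used).
#' @param measures Subset of `c("vat", "integrity", "tenacity")`.
#' @param k_values Integer cluster counts.
#' @param modes Subset of `c("reassigned", "no_reassignment")`.
#' @return A tibble with one row per configuration and a content-hash
#'   `config_id`.
#' @examples
#' nrow(enumerate_configs(paste0("g", 1:6)))
#' @export
enumerate_configs <- function(graphs,
                              measures = c("vat", "integrity", "tenacity"),
                              k_values = 2:5,
                              modes = c("reassigned", "no_reassignment")) {
  if (is.list(graphs)) graphs <- names(graphs)
  stopifnot(length(graphs) > 0, length(measures) > 0,
            length(k_values) > 0, length(modes) > 0,
            all(measures %in% MEASURES),
            all(modes %in% c("reassigned", "no_reassignment")))
  grid <- tidyr::expand_grid(graph_tag = graphs, measure = measures,
                             k = as.integer(k_values), mode = modes)
  stopifnot(nrow(grid) ==
    length(graphs) * length(measures) * length(k_values) * length(modes))
  grid$config_id <- vapply(seq_len(nrow(grid)), function(i)
    rlang::hash(grid[i, c("graph_tag", "measure", "k", "mode")]), character(1))
  grid
}

#' Run the configuration grid end to end
#'
#' Executes [nbr_clust()] plus [validate_clustering()] for every
#' configuration.  The greedy resilience evaluation is cached per
#' (graph, measure), so varying k and mode reuses one attack-set search.
#' Per-configuration failures are captured as error records without
#' aborting the rest of the grid.  After the grid completes, the SD and
#' CVNN indices are re-normalized across each (measure, mode, graph) family.
#'
#' @param graphs Named list of base graphs (see [base_graph_grid()]).
#' @param points The feature table the graphs were built from (used by the
#'   geometric indices); for a correlation-filtered graph family pass the
#'   table via `points_by_set` instead.
#' @param points_by_set Optional named list mapping a graph's `feature_set`
#'   attribute (e.g. `"all"`, `"corr"`) to its feature table.
#' @param configs Optional configuration tibble from [enumerate_configs()];
#'   defaults to the full grid over `graphs`.
#' @param params,thresholds See [index_params()], [selection_thresholds()].
#' @return A tibble: the configuration columns, an `error` column
#'   (`NA` on success), the fitted clusterings in the list-column
#'   `clustering`, and the validation-report columns.
#' @export
run_grid <- function(graphs, points, points_by_set = NULL, configs = NULL,
                     params = index_params(),
                     thresholds = selection_thresholds()) {
  stopifnot(is.list(graphs), !is.null(names(graphs)))
  configs <- configs %||% enumerate_configs(graphs)
  eval_cache <- new.env(parent = emptyenv())
  rows <- vector("list", nrow(configs))
  clusterings <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, ]
    res <- tryCatch({
      g <- graphs[[cfg$graph_tag]]
      if (is.null(g)) abort(paste0("Unknown graph tag '", cfg$graph_tag, "'."))
      fs <- igraph::graph_attr(g, "feature_set") %||% "all"
      pts <- (points_by_set %||% list())[[fs]] %||% points
      key <- paste(cfg$graph_tag, cfg$measure, sep = "|")
      if (is.null(eval_cache[[key]])) {
        eval_cache[[key]] <- greedy_bc_minimize(g, cfg$measure)
      }
      cl <- nbr_clust(g, cfg$measure, cfg$k, cfg$mode,
                      eval = eval_cache[[key]])
      rep <- validate_clustering(pts, cl, g, params, thresholds)
      rep$graph_tag <- cfg$graph_tag
      list(report = rep, clustering = cl, error = NA_character_)
    }, error = function(e) list(report = NULL, clustering = NULL,
                                error = conditionMessage(e)))
    base <- cfg
    base$error <- res$error
    if (!is.null(res$report)) {
      base <- dplyr::bind_cols(base,
        res$report[setdiff(names(res$report), names(base))])
    }
    rows[[i]] <- base
    clusterings[i] <- list(res$clustering)   # keep NULL slots for failures
  }
  out <- bind_rows(rows)
  out$clustering <- clusterings
  ok <- is.na(out$error)
  if (any(ok)) {
    out[ok, ] <- finalize_family_indices(out[ok, ],
      group_vars = c("graph_tag", "measure", "mode"))
  }
  out
}

#' Rank grid results by majority vote, per attack-set mode
#'
#' Complete-clustering and no-reassignment configurations are ranked
#' separately (they answer different questions about the attack set), each
#' via [select_optimal()].
#'
#' @param results Output of [run_grid()].
#' @param thresholds A [selection_thresholds()] list.
#' @return Named list of ranked tibbles, one per mode present.
#' @export
rank_results <- function(results, thresholds = selection_thresholds()) {
  ok <- results[is.na(results$error), , drop = FALSE]
  if (nrow(ok) == 0L) abort("No successful configuration to rank.")
  ok$clustering <- NULL
  out <- list()
  for (m in unique(ok$mode)) {
    out[[m]] <- select_optimal(ok[ok$mode == m, , drop = FALSE], thresholds)
  }
  out
}
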