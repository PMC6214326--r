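# ggplot2 views of clusterings, greedy traces, and ranked reports.

#' @describeIn nbr_clust Plot a clustering over the point geometry: points
#'   on the first two principal components (or the two features given in
#'   `dims`), coloured by cluster; attack-set nodes are crossed.
#' @param object An `nbr_clustering`.
#' @param points The feature table the clustering was computed from.
#' @param dims Optional character pair of feature names to plot instead of
#'   principal components.
#' @param ... Unused.
#' @export
autoplot.nbr_clustering <- function(object, points, dims = NULL, ...) {
  td <- tidy(object)
  m <- as_feature_matrix(points)
  if (is.null(dims)) {
    if (ncol(m) > 2) {
      pc <- prcomp(m, rank. = 2)
      xy <- pc$x[, 1:2, drop = FALSE]
      axes <- c("PC1", "PC2")
    } else {
      xy <- m[, 1:min(2, ncol(m)), drop = FALSE]
      if (ncol(xy) == 1) xy <- cbind(xy, 0)
      axes <- colnames(m)[1:2]
    }
  } else {
    xy <- m[, dims, drop = FALSE]
    axes <- dims
  }
  df <- tibble(node = rownames(m), x = xy[, 1], y = xy[, 2]) |>
    left_join(td, by = "node") |>
    mutate(cluster = factor(.data$cluster),
           attack = .data$was_attack_node == 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point(size = 1.8, na.rm = TRUE) +
    ggplot2::geom_point(data = df[df$attack, , drop = FALSE],
                        shape = 4, size = 3, colour = "black") +
    ggplot2::labs(x = axes[1], y = axes[2], colour = "cluster",
                  title = paste0("NBR clustering (k = ", object$k, ", ",
                                 object$mode, ")")) +
    ggplot2::theme_minimal()
}

#' @describeIn greedy_bc_minimize Plot the greedy trace: objective value
#'   against attack-set size, with the chosen prefix marked.
#' @param object A `resilience_eval` from [greedy_bc_minimize()].
#' @param ... Unused.
#' @export
autoplot.resilience_eval <- function(object, ...) {
  tr <- tidy(object)
  if (nrow(tr) == 0L) abort("No greedy trace to plot (exact evaluation?).")
  chosen <- length(object$attack_set)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$step, y = .data$objective)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = chosen, linetype = 2, colour = "red") +
    ggplot2::labs(x = "|S| (nodes removed)",
                  y = paste(object$measure, "objective"),
                  title = "Greedy-BC prefix objectives") +
    ggplot2::theme_minimal()
}

#' Plot index votes of ranked configurations
#'
#' Bar chart of majority votes per configuration, admissible configurations
#' filled.
#'
#' @param ranked A ranked tibble from [select_optimal()] or one element of
#'   [rank_results()].
#' @return A ggplot object.
#' @export
plot_votes <- function(ranked) {
  df <- ranked |>
    mutate(config = paste0(.data$graph_tag, " ", .data$measure,
                           " k=", .data$k))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$config,
                                                      .data$votes_won),
                                   y = .data$votes_won,
                                   fill = .data$admissible)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "index votes", fill = "admissible") +
    ggplot2::theme_minimal()
}
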