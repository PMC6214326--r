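# Delimited-text IO for feature tables, labels, and score-range sidecars.

#' Read a delimited feature table
#'
#' Reads a CSV/TSV with a header row into a tibble; a `sample_id` column is
#' kept as identifiers, all other columns must parse as numeric.  Cells
#' matching `na_tokens` become missing values.
#'
#' @param path File path; the delimiter is taken from the extension
#'   (`.tsv` = tab, otherwise comma) unless `delim` is given.
#' @param delim Optional field delimiter.
#' @param na_tokens Strings treated as missing (default empty cell and "NA").
#' @return A tibble of samples by features.
#' @export
read_feature_table <- function(path, delim = NULL,
                               na_tokens = c("", "NA")) {
  delim <- delim %||% if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.delim(path, sep = delim, na.strings = na_tokens,
                          check.names = FALSE, stringsAsFactors = FALSE)
  out <- as_tibble(df)
  for (f in feature_cols(out)) {
    if (!is.numeric(out[[f]])) out[[f]] <- as.numeric(out[[f]])
  }
  out
}

#' @rdname read_feature_table
#' @param data Feature table to write.
#' @export
write_feature_table <- function(data, path, delim = NULL) {
  delim <- delim %||% if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(data, path, sep = delim, quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write cluster label files
#'
#' Tab-separated files with columns `node_id`, `cluster`,
#' `was_attack_node` (0/1); unassigned attack nodes carry an empty cluster.
#'
#' @param clustering An `nbr_clustering`.
#' @param path File path.
#' @name labels_io
#' @export
write_labels <- function(clustering, path) {
  td <- tidy(clustering)
  names(td)[names(td) == "node"] <- "node_id"
  utils::write.table(td, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname labels_io
#' @export
read_labels <- function(path) {
  as_tibble(utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                              colClasses = c(node_id = "character")))
}

#' Read a JSON score-range sidecar
#'
#' The sidecar maps feature name to a two-element `[min, max]` array.
#'
#' @param path JSON file path.
#' @return A tibble with columns `feature`, `min`, `max`.
#' @export
read_ranges <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  tibble(feature = names(raw),
         min = vapply(raw, function(r) r[[1]], numeric(1)),
         max = vapply(raw, function(r) r[[2]], numeric(1)))
}
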