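# Internal helpers shared across modules.

# Names of feature columns: every column except an optional `sample_id`.
feature_cols <- function(data) {
  setdiff(names(data), "sample_id")
}

# Sample identifiers as characters; falls back to row numbers.
sample_ids <- function(data) {
  if ("sample_id" %in% names(data)) {
    as.character(data[["sample_id"]])
  } else {
    as.character(seq_len(nrow(data)))
  }
}

# Numeric matrix of features with sample ids as rownames.
as_feature_matrix <- function(data) {
  feats <- feature_cols(data)
  if (length(feats) == 0L) abort("`data` has no feature columns.")
  bad <- feats[!vapply(data[feats], is.numeric, logical(1))]
  if (length(bad) > 0L) {
    abort(paste0("Non-numeric feature columns: ", toString(bad)))
  }
  m <- as.matrix(data[feats])
  rownames(m) <- sample_ids(data)
  m
}

# Normalise a ranges argument (named list of c(min, max) or a tibble with
# columns feature/min/max) to a named list, or NULL.
as_ranges_list <- function(ranges) {
  if (is.null(ranges)) return(NULL)
  if (is.data.frame(ranges)) {
    stopifnot(all(c("feature", "min", "max") %in% names(ranges)))
    out <- Map(function(lo, hi) c(lo, hi), ranges$min, ranges$max)
    names(out) <- ranges$feature
    return(out)
  }
  if (is.list(ranges)) return(ranges)
  abort("`ranges` must be NULL, a named list, or a feature/min/max data frame.")
}

# Deterministic index of the maximum (first on ties).
which_max_first <- function(x) which.max(x)
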