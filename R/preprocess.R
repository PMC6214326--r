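#' Mean-impute missing values in selected feature columns
#'
#' Replaces every `NA` in the chosen columns with the arithmetic mean of the
#' observed values of that column.  Observed entries are never altered.
#'
#' @param data A data frame of samples (rows) by numeric features (columns).
#'   An optional `sample_id` column is carried through untouched.
#' @param features Character vector of feature names to impute.  Defaults to
#'   every feature column that contains at least one `NA`.
#' @return A tibble of the same shape with the selected columns completed.
#'   The number of values imputed per feature is recorded in the
#'   `"imputed"` attribute.
#' @examples
#' impute_mean(data.frame(x = c(1, NA, 3)))
#' @export
impute_mean <- function(data, features = NULL) {
  feats <- feature_cols(data)
  if (is.null(features)) {
    features <- feats[vapply(data[feats], anyNA, logical(1))]
  }
  missing_feats <- setdiff(features, feats)
  if (length(missing_feats) > 0L) {
    abort(paste0("Unknown feature(s): ", toString(missing_feats)))
  }
  out <- as_tibble(data)
  counts <- integer(0)
  for (f in features) {
    col <- out[[f]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss)) {
      abort(paste0("Feature '", f, "' is entirely missing; no basis for mean imputation."))
    }
    col[miss] <- mean(col[!miss])
    out[[f]] <- col
    counts[f] <- sum(miss)
  }
  attr(out, "imputed") <- counts
  out
}

#' Regression-impute missing values in target feature columns
#'
#' For each target feature, fits an ordinary least-squares model of that
#' feature on all other features and fills its missing entries with model
#' predictions.  Training rows are those where the target is observed;
#' predictor gaps are mean-imputed for the fit and the prediction only.
#' Predictions are clipped to the feature's known score range when `ranges`
#' supplies one.  A rank-deficient design (or too few training rows) falls
#' back to mean imputation with a warning.
#'
#' @inheritParams impute_mean
#' @param features Character vector of target features to impute.
#' @param ranges Optional known score ranges: a named list of `c(min, max)`
#'   or a data frame with columns `feature`, `min`, `max`.
#' @return A tibble with the target columns completed; attribute `"imputed"`
#'   counts imputations per feature.
#' @examples
#' d <- data.frame(x = c(1, 2, 3, 4), y = c(2, 4, NA, 8))
#' impute_regression(d, "y")
#' @export
impute_regression <- function(data, features, ranges = NULL) {
  feats <- feature_cols(data)
  stopifnot(all(features %in% feats))
  ranges <- as_ranges_list(ranges)
  out <- as_tibble(data)
  counts <- integer(0)
  for (f in features) {
    y <- out[[f]]
    miss <- is.na(y)
    if (!any(miss)) next
    if (all(miss)) abort(paste0("Feature '", f, "' is entirely missing."))
    preds <- setdiff(feats, f)
    x <- as.matrix(out[preds])
    # mean-impute predictor gaps for fitting/prediction only
    for (j in seq_len(ncol(x))) {
      xm <- is.na(x[, j])
      if (all(xm)) abort(paste0("Predictor '", preds[j], "' is entirely missing."))
      if (any(xm)) x[xm, j] <- mean(x[!xm, j])
    }
    design <- cbind(1, x[!miss, , drop = FALSE])
    deficient <- nrow(design) < ncol(design) ||
      qr(design)$rank < ncol(design)
    if (deficient) {
      warn(paste0("Design for feature '", f,
                  "' is rank-deficient; falling back to mean imputation."))
      y[miss] <- mean(y[!miss])
    } else {
      fit <- lm.fit(design, y[!miss])
      pred <- cbind(1, x[miss, , drop = FALSE]) %*% fit$coefficients
      if (!is.null(ranges[[f]])) {
        pred <- pmin(pmax(pred, ranges[[f]][1]), ranges[[f]][2])
      }
      y[miss] <- as.numeric(pred)
    }
    out[[f]] <- y
    counts[f] <- sum(miss)
  }
  attr(out, "imputed") <- counts
  out
}

#' Normalize features to the unit interval
#'
#' Maps each feature value `x` to `(x - min) / (max - min)` using the known
#' score range when supplied and the observed range otherwise (reported via
#' a message so runs are auditable).  Constant-range features map to 0.
#'
#' @inheritParams impute_regression
#' @return A tibble with all feature columns in `[0, 1]`.
#' @examples
#' normalize_features(data.frame(x = c(2, 4, 6)))
#' @export
normalize_features <- function(data, ranges = NULL) {
  feats <- feature_cols(data)
  if (anyNA(data[feats])) {
    abort("`data` has missing values; impute before normalizing.")
  }
  ranges <- as_ranges_list(ranges)
  out <- as_tibble(data)
  fallback <- character(0)
  for (f in feats) {
    r <- ranges[[f]]
    if (is.null(r)) {
      r <- range(out[[f]])
      fallback <- c(fallback, f)
    } else if (r[2] <= r[1]) {
      abort(paste0("Invalid range for feature '", f, "': max <= min."))
    }
    if (r[2] == r[1]) {
      out[[f]] <- rep(0, nrow(out))
    } else {
      out[[f]] <- (out[[f]] - r[1]) / (r[2] - r[1])
    }
  }
  if (length(fallback) > 0L) {
    inform(paste0("Observed-range fallback used for: ", toString(fallback)))
  }
  out
}

#' Remove highly correlated features
#'
#' Iteratively removes one member of the most-correlated feature pair while
#' any pair exceeds the threshold in absolute Pearson correlation.  From the
#' offending pair, the feature with the larger mean absolute correlation to
#' all remaining features is dropped (ties drop the later column).
#' Zero-variance columns have their correlations treated as 0 and are never
#' removed on that account.
#'
#' @inheritParams impute_mean
#' @param threshold Absolute correlation above which a pair is considered
#'   redundant; the default mirrors the common choice of 0.8.
#' @return The reduced tibble.  Attribute `"removed"` holds the dropped
#'   feature names in removal order (also retrievable with
#'   [removed_features()]).
#' @examples
#' d <- data.frame(a = 1:5, b = (1:5) * 2, c = c(5, 3, 4, 1, 2))
#' removed_features(correlation_filter(d, 0.8))
#' @export
correlation_filter <- function(data, threshold = 0.8) {
  feats <- feature_cols(data)
  if (length(feats) < 2L) abort("Need at least two features.")
  if (anyNA(data[feats])) abort("`data` has missing values.")
  stopifnot(threshold > 0, threshold <= 1)
  x <- as.matrix(data[feats])
  constant <- apply(x, 2, function(col) var(col) == 0)
  if (any(constant)) {
    inform(paste0("Zero-variance feature(s) treated as uncorrelated: ",
                  toString(feats[constant])))
  }
  removed <- character(0)
  keep <- feats
  repeat {
    if (length(keep) < 2L) break
    cm <- suppressWarnings(abs(cor(x[, keep, drop = FALSE])))
    cm[!is.finite(cm)] <- 0
    diag(cm) <- 0
    if (max(cm) <= threshold) break
    idx <- which(cm == max(cm), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    # mean |r| to all remaining features (self excluded)
    mi <- mean(cm[i, -i]); mj <- mean(cm[j, -j])
    drop_idx <- if (mi > mj) i else j    # tie drops the later column j
    removed <- c(removed, keep[drop_idx])
    keep <- keep[-drop_idx]
  }
  out <- as_tibble(data)[c(intersect(names(data), "sample_id"), keep)]
  attr(out, "removed") <- removed
  out
}

#' Features removed by the last correlation filter
#'
#' @param data A tibble returned by [correlation_filter()].
#' @return Character vector of removed feature names (possibly empty).
#' @export
removed_features <- function(data) {
  attr(data, "removed") %||% character(0)
}
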