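# Seeded generators: Gaussian-mixture feature tables, named toy graphs, and
# a phenotype-style benchmark table with the structure the pipeline assumes.

# Cluster centers with pairwise distance >= separation (rejection sampling
# in a box that grows until placement succeeds).
place_centers <- function(k, d, separation) {
  box <- separation * max(2, ceiling(k^(1 / d)) + 1)
  repeat {
    for (attempt in seq_len(200)) {
      centers <- matrix(runif(k * d, 0, box), k, d)
      if (k == 1L || min(dist(centers)) >= separation) return(centers)
    }
    box <- box * 1.5
  }
}

#' Gaussian-mixture feature table with planted labels
#'
#' Draws `n` points from `k_true` isotropic Gaussian clusters (unit
#' within-cluster standard deviation) whose centers are at least
#' `separation` standard deviations apart.  A fraction of points is replaced
#' by uniform outliers over the bounding box; optional near-duplicate
#' feature pairs (correlation > 0.9) and random missingness can be added.
#' Fully deterministic given `seed`.
#'
#' @param n Number of samples (>= 10 per planted cluster).
#' @param d Number of base features.
#' @param k_true Number of planted clusters.
#' @param separation Between-center distance in within-cluster sd units;
#'   the default 8 gives the clearly separated regime used for recovery
#'   benchmarks.
#' @param outlier_fraction Fraction of samples drawn uniform over the
#'   bounding box instead (in `[0, 0.2]`).
#' @param correlated_pairs Number of extra features appended as noisy copies
#'   of existing ones.
#' @param missing_fraction Fraction of cells masked as `NA`.
#' @param seed Integer seed.
#' @return A list: `data` (tibble with `sample_id` + features), `labels`
#'   (tibble `sample_id`, `planted_cluster`, `is_outlier`; outliers carry
#'   `planted_cluster = NA`), and `ranges` (feature/min/max tibble of the
#'   declared score ranges that all generated values respect).
#' @examples
#' sim <- gaussian_mixture_table(n = 60, d = 2, k_true = 2, seed = 1)
#' table(sim$labels$planted_cluster)
#' @export
gaussian_mixture_table <- function(n, d, k_true, separation = 8,
                                   outlier_fraction = 0,
                                   correlated_pairs = 0,
                                   missing_fraction = 0, seed = 1) {
  stopifnot(k_true >= 1, n >= 10 * k_true, d >= 1,
            outlier_fraction >= 0, outlier_fraction <= 0.2,
            missing_fraction >= 0, missing_fraction < 1,
            correlated_pairs >= 0, correlated_pairs <= d)
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    centers <- place_centers(k_true, d, separation)
    lab <- rep(seq_len(k_true) - 1L, length.out = n)
    x <- centers[lab + 1L, , drop = FALSE] + matrix(rnorm(n * d), n, d)
    # declared score ranges: the cluster box padded by 4 sd
    lo <- apply(centers, 2, min) - 4
    hi <- apply(centers, 2, max) + 4
    x <- pmin(pmax(x, matrix(lo, n, d, byrow = TRUE)),
              matrix(hi, n, d, byrow = TRUE))
    n_out <- round(outlier_fraction * n)
    is_out <- rep(FALSE, n)
    if (n_out > 0) {
      pick <- sample.int(n, n_out)
      is_out[pick] <- TRUE
      lab[pick] <- NA_integer_
      x[pick, ] <- matrix(runif(n_out * d, rep(lo, each = n_out),
                                rep(hi, each = n_out)), n_out, d)
    }
    feat_names <- paste0("f", seq_len(d))
    if (correlated_pairs > 0) {
      for (p in seq_len(correlated_pairs)) {
        src <- ((p - 1L) %% d) + 1L
        x <- cbind(x, x[, src] + rnorm(n, sd = 0.1))
        feat_names <- c(feat_names, paste0("f", src, "_dup"))
        lo <- c(lo, lo[src] - 1); hi <- c(hi, hi[src] + 1)
      }
    }
    if (missing_fraction > 0) {
      mask <- matrix(runif(length(x)) < missing_fraction, nrow(x), ncol(x))
      x[mask] <- NA_real_
    }
    colnames(x) <- feat_names
    list(
      data = dplyr::bind_cols(tibble(sample_id = paste0("s", seq_len(n))),
                              as_tibble(x)),
      labels = tibble(sample_id = paste0("s", seq_len(n)),
                      planted_cluster = lab, is_outlier = is_out),
      ranges = tibble(feature = feat_names, min = lo, max = hi))
  })
}

#' Named toy graphs for resilience fixtures
#'
#' Deterministic unit-weight graphs with vertex names `"0", "1", ...`:
#' `star` (center `"0"`), `path`, `cycle`, `complete`, `barbell` (two equal
#' cliques joined by one bridge edge; `size` must be even), and
#' `bridge_cliques` (alias of `barbell`).
#'
#' @param name One of `"star"`, `"path"`, `"cycle"`, `"complete"`,
#'   `"barbell"`, `"bridge_cliques"`.
#' @param size Total number of vertices.
#' @return An igraph with `weight = 1` on every edge.
#' @examples
#' igraph::ecount(toy_graph("complete", 5))
#' @export
toy_graph <- function(name, size) {
  stopifnot(size >= 2)
  g <- switch(name,
    star = igraph::make_star(size, mode = "undirected", center = 1),
    path = igraph::make_ring(size, circular = FALSE),
    cycle = igraph::make_ring(size, circular = TRUE),
    complete = igraph::make_full_graph(size),
    barbell = ,
    bridge_cliques = {
      stopifnot(size %% 2 == 0, size >= 4)
      half <- size %/% 2
      gg <- igraph::disjoint_union(igraph::make_full_graph(half),
                                   igraph::make_full_graph(half))
      igraph::add_edges(gg, c(half, half + 1))   # bridge between cliques
    },
    abort(paste0("Unknown toy graph '", name, "'."))
  )
  igraph::V(g)$name <- as.character(seq_len(size) - 1L)
  igraph::E(g)$weight <- 1
  g
}

# The 36 phenotype-style feature names, grouped as in standard ASD batteries.
phenotype_feature_inventory <- function() {
  list(
    asd_symptoms = c("ados_comm_social", "ados_rrb", "ados_social_affect",
                     "adir_social_a", "adir_verbal_b", "adir_repetitive_c",
                     "adir_q86_abnormality"),
    cognitive_adaptive = c("vineland_social", "vineland_daily_living",
                           "verbal_iq", "nonverbal_iq"),
    language_comm = c("vineland_communication", "regression", "word_delay",
                      "adir_q30_language"),
    behavioral = c("abc_stereotypy", "abc_lethargy", "abc_irritability",
                   "abc_hyperactivity", "abc_inappropriate_speech",
                   "rbs_compulsive", "rbs_self_injurious", "rbs_stereotyped",
                   "rbs_ritualistic", "rbs_restricted", "rbs_sameness",
                   "cbcl_internalizing", "cbcl_externalizing"),
    srs = c("srs_awareness", "srs_cognition", "srs_communication",
            "srs_mannerisms", "srs_motivation", "srs_t_score"),
    genetic = c("bapq_father", "bapq_mother"))
}

#' Synthetic phenotype-style benchmark table
#'
#' A 500 x 36 table mimicking the shape of a multi-instrument phenotype
#' battery (entirely synthetic; scores carry no clinical meaning).  It has
#' four planted severity subgroups loading on all instruments, three
#' near-duplicate feature columns so that [correlation_filter()] at 0.8
#' removes exactly three features, and about 0.1% missing cells concentrated
#' (>= 90%) in two designated features — the structure the preprocessing
#' pipeline is designed to handle.
#'
#' @param seed Integer seed.
#' @param n Number of samples (default 500).
#' @return A list: `data`, `labels` (planted subgroup per sample), `ranges`
#'   (declared score ranges for normalization), and `missing_targets` (the
#'   two features holding most of the missingness, the intended targets of
#'   [impute_regression()]).
#' @export
phenotype_like_table <- function(seed = 1, n = 500) {
  inv <- phenotype_feature_inventory()
  feats <- unname(unlist(inv))
  # the three engineered near-duplicates (mirroring a filtered 33-feature set)
  dup_map <- c(ados_social_affect = "ados_comm_social",
               verbal_iq = "nonverbal_iq",
               srs_t_score = "srs_communication")
  base_feats <- setdiff(feats, names(dup_map))
  d <- length(base_feats)
  set.seed(seed)
  k <- 4L
  severity <- seq(-1.5, 1.5, length.out = k)
  lab <- rep(seq_len(k) - 1L, length.out = n)
  load <- runif(d, 0.7, 1.3)              # per-feature severity loading
  sigma <- runif(d, 1.0, 1.5)             # independent instrument noise
  z <- outer(severity[lab + 1L], load) +
    matrix(rnorm(n * d), n, d) * matrix(sigma, n, d, byrow = TRUE)
  colnames(z) <- base_feats
  x <- matrix(NA_real_, n, length(feats), dimnames = list(NULL, feats))
  x[, base_feats] <- z
  for (dup in names(dup_map)) {
    x[, dup] <- x[, dup_map[[dup]]] + rnorm(n, sd = 0.25)
  }
  # map the latent scores onto plausible instrument scales
  lo <- setNames(rep(0, length(feats)), feats)
  hi <- setNames(rep(100, length(feats)), feats)
  hi[grep("^ados|^adir", feats)] <- 30
  hi[grep("^rbs|^abc", feats)] <- 50
  hi[c("regression", "word_delay")] <- 5
  hi[c("bapq_father", "bapq_mother")] <- 6
  hi[grep("iq$", feats)] <- 160
  for (j in seq_along(feats)) {
    f <- feats[j]
    span <- hi[f] - lo[f]
    x[, f] <- lo[f] + span * (x[, f] - (-6)) / 12   # latent in ~[-6, 6]
    x[, f] <- pmin(pmax(x[, f], lo[f]), hi[f])
  }
  # ~0.1% missing cells, >= 90% of them in the two designated features
  targets <- c("vineland_social", "cbcl_internalizing")
  n_missing <- round(0.001 * n * length(feats))
  n_target <- ceiling(0.92 * n_missing)
  for (t in seq_len(n_target)) {
    x[sample.int(n, 1), targets[((t - 1) %% 2) + 1]] <- NA_real_
  }
  other <- setdiff(feats, targets)
  for (t in seq_len(n_missing - n_target)) {
    x[sample.int(n, 1), sample(other, 1)] <- NA_real_
  }
  list(
    data = dplyr::bind_cols(tibble(sample_id = paste0("p", seq_len(n))),
                            as_tibble(x)),
    labels = tibble(sample_id = paste0("p", seq_len(n)),
                    planted_cluster = lab, is_outlier = FALSE),
    ranges = tibble(feature = feats, min = unname(lo), max = unname(hi)),
    missing_targets = targets)
}
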