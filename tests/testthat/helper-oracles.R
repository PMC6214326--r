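# Independent oracles used only by the tests: plain-loop implementations of
# component finding, the resilience formulas, and the validation indices.

# Connected components by breadth-first search over an adjacency matrix.
oracle_components <- function(adj, keep) {
  n <- length(keep)
  visited <- rep(FALSE, sum(keep))
  idx <- which(keep)
  sizes <- integer(0)
  seen <- rep(FALSE, n)
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      nbrs <- which(adj[v, ] & keep & !seen)
      seen[nbrs] <- TRUE
      queue <- c(queue, nbrs)
    }
    sizes <- c(sizes, size)
  }
  sizes
}

# Direct evaluation of the three resilience formulas for attack set `s_idx`
# (integer indices) on adjacency matrix `adj`.
oracle_objective <- function(adj, s_idx, measure) {
  n <- nrow(adj)
  keep <- rep(TRUE, n); keep[s_idx] <- FALSE
  sizes <- oracle_components(adj, keep)
  cmax <- if (length(sizes)) max(sizes) else 0L
  s <- length(s_idx)
  switch(measure,
         vat = s / (n - s - cmax + 1),
         integrity = (s + cmax) / n,
         tenacity = (s + cmax) / length(sizes))
}

# Random connected graph with unit weights and names "1".."n".
random_connected_graph <- function(n, p = 0.35) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- as.character(seq_len(n))
  igraph::E(g)$weight <- 1
  g
}

adjacency_of <- function(g) igraph::as_adjacency_matrix(g, sparse = FALSE) > 0

# Adjusted Rand index between a fitted clustering and planted labels,
# scored on assigned (non-NA) nodes only.
fixture_ari <- function(clustering, truth) {
  m <- merge(tidy(clustering), truth, by.x = "node", by.y = "sample_id")
  m <- m[!is.na(m$cluster) & !is.na(m$planted_cluster), ]
  mclust::adjustedRandIndex(m$cluster, m$planted_cluster)
}

# ---- naive index oracles (plain double loops, no shared code) ------------

omat <- function(points) {
  m <- as.matrix(points[setdiff(names(points), "sample_id")])
  rownames(m) <- if ("sample_id" %in% names(points))
    as.character(points$sample_id) else as.character(seq_len(nrow(m)))
  m
}

ed <- function(a, b) sqrt(sum((a - b)^2))

oracle_silhouette <- function(x, lab) {
  ids <- sort(unique(lab))
  per_cluster <- sapply(ids, function(ci) {
    members <- which(lab == ci)
    mean(sapply(members, function(p) {
      if (length(members) == 1) return(0)
      a <- mean(sapply(setdiff(members, p), function(q) ed(x[p, ], x[q, ])))
      b <- min(sapply(setdiff(ids, ci), function(cj)
        mean(sapply(which(lab == cj), function(q) ed(x[p, ], x[q, ])))))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }))
  })
  mean(per_cluster)
}

oracle_ch <- function(x, lab) {
  ids <- sort(unique(lab)); k <- length(ids); n <- nrow(x)
  c_all <- colMeans(x)
  between <- sum(sapply(ids, function(ci) {
    m <- x[lab == ci, , drop = FALSE]
    nrow(m) * ed(colMeans(m), c_all)^2
  }))
  within <- sum(sapply(ids, function(ci) {
    m <- x[lab == ci, , drop = FALSE]
    sum(apply(m, 1, function(r) ed(r, colMeans(m))^2))
  }))
  if (within == 0) return(Inf)
  (between / (k - 1)) / (within / (n - k))
}

oracle_db <- function(x, lab) {
  ids <- sort(unique(lab)); k <- length(ids)
  cen <- t(sapply(ids, function(ci) colMeans(x[lab == ci, , drop = FALSE])))
  s <- sapply(ids, function(ci) {
    m <- x[lab == ci, , drop = FALSE]
    mean(apply(m, 1, function(r) ed(r, colMeans(m))))
  })
  mean(sapply(seq_len(k), function(i)
    max(sapply(setdiff(seq_len(k), i), function(j)
      (s[i] + s[j]) / ed(cen[i, ], cen[j, ])))))
}

oracle_dunn <- function(x, lab) {
  ids <- sort(unique(lab))
  inter <- Inf; diam <- 0
  for (p in seq_len(nrow(x))) for (q in seq_len(nrow(x))) {
    if (p == q) next
    d <- ed(x[p, ], x[q, ])
    if (lab[p] == lab[q]) diam <- max(diam, d) else inter <- min(inter, d)
  }
  inter / diam
}

oracle_xb <- function(x, lab) {
  ids <- sort(unique(lab))
  cen <- t(sapply(ids, function(ci) colMeans(x[lab == ci, , drop = FALSE])))
  within <- sum(sapply(seq_along(ids), function(i)
    sum(apply(x[lab == ids[i], , drop = FALSE], 1,
              function(r) ed(r, cen[i, ])^2))))
  mind2 <- min(sapply(seq_along(ids), function(i)
    sapply(seq_along(ids), function(j)
      if (i == j) Inf else ed(cen[i, ], cen[j, ])^2)))
  within / (nrow(x) * mind2)
}

oracle_varnorm <- function(m) {
  v <- colMeans(m^2) - colMeans(m)^2
  sqrt(sum(v^2))
}

oracle_scat <- function(x, lab) {
  ids <- sort(unique(lab))
  mean(sapply(ids, function(ci) oracle_varnorm(x[lab == ci, , drop = FALSE]))) /
    oracle_varnorm(x)
}

oracle_dis <- function(x, lab) {
  ids <- sort(unique(lab)); k <- length(ids)
  cen <- t(sapply(ids, function(ci) colMeans(x[lab == ci, , drop = FALSE])))
  cd <- as.matrix(dist(cen))
  off <- cd[upper.tri(cd)]
  (max(off) / min(off)) * sum(1 / rowSums(cd))
}

oracle_sdbw <- function(x, lab) {
  ids <- sort(unique(lab)); k <- length(ids)
  cen <- t(sapply(ids, function(ci) colMeans(x[lab == ci, , drop = FALSE])))
  stdev <- mean(sapply(ids, function(ci)
    oracle_varnorm(x[lab == ci, , drop = FALSE])))
  f <- function(pts, u) sum(apply(pts, 1, function(r) ed(r, u)) <= stdev)
  total <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    pts <- x[lab %in% ids[c(i, j)], , drop = FALSE]
    denom <- max(f(pts, cen[i, ]), f(pts, cen[j, ]))
    if (denom > 0) total <- total + f(pts, (cen[i, ] + cen[j, ]) / 2) / denom
  }
  oracle_scat(x, lab) + total / (k * (k - 1))
}

oracle_i_index <- function(x, lab, p = 2) {
  ids <- sort(unique(lab)); k <- length(ids)
  cen <- t(sapply(ids, function(ci) colMeans(x[lab == ci, , drop = FALSE])))
  c_all <- colMeans(x)
  num <- sum(apply(x, 1, function(r) ed(r, c_all)))
  within <- sum(sapply(seq_len(k), function(i)
    sum(apply(x[lab == ids[i], , drop = FALSE], 1,
              function(r) ed(r, cen[i, ])))))
  maxcd <- max(dist(cen))
  (num / (k * within) * maxcd)^p
}

oracle_cvnn_terms <- function(x, lab, nn) {
  ids <- sort(unique(lab)); n <- nrow(x)
  d <- as.matrix(dist(x))
  sep <- max(sapply(ids, function(ci) {
    members <- which(lab == ci)
    mean(sapply(members, function(p) {
      ord <- order(d[p, ], seq_len(n))
      ord <- ord[ord != p][seq_len(nn)]
      sum(lab[ord] != ci) / nn
    }))
  }))
  com <- sum(sapply(ids, function(ci) {
    members <- which(lab == ci); ni <- length(members)
    if (ni < 2) return(0)
    tot <- 0
    for (a in seq_len(ni - 1)) for (b in (a + 1):ni)
      tot <- tot + ed(x[members[a], ], x[members[b], ])
    2 / (ni * (ni - 1)) * tot
  }))
  list(sep = sep, com = com)
}
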