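# Validation indices, graph quality, and majority-vote selection.

two_pair_config <- function(y2 = 1) {
  list(points = tibble::tibble(x = c(0, 0, 10, 10), y = c(0, y2, 0, y2)),
       labels = c(0, 0, 1, 1))
}

test_that("indices reproduce the hand-computed 4-point values", {
  cfg1 <- two_pair_config(1)
  expect_equal(silhouette_index(cfg1$points, cfg1$labels),
               (10 + sqrt(101)) / 2 * 2 / (10 + sqrt(101)) - 1 /
                 ((10 + sqrt(101)) / 2), tolerance = 1e-9)
  expect_equal(round(silhouette_index(cfg1$points, cfg1$labels), 4), 0.9002)
  expect_equal(dunn_index(cfg1$points, cfg1$labels), 10)
  cfg2 <- two_pair_config(2)
  expect_equal(calinski_harabasz_index(cfg2$points, cfg2$labels), 50)
  expect_equal(davies_bouldin_index(cfg2$points, cfg2$labels), 0.2)
  expect_equal(xie_beni_index(cfg2$points, cfg2$labels), 0.01)
  geo <- geometric_validity_suite(cfg2$points, cfg2$labels,
                                  index_params(cvnn_nn = 1))
  expect_equal(geo$scat, 1 / sqrt(626), tolerance = 1e-9)
  expect_equal(geo$I, 650, tolerance = 1e-9)
  expect_equal(geo$sep_raw, 0)   # nearest neighbour is always intra-cluster
})

test_that("degenerate configurations follow the documented conventions", {
  dup <- tibble::tibble(x = c(0, 0, 5, 5), y = c(0, 0, 0, 0))
  expect_equal(silhouette_index(dup, c(0, 0, 1, 1)), 1)   # a = 0
  allsame <- tibble::tibble(x = rep(1, 4), y = rep(2, 4))
  expect_equal(silhouette_index(allsame, c(0, 0, 1, 1)), 0)
  expect_message(ch <- calinski_harabasz_index(dup, c(0, 0, 1, 1)), "Inf")
  expect_equal(ch, Inf)
  singles <- tibble::tibble(x = c(0, 9), y = c(0, 0))
  expect_equal(davies_bouldin_index(singles, c(0, 1)), 0)
  expect_error(dunn_index(singles, c(0, 1)), "singleton")
  expect_error(davies_bouldin_index(allsame, c(0, 0, 1, 1)), "Coincident")
  expect_error(silhouette_index(dup, c(0, 0, 0, 0)), "two clusters")
})

test_that("all nine indices agree with the direct-formula oracles", {
  set.seed(19)
  for (rep in 1:10) {
    n <- sample(12:20, 1)
    k <- sample(2:4, 1)
    lab <- sample(0:(k - 1), n, replace = TRUE)
    lab[1:k] <- 0:(k - 1)                 # every cluster non-empty
    centers <- matrix(runif(k * 2, 0, 6), k, 2)
    x <- centers[lab + 1, , drop = FALSE] + matrix(rnorm(n * 2), n, 2)
    pts <- tibble::as_tibble(as.data.frame(x)); names(pts) <- c("f1", "f2")
    expect_equal(silhouette_index(pts, lab), oracle_silhouette(x, lab),
                 tolerance = 1e-9)
    expect_equal(calinski_harabasz_index(pts, lab), oracle_ch(x, lab),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin_index(pts, lab), oracle_db(x, lab),
                 tolerance = 1e-9)
    expect_equal(dunn_index(pts, lab), oracle_dunn(x, lab), tolerance = 1e-9)
    expect_equal(xie_beni_index(pts, lab), oracle_xb(x, lab), tolerance = 1e-9)
    geo <- geometric_validity_suite(pts, lab, index_params(cvnn_nn = 3))
    expect_equal(geo$scat, oracle_scat(x, lab), tolerance = 1e-9)
    expect_equal(geo$dis, oracle_dis(x, lab), tolerance = 1e-9)
    expect_equal(geo$SD, oracle_dis(x, lab) * oracle_scat(x, lab) +
                   oracle_dis(x, lab), tolerance = 1e-9)
    expect_equal(geo$S_Dbw, oracle_sdbw(x, lab), tolerance = 1e-9)
    expect_equal(geo$I, oracle_i_index(x, lab), tolerance = 1e-9)
    cv <- oracle_cvnn_terms(x, lab, 3)
    expect_equal(geo$sep_raw, cv$sep, tolerance = 1e-9)
    expect_equal(geo$com_raw, cv$com, tolerance = 1e-9)
  }
})

test_that("index ranges hold on randomized inputs", {
  set.seed(29)
  for (rep in 1:10) {
    n <- sample(10:16, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    lab <- sample(0:1, n, replace = TRUE); lab[1:2] <- 0:1
    pts <- tibble::as_tibble(as.data.frame(x))
    si <- silhouette_index(pts, lab)
    expect_gte(si, -1); expect_lte(si, 1)
    expect_gte(dunn_index(pts, lab), 0)
    expect_gte(calinski_harabasz_index(pts, lab), 0)
    g <- random_connected_graph(n)
    glab <- setNames(lab, as.character(seq_len(n)))
    q <- graph_modularity(g, glab)
    expect_lte(q, 1)
    cond <- graph_conductance(g, glab)
    expect_gte(as.numeric(cond), 0); expect_lte(as.numeric(cond), 1)
  }
})

test_that("modularity and conductance match hand counts on toy graphs", {
  tri2 <- igraph::disjoint_union(igraph::make_full_graph(3),
                                 igraph::make_full_graph(3))
  igraph::V(tri2)$name <- as.character(0:5)
  igraph::E(tri2)$weight <- 1
  lab <- setNames(c(0, 0, 0, 1, 1, 1), as.character(0:5))
  expect_equal(graph_modularity(tri2, lab), 0.5)
  expect_equal(as.numeric(graph_conductance(tri2, lab)), 0)  # disjoint
  bridged <- toy_graph("bridge_cliques", 6)
  expect_equal(as.numeric(graph_conductance(bridged, lab)), 1 / 7)
  expect_equal(unname(attr(graph_conductance(bridged, lab), "per_cluster")),
               c(1 / 7, 1 / 7))
  one <- setNames(rep(0, 6), as.character(0:5))
  expect_equal(graph_modularity(bridged, one), 0)
  expect_equal(as.numeric(graph_conductance(bridged, one)), 0)
})

test_that("separated mixtures score best at the planted k", {
  sim <- gaussian_mixture_table(n = 90, d = 3, k_true = 3, separation = 8,
                                seed = 8)
  truth <- sim$labels$planted_cluster
  x <- sim$data
  si_true <- silhouette_index(x, truth)
  wrong <- (truth + (seq_along(truth) %% 2)) %% 3   # corrupted labels
  expect_gt(si_true, silhouette_index(x, wrong))
  expect_gt(calinski_harabasz_index(x, truth), calinski_harabasz_index(x, wrong))
  expect_gt(dunn_index(x, truth), dunn_index(x, wrong))
})

test_that("majority-vote selection gates, votes, and ranks as documented", {
  mk_report <- function(si, ch, db, dunn, xb, sd, sdbw, ii, cvnn,
                        mod, cond, minsz, n = 100) {
    tibble::tibble(graph_tag = "g", measure = "vat", k = 2, mode = "reassigned",
                   SI = si, CH = ch, DB = db, Dunn = dunn, XB = xb, SD = sd,
                   S_Dbw = sdbw, I = ii, CVNN = cvnn,
                   scat = 0.1, dis = 1, sep_raw = 0.1, com_raw = 1,
                   modularity = mod, conductance = cond,
                   conductance_mean = cond, min_cluster_size = minsz,
                   n_scored = n, n_total = n, admissible = NA)
  }
  # single surviving report wins all nine votes
  one <- mk_report(0.5, 10, 1, 1, 0.1, 1, 1, 5, 1, 0.7, 0.02, 30)
  out <- select_optimal(one)
  expect_equal(out$votes_won, 9)
  # A better on 6 indices, B on 3
  a <- mk_report(0.9, 100, 0.5, 2, 0.05, 2, 2, 10, 2, 0.7, 0.02, 30)
  b <- mk_report(0.2, 10, 0.9, 1, 0.50, 1, 1, 2, 1, 0.7, 0.02, 30)
  out2 <- select_optimal(dplyr::bind_rows(a, b))
  expect_equal(out2$votes_won, c(6, 3))
  expect_equal(out2$rank, c(1, 2))
  # a report below the size floor is excluded before voting
  small <- mk_report(0.99, 999, 0.1, 9, 0.01, 0.1, 0.1, 99, 0.1, 0.9, 0.01,
                     minsz = 0)
  out3 <- select_optimal(dplyr::bind_rows(a, small))
  expect_equal(nrow(out3), 1)
  expect_equal(out3$votes_won, 9)
  expect_error(select_optimal(small), "floor")
  # an inadmissible report never outranks an admissible one with equal votes
  bad_gate <- mk_report(0.9, 100, 0.5, 2, 0.05, 2, 2, 10, 2,
                        mod = 0.2, cond = 0.5, minsz = 30)
  out4 <- select_optimal(dplyr::bind_rows(bad_gate, a))
  expect_true(out4$admissible[1])
})
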