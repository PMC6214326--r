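# Components-to-clusters, attack-set reassignment, merge/split adjustment.

test_that("components after removal become 0-based contiguous clusters", {
  star <- toy_graph("star", 6)
  cl <- components_after_removal(star, "0")
  expect_equal(cl$k, 5)
  expect_setequal(cl$unassigned, "0")
  expect_equal(sort(unique(cl$labels)), 0:4)
  p5 <- toy_graph("path", 5)
  cl2 <- components_after_removal(p5, "2")
  expect_equal(cl2$k, 2)
  expect_equal(unname(cl2$labels[c("0", "1")]), c(0, 0))
  expect_equal(unname(cl2$labels[c("3", "4")]), c(1, 1))
  cl3 <- components_after_removal(p5, character(0))
  expect_equal(cl3$k, 1)
  expect_length(cl3$labels, 5)
})

test_that("reassignment follows neighbour plurality with documented ties", {
  # node 9 has two neighbours in cluster 1, one in cluster 0
  g <- igraph::make_graph(~ a - b, c - d, c - e, x - a, x - c, x - d)
  igraph::E(g)$weight <- 1
  cl <- components_after_removal(g, "x")
  cl2 <- reassign_attack_set(g, cl)
  expect_equal(cl2$labels[["x"]], cl2$labels[["c"]])
  expect_equal(cl2$mode, "reassigned")
  expect_length(cl2$unassigned, 0)
  # star centre with 5 singleton leaf clusters: ties resolve to cluster 0
  star <- toy_graph("star", 6)
  cls <- reassign_attack_set(star, components_after_removal(star, "0"))
  expect_equal(cls$labels[["0"]], 0)
  # chain of two attack nodes: the inner one inherits through the outer
  chain <- igraph::make_graph(~ a - b, b - x, x - y)
  igraph::E(chain)$weight <- 1
  cl3 <- components_after_removal(chain, c("x", "y"))
  cl4 <- reassign_attack_set(chain, cl3)
  expect_equal(unname(cl4$labels[c("x", "y")]), c(0, 0))
})

test_that("reassignment never relabels an already-labelled node", {
  set.seed(13)
  g <- random_connected_graph(15)
  ev <- greedy_bc_minimize(g, "integrity")
  cl <- components_after_removal(g, ev$attack_set)
  cl2 <- reassign_attack_set(g, cl)
  expect_identical(cl2$labels[names(cl$labels)], cl$labels)
})

test_that("merging maximizes the normalized-cut score pair by pair", {
  # clusters A (2 nodes), B (2 nodes), C (4 nodes); 2 A-B edges, 1 B-C edge
  g <- igraph::make_graph(~ a1 - b1, a2 - b2, a1 - a2, b1 - b2, b1 - c1,
                          c1 - c2, c2 - c3, c3 - c4)
  igraph::E(g)$weight <- 1
  labels <- setNames(c(0L, 0L, 1L, 1L, 2L, 2L, 2L, 2L),
                     c("a1", "a2", "b1", "b2", "c1", "c2", "c3", "c4"))
  cl <- nbrclust:::new_nbr_clustering(labels, "reassigned")
  merged <- merge_to_k(g, cl, 2)
  expect_equal(merged$k, 2)
  expect_equal(merged$labels[["a1"]], merged$labels[["b1"]])  # A+B merged
  expect_false(merged$labels[["a1"]] == merged$labels[["c1"]])
  # terminal case: down to one cluster
  expect_equal(length(unique(merge_to_k(g, cl, 1)$labels)), 1)
  # no-op at current k
  expect_identical(merge_to_k(g, cl, 3)$labels, cl$labels)
})

test_that("splitting divides the least resilient cluster at its attack set", {
  # two 5-cliques joined through one bridge node, all one cluster
  g <- toy_graph("complete", 5)
  h <- toy_graph("complete", 5)
  igraph::V(h)$name <- as.character(5:9)
  gh <- igraph::disjoint_union(g, h)
  gh <- igraph::add_vertices(gh, 1, name = "bridge")
  gh <- igraph::add_edges(gh, c("0", "bridge", "bridge", "5"))
  igraph::E(gh)$weight <- 1
  labels <- setNames(rep(0L, 11), igraph::V(gh)$name)
  cl <- nbrclust:::new_nbr_clustering(labels, "reassigned")
  out <- split_to_k(gh, cl, 2, "integrity")
  expect_equal(out$k, 2)
  truth <- tibble::tibble(sample_id = igraph::V(gh)$name,
                          planted_cluster = c(rep(0L, 5), rep(1L, 5), NA))
  expect_equal(fixture_ari(out, truth), 1)
  # no-op at current k
  expect_equal(split_to_k(gh, cl, 1, "integrity")$k, 1)
})

test_that("indivisible clusters dissolve so every split increases k", {
  tri <- toy_graph("complete", 3)
  cl <- nbrclust:::new_nbr_clustering(
    setNames(rep(0L, 3), igraph::V(tri)$name), "reassigned")
  out <- split_to_k(tri, cl, 2, "integrity")
  expect_gte(out$k, 2)
})

test_that("split errors when no splittable cluster remains", {
  p4 <- toy_graph("path", 4)
  labels <- setNames(c(0L, 0L, 1L, 1L), igraph::V(p4)$name)
  cl <- nbrclust:::new_nbr_clustering(labels, "reassigned")
  expect_error(split_to_k(p4, cl, 4, "integrity"), "achievable k = 2")
})

test_that("end-to-end clustering recovers planted blobs deterministically", {
  sim <- gaussian_mixture_table(n = 60, d = 2, k_true = 2, separation = 8,
                                seed = 4)
  g <- knn_graph(sim$data, min_connectivity(sim$data))
  cl <- nbr_clust(g, "integrity", 2, "reassigned")
  expect_equal(cl$k, 2)
  # base components recover the blobs exactly; folding the attack set back
  # in can cost a node or two (bridge nodes tie between balanced blobs)
  cl_base <- nbr_clust(g, "integrity", 2, "no_reassignment")
  expect_equal(fixture_ari(cl_base, sim$labels), 1)
  expect_gte(fixture_ari(cl, sim$labels), 0.9)
  # no-reassignment labels agree with the reassigned run on V - S
  cl_nr <- cl_base
  common <- names(cl_nr$labels)
  tab <- table(cl$labels[common], cl_nr$labels[common])
  expect_equal(sum(apply(tab, 1, max)), length(common))  # same partition
  # exact k contract on a 3-blob fixture
  sim3 <- gaussian_mixture_table(n = 90, d = 2, k_true = 3, separation = 8,
                                 seed = 5)
  g3 <- knn_graph(sim3$data, min_connectivity(sim3$data))
  expect_equal(nbr_clust(g3, "vat", 3)$k, 3)
  # determinism: identical inputs give identical labelings
  cl_b <- nbr_clust(g, "integrity", 2, "reassigned")
  expect_identical(cl$labels, cl_b$labels)
})

test_that("tidy and glance expose labels and provenance", {
  sim <- gaussian_mixture_table(n = 40, d = 2, k_true = 2, separation = 8,
                                seed = 6)
  g <- knn_graph(sim$data, min_connectivity(sim$data))
  cl <- nbr_clust(g, "tenacity", 2, "no_reassignment")
  td <- tidy(cl)
  expect_named(td, c("node", "cluster", "was_attack_node"))
  expect_equal(nrow(td), 40)
  expect_equal(sum(is.na(td$cluster)), length(cl$unassigned))
  gl <- glance(cl)
  expect_equal(gl$measure, "tenacity")
  expect_equal(gl$k, 2)
})
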