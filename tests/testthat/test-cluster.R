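# kNN graph construction, Louvain clustering, sub-clustering, and
# within-cluster distance matrices.

test_that("kNN graph of collinear points at k = 1 is a path", {
  Y <- matrix(c(0, 1, 2.1, 0, 0, 0), ncol = 2,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- build_knn_graph(Y, 1)
  expect_equal(igraph::ecount(g), 2)
  el <- apply(igraph::as_edgelist(g), 1, function(e)
    paste(sort(e), collapse = "-"))
  expect_setequal(el, c("a-b", "b-c"))
})

test_that("k >= n-1 gives a complete, symmetric graph", {
  set.seed(2)
  Y <- matrix(rnorm(10), 5, 2, dimnames = list(letters[1:5], NULL))
  g <- build_knn_graph(Y, 4)
  expect_equal(igraph::ecount(g), choose(5, 2))
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  expect_equal(A, t(A))
})

test_that("Louvain separates disconnected cliques and keeps one clique whole", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- sprintf("s%02d", 1:10)
  cl <- louvain_cluster(g, resolution = 1, seed = 1)
  expect_equal(length(unique(cl$main_cluster)), 2L)
  expect_equal(length(unique(cl$main_cluster[1:5])), 1L)
  expect_equal(length(unique(cl$main_cluster[6:10])), 1L)

  g1 <- igraph::make_full_graph(6)
  igraph::V(g1)$name <- letters[1:6]
  cl1 <- louvain_cluster(g1, resolution = 1, seed = 1)
  expect_equal(unique(cl1$main_cluster), 1L)
  expect_error(louvain_cluster(igraph::make_empty_graph(0, directed = FALSE)),
               "empty graph")
})

test_that("bridged cliques: Louvain attains the brute-force modularity optimum", {
  # two 4-cliques joined by a single bridge edge
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::add_edges(g, c(1, 5))
  igraph::V(g)$name <- sprintf("s%d", 1:8)
  cl <- louvain_cluster(g, resolution = 1, seed = 3)
  got_mod <- hand_modularity(g, cl$main_cluster, resolution = 1)
  # brute force over all 4140 partitions of 8 nodes
  best <- max(vapply(all_partitions(8), function(p)
    hand_modularity(g, p, resolution = 1), numeric(1)))
  expect_gte(got_mod + 1e-12, best)
  # the 2-cluster cut beats the trivial 1-cluster partition
  two <- hand_modularity(g, rep(1:2, each = 4), resolution = 1)
  one <- hand_modularity(g, rep(1, 8), resolution = 1)
  expect_gt(two, one)
  expect_equal(attr(cl, "modularity"), got_mod, tolerance = 1e-12)
})

test_that("cluster labels are dense and ordered by decreasing size", {
  g <- igraph::disjoint_union(igraph::make_full_graph(3),
                              igraph::make_full_graph(7),
                              igraph::make_full_graph(5))
  igraph::V(g)$name <- sprintf("s%02d", 1:15)
  cl <- louvain_cluster(g, resolution = 1, seed = 1)
  sizes <- as.integer(table(cl$main_cluster))
  expect_equal(sort(unique(cl$main_cluster)), 1:3)
  expect_equal(sizes, c(7L, 5L, 3L))
})

test_that("sub-clustering separates complexes merged at the main level", {
  cfg <- synth_config(n_genes = 500, n_complexes = 2,
                      complex_size_range = c(14, 15),
                      n_background_strains = 0, n_paralog_pairs = 0,
                      seed = 8)
  sim <- generate_deleteome(cfg)
  X <- sim$matrix
  forced <- data.frame(strain = rownames(X), main_cluster = 1L)
  out <- subcluster(X, forced, cluster_params(seed = 8),
                    reduce_params(seed = 8))
  expect_equal(nrow(out), nrow(X))          # partition conserved
  truth <- rep(NA_integer_, nrow(X))
  for (i in seq_along(sim$truth$complexes))
    truth[rownames(X) %in% sim$truth$complexes[[i]]] <- i
  ari <- mclust::adjustedRandIndex(out$sub_cluster, truth)
  expect_gte(ari, 0.8)
})

test_that("sub-clustering leaves small clusters untouched", {
  set.seed(4)
  X <- named_matrix(rnorm(10 * 30), 10)
  asg <- data.frame(strain = rownames(X), main_cluster = rep(1:2, each = 5))
  out <- subcluster(X, asg, cluster_params(subcluster_min_size = 25))
  expect_equal(out$sub_cluster, as.character(asg$main_cluster))
})

test_that("within-cluster distances are symmetric with a tight-pair leaf order", {
  # two tight pairs far apart: average linkage must keep pairs adjacent
  Y <- matrix(c(0, 0.1, 10, 10.1, 0, 0, 0, 0), ncol = 2,
              dimnames = list(c("a", "b", "c", "d"), NULL))
  asg <- data.frame(strain = rownames(Y), main_cluster = 1L)
  res <- within_cluster_distances(Y, asg, 1L)
  expect_equal(res$dist, t(res$dist))
  expect_equal(unname(diag(res$dist)), rep(0, 4))
  lo <- res$leaf_order
  expect_equal(abs(diff(match(c("a", "b"), lo))), 1)
  expect_equal(abs(diff(match(c("c", "d"), lo))), 1)
  expect_error(within_cluster_distances(Y, asg, 99L), "fewer than 2")
})
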