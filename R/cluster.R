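# Community detection on embedded strains: kNN graph construction, Louvain
# clustering, size-triggered sub-clustering, and within-cluster distance
# matrices for heatmap/dendrogram rendering.

#' Clustering parameter set
#'
#' @param k_neighbors kNN graph neighbourhood size (default 3).
#' @param resolution Louvain modularity resolution (default 1e-4; low
#'   resolution keeps only well-separated groups apart — the knob trades
#'   granularity, and since Louvain never merges disconnected components
#'   the sparse k = 3 graph still yields many clusters).
#' @param subcluster_min_size main clusters strictly larger than this are
#'   re-embedded and re-clustered (default 25).
#' @param seed seed for the Louvain node-order shuffle and sub-embeddings.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(k_neighbors = 3L, resolution = 1e-4,
                           subcluster_min_size = 25L, seed = 1L) {
  if (k_neighbors < 1L) stop("k_neighbors must be >= 1")
  if (resolution <= 0) stop("resolution must be > 0")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 resolution = resolution,
                 subcluster_min_size = as.integer(subcluster_min_size),
                 seed = as.integer(seed)),
            class = "cluster_params")
}

#' Build the k-nearest-neighbour graph of embedded strains
#'
#' Edge (i, j) exists iff j is among i's k nearest Euclidean neighbours or
#' vice versa (symmetrized union — denser than the mutual rule and free of
#' singletons at small k). Edges are unweighted. Distance ties are broken
#' by strain-id order so the graph is deterministic even with duplicated
#' coordinates.
#'
#' @param embedding a `pm_embedding` (or coordinate matrix with rownames).
#' @param k neighbourhood size; needs at least `k + 1` strains.
#' @return an undirected [igraph::graph] with strain ids as vertex names.
#' @export
build_knn_graph <- function(embedding, k = 3L) {
  Y <- .coords(embedding)
  n <- nrow(Y)
  if (n < k + 1L) stop("need at least k + 1 strains for a kNN graph")
  D <- as.matrix(stats::dist(Y))
  ids <- rownames(Y)
  tie_rank <- rank(ids, ties.method = "first")
  edges <- vector("list", n)
  for (i in seq_len(n)) {
    d <- D[i, ]
    d[i] <- Inf
    nn <- order(d, tie_rank)[seq_len(k)]
    edges[[i]] <- cbind(i, nn)
  }
  em <- do.call(rbind, edges)
  g <- igraph::graph_from_edgelist(em, directed = FALSE)
  g <- igraph::simplify(g)   # union symmetrization, no multi-edges
  igraph::V(g)$name <- ids
  g
}

#' Louvain clustering of a strain graph
#'
#' Runs modularity-based Louvain community detection at the given
#' resolution. Vertex order is shuffled under the seed before clustering
#' (Louvain is order-dependent), then labels are mapped back and renumbered
#' 1, 2, ... by decreasing cluster size (ties by smallest member id).
#'
#' @param graph undirected igraph with strain-id vertex names.
#' @param resolution modularity resolution parameter.
#' @param seed node-order shuffle seed.
#' @return data.frame `strain`, `main_cluster` (integer, dense from 1) in
#'   graph vertex order; attribute `modularity` holds the achieved
#'   resolution-scaled modularity.
#' @export
louvain_cluster <- function(graph, resolution = 1e-4, seed = 1L) {
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  set.seed(seed)
  perm <- sample.int(n)
  g2 <- igraph::permute(graph, perm)
  cl <- igraph::cluster_louvain(g2, resolution = resolution)
  memb <- igraph::membership(cl)[perm]   # back to original vertex order
  ids <- igraph::V(graph)$name
  relabel <- .relabel_by_size(memb, ids)
  out <- data.frame(strain = ids, main_cluster = relabel,
                    stringsAsFactors = FALSE)
  attr(out, "modularity") <- igraph::modularity(g2, igraph::membership(cl),
                                                resolution = resolution)
  out
}

# Renumber cluster labels 1..K by decreasing size; ties by smallest member.
.relabel_by_size <- function(memb, ids) {
  memb <- as.integer(memb)
  sizes <- table(memb)
  firsts <- tapply(ids, memb, min)
  o <- order(-as.integer(sizes), firsts[names(sizes)])
  map <- integer(max(memb))
  map[as.integer(names(sizes))[o]] <- seq_along(o)
  map[memb]
}

#' Sub-cluster large main clusters
#'
#' Every main cluster with more than `subcluster_min_size` strains is
#' re-processed on its own: the expression matrix is restricted to the
#' cluster, PCA is recomputed (`n_pcs_sub` components, capped at size - 1),
#' UMAP re-embedded, and the kNN + Louvain step repeated at the same
#' resolution. Strains in small clusters keep their main label as the sub
#' label. Sub labels are `"<main>.<sub>"` strings; small clusters get
#' `"<main>"`.
#'
#' @param X strains x genes expression matrix.
#' @param assignment data.frame with `strain`, `main_cluster`.
#' @param cparams a [cluster_params()].
#' @param rparams a [reduce_params()] (uses `n_pcs_sub`).
#' @return the assignment data.frame with a `sub_cluster` character column.
#' @export
subcluster <- function(X, assignment, cparams = cluster_params(),
                       rparams = reduce_params()) {
  validate_expression_matrix(X)
  out <- assignment
  out$sub_cluster <- as.character(out$main_cluster)
  for (mc in sort(unique(assignment$main_cluster))) {
    members <- assignment$strain[assignment$main_cluster == mc]
    if (length(members) <= cparams$subcluster_min_size) next
    Xs <- X[members, , drop = FALSE]
    n <- nrow(Xs)
    child_seed <- .child_seed(cparams$seed, 50L + mc)
    npc <- min(rparams$n_pcs_sub, n - 1L, ncol(Xs))
    sp <- rparams
    sp$n_neighbors <- min(rparams$n_neighbors, n - 1L)
    sp$seed <- child_seed
    scores <- pca_scores(Xs, npc, center = rparams$center,
                         scale = rparams$scale)
    emb <- embed_umap(scores, sp)
    g <- build_knn_graph(emb, min(cparams$k_neighbors, n - 1L))
    sub <- louvain_cluster(g, cparams$resolution, seed = child_seed)
    lab <- paste0(mc, ".", sub$main_cluster)
    out$sub_cluster[match(sub$strain, out$strain)] <- lab
  }
  out
}

#' Within-cluster distance matrix and dendrogram leaf order
#'
#' Pairwise Euclidean embedded distances among one cluster's members, plus
#' average-linkage hierarchical clustering of that distance matrix — the
#' ingredients of a fine-scale within-cluster heatmap.
#'
#' @param embedding a `pm_embedding`.
#' @param assignment data.frame with `strain` and cluster labels.
#' @param cluster_id cluster to extract.
#' @param level `"main_cluster"` or `"sub_cluster"` column to match
#'   `cluster_id` against.
#' @return list with `dist` (symmetric matrix, zero diagonal), `hclust`
#'   (the average-linkage tree) and `leaf_order` (strain ids in dendrogram
#'   order).
#' @export
within_cluster_distances <- function(embedding, assignment, cluster_id,
                                     level = "main_cluster") {
  members <- assignment$strain[assignment[[level]] == cluster_id]
  if (length(members) < 2L)
    stop("cluster '", cluster_id, "' has fewer than 2 strains")
  Y <- .coords(embedding)[members, , drop = FALSE]
  D <- as.matrix(stats::dist(Y))
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  list(dist = D, hclust = hc, leaf_order = members[hc$order])
}
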