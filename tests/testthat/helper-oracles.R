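# Shared fixtures and independent oracles used across the suite.

# Small, fast synthetic configuration for module-level tests.
tiny_config <- function(seed = 1L, ...) {
  synth_config(n_genes = 400L, n_complexes = 8L,
               complex_size_range = c(3L, 5L),
               n_background_strains = 30L, n_paralog_pairs = 4L,
               seed = seed, ...)
}

# Mann-Whitney AUC estimator: mean over all positive-negative comparisons,
# ties counted half. Scores are in "higher is hit" orientation.
mw_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# All set partitions of 1..n as membership vectors (restricted growth
# strings); used to brute-force the modularity optimum on small graphs.
all_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, kmax) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(kmax + 1L))
      recurse(c(prefix, v), max(kmax, v))
  }
  recurse(integer(0), 0L)
  out
}

# Newman modularity with a resolution parameter, computed from scratch for
# an unweighted undirected igraph (independent of igraph::modularity).
hand_modularity <- function(graph, membership, resolution = 1) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  k <- rowSums(A)
  m2 <- sum(k)                       # 2m
  delta <- outer(membership, membership, "==")
  sum((A - resolution * outer(k, k) / m2) * delta) / m2
}

# Expression fixture with named dimensions.
named_matrix <- function(vals, nr, strains = sprintf("s%02d", seq_len(nr))) {
  m <- matrix(vals, nrow = nr)
  dimnames(m) <- list(strains, sprintf("g%02d", seq_len(ncol(m))))
  m
}
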