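# Low-dimensional representations of the strain x gene matrix: PCA scores,
# UMAP and t-SNE on those scores, a random orthonormal projection baseline,
# and an identity "high-dimensional" view so that downstream pair scoring
# treats every space uniformly.

#' Embedding constructor
#'
#' Light container for per-strain coordinates under a named reduction
#' method. Strain order always matches the input matrix.
#'
#' @param coords numeric matrix (strains x dims) with strain rownames.
#' @param method one of `"umap"`, `"tsne"`, `"pca"`, `"random_projection"`,
#'   `"highdim"`.
#' @return object of class `pm_embedding`: list with `strain_ids`, `coords`,
#'   `method`.
#' @export
new_embedding <- function(coords, method) {
  coords <- as.matrix(coords)
  if (is.null(rownames(coords))) stop("coords need strain rownames")
  if (any(!is.finite(coords))) stop("non-finite embedding coordinate")
  structure(list(strain_ids = rownames(coords), coords = coords,
                 method = method),
            class = "pm_embedding")
}

#' @export
print.pm_embedding <- function(x, ...) {
  cat("pm_embedding [", x$method, "]: ", nrow(x$coords), " strains x ",
      ncol(x$coords), " dims\n", sep = "")
  invisible(x)
}

#' Embedding parameter set
#'
#' Defaults follow the pipeline's reference configuration: 100 principal
#' components feed UMAP (cosine metric, `n_neighbors = 10`,
#' `min_dist = 0.05`, 2 output dimensions); sub-clustering re-embeds with
#' 25 components; t-SNE uses perplexity 30.
#'
#' @param n_pcs_main,n_pcs_sub principal components for the main and
#'   sub-cluster embeddings.
#' @param umap_metric distance metric for the UMAP graph.
#' @param n_neighbors UMAP neighbourhood size.
#' @param min_dist UMAP minimum embedded distance.
#' @param out_dims output dimensionality.
#' @param perplexity t-SNE perplexity.
#' @param center,scale gene-wise centering/scaling before PCA. The input is
#'   assumed to be on a common log-ratio scale, so only centering is on by
#'   default.
#' @param seed seed for the stochastic optimizers.
#' @return list of class `reduce_params`.
#' @export
reduce_params <- function(n_pcs_main = 100L, n_pcs_sub = 25L,
                          umap_metric = "cosine", n_neighbors = 10L,
                          min_dist = 0.05, out_dims = 2L, perplexity = 30,
                          center = TRUE, scale = FALSE, seed = 1L) {
  if (out_dims < 1L) stop("out_dims must be >= 1")
  if (n_neighbors < 2L) stop("n_neighbors must be >= 2")
  structure(list(n_pcs_main = as.integer(n_pcs_main),
                 n_pcs_sub = as.integer(n_pcs_sub),
                 umap_metric = umap_metric,
                 n_neighbors = as.integer(n_neighbors),
                 min_dist = min_dist, out_dims = as.integer(out_dims),
                 perplexity = perplexity, center = isTRUE(center),
                 scale = isTRUE(scale), seed = as.integer(seed)),
            class = "reduce_params")
}

#' Principal-component scores of the gene-centered matrix
#'
#' Computes PC scores via the eigendecomposition of the smaller Gram matrix
#' (strains x strains when strains < genes), so the full compendium is
#' handled without forming a genes x genes covariance. Components are
#' ordered by decreasing explained variance. The sign of each component is
#' fixed so that its largest-magnitude gene loading is positive, making
#' results deterministic.
#'
#' @param X strains x genes numeric matrix.
#' @param n_components number of components, at most `min(strains - 1,
#'   genes)`.
#' @param center,scale gene-wise centering/scaling (default: center only).
#' @return `pm_embedding` with method `"pca"`; attribute `var_explained`
#'   holds per-component variances (summing, over a full decomposition, to
#'   the total gene-wise variance).
#' @export
pca_scores <- function(X, n_components, center = TRUE, scale = FALSE) {
  validate_expression_matrix(X)
  n <- nrow(X); p <- ncol(X)
  kmax <- min(n - 1L, p)
  if (n_components > kmax)
    stop("rank-deficient request: n_components must be <= min(strains-1, genes) = ",
         kmax)
  Xc <- scale(X, center = center, scale = scale)
  if (scale) Xc[, attr(Xc, "scaled:scale") == 0] <- 0
  Xc <- Xc[, , drop = FALSE]   # drop scaling attributes
  attr(Xc, "scaled:center") <- NULL; attr(Xc, "scaled:scale") <- NULL
  if (n <= p) {
    eg <- eigen(tcrossprod(Xc), symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(n_components)], 0)
    U <- eg$vectors[, seq_len(n_components), drop = FALSE]
    scores <- U * rep(sqrt(lam), each = n)
  } else {
    eg <- eigen(crossprod(Xc), symmetric = TRUE)
    lam <- pmax(eg$values[seq_len(n_components)], 0)
    V <- eg$vectors[, seq_len(n_components), drop = FALSE]
    scores <- Xc %*% V
  }
  tol <- max(lam, 1) * 1e-12
  for (j in seq_len(n_components)) {
    if (lam[j] <= tol) { scores[, j] <- 0; next }
    loading <- crossprod(Xc, scores[, j]) / lam[j]   # unit-norm loading
    if (loading[which.max(abs(loading))] < 0) scores[, j] <- -scores[, j]
  }
  dimnames(scores) <- list(rownames(X), paste0("PC", seq_len(n_components)))
  emb <- new_embedding(scores, "pca")
  attr(emb, "var_explained") <- lam / (n - 1)
  emb
}

# Coordinates from an embedding or a bare matrix.
.coords <- function(x) {
  if (inherits(x, "pm_embedding")) x$coords else as.matrix(x)
}

#' UMAP embedding of PCA scores
#'
#' Wraps the uwot implementation with the pipeline's reference parameters
#' (cosine metric, 10 neighbours, `min_dist` 0.05). Runs single-threaded
#' with a fixed seed so that identical input and seed give identical
#' coordinates on the same platform and library version.
#'
#' @param scores a `pm_embedding` of PCA scores (or any numeric matrix with
#'   strain rownames).
#' @param params a [reduce_params()].
#' @return `pm_embedding` with method `"umap"`.
#' @export
embed_umap <- function(scores, params = reduce_params()) {
  S <- .coords(scores)
  if (nrow(S) < params$n_neighbors + 1L)
    stop("need at least n_neighbors + 1 = ", params$n_neighbors + 1L,
         " strains, got ", nrow(S))
  set.seed(params$seed)
  Y <- uwot::umap(S, n_neighbors = params$n_neighbors,
                  n_components = params$out_dims,
                  metric = params$umap_metric, min_dist = params$min_dist,
                  n_threads = 1, n_sgd_threads = 0)
  rownames(Y) <- rownames(S)
  new_embedding(Y, "umap")
}

#' t-SNE embedding of PCA scores
#'
#' Perplexity defaults to 30 and is validated against the strain count
#' (`Rtsne` requires `3 * perplexity < n - 1`).
#'
#' @inheritParams embed_umap
#' @return `pm_embedding` with method `"tsne"`.
#' @export
embed_tsne <- function(scores, params = reduce_params()) {
  S <- .coords(scores)
  if (nrow(S) < params$n_neighbors + 1L)
    stop("need at least n_neighbors + 1 strains, got ", nrow(S))
  if (nrow(S) - 1L < 3 * params$perplexity)
    stop("perplexity ", params$perplexity, " too large for ", nrow(S),
         " strains")
  set.seed(params$seed)
  Y <- Rtsne::Rtsne(S, dims = params$out_dims,
                    perplexity = params$perplexity, pca = FALSE,
                    check_duplicates = FALSE, num_threads = 1)$Y
  rownames(Y) <- rownames(S)
  new_embedding(Y, "tsne")
}

#' Random orthonormal projection baseline
#'
#' Johnson-Lindenstrauss-style baseline: a seeded Gaussian random matrix is
#' orthonormalized by QR and the data are projected onto it. Linear, so
#' differences project to differences.
#'
#' @param X strains x genes matrix.
#' @param out_dims projection dimensionality.
#' @param seed seed for the random matrix.
#' @return `pm_embedding` with method `"random_projection"`; the projection
#'   matrix is kept in attribute `rotation`.
#' @export
embed_random_projection <- function(X, out_dims = 2L, seed = 1L) {
  if (out_dims < 1L) stop("out_dims must be >= 1")
  X <- as.matrix(X)
  set.seed(seed)
  R <- matrix(stats::rnorm(ncol(X) * out_dims), ncol(X), out_dims)
  Q <- qr.Q(qr(R))
  Y <- X %*% Q
  rownames(Y) <- rownames(X)
  emb <- new_embedding(Y, "random_projection")
  attr(emb, "rotation") <- Q
  emb
}

#' Identity (high-dimensional) view
#'
#' Wraps the raw gene-space matrix as an embedding so pair scoring can use
#' gene-space Euclidean distance through the same interface.
#'
#' @param X strains x genes matrix.
#' @return `pm_embedding` with method `"highdim"` and `coords` equal to `X`.
#' @export
highdim_view <- function(X) {
  new_embedding(as.matrix(X), "highdim")
}
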