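# Per-pair interaction scores: Euclidean distance in an embedding and
# Pearson correlation of deletion profiles, assembled into the labelled
# pair table all benchmarking consumes.

#' Euclidean embedded distance for gene pairs
#'
#' Pairs with either gene absent from the embedding are dropped — never
#' silently: they are returned in the `dropped` element with a count.
#'
#' @param embedding a `pm_embedding`.
#' @param pairs data.frame with columns `gene_a`, `gene_b`.
#' @return list: `pairs` (retained rows with a `dist` column), `dropped`
#'   (dropped rows), `n_dropped`.
#' @export
pair_embedding_distance <- function(embedding, pairs) {
  Y <- .coords(embedding)
  ok <- pairs$gene_a %in% rownames(Y) & pairs$gene_b %in% rownames(Y)
  kept <- pairs[ok, , drop = FALSE]
  us <- unique(c(kept$gene_a, kept$gene_b))
  ia <- match(kept$gene_a, us); ib <- match(kept$gene_b, us)
  Ys <- Y[us, , drop = FALSE]
  if (ncol(Ys) <= 16L || nrow(kept) < length(us)) {
    delta <- Ys[ia, , drop = FALSE] - Ys[ib, , drop = FALSE]
    kept$dist <- sqrt(rowSums(delta^2))
  } else {
    # many pairs in a high-dimensional space: go through the Gram matrix of
    # the unique strains instead of materializing a pairs x genes block
    G <- tcrossprod(Ys)
    sq <- diag(G)
    kept$dist <- sqrt(pmax(sq[ia] + sq[ib] - 2 * G[cbind(ia, ib)], 0))
  }
  list(pairs = kept, dropped = pairs[!ok, , drop = FALSE],
       n_dropped = sum(!ok))
}

#' Pearson correlation of two strains' deletion profiles, per pair
#'
#' Correlation is computed across all measured genes. A zero-variance
#' profile makes the correlation undefined; such pairs get `NA` (recorded,
#' never coerced to 0) so correlation-based analyses can exclude them.
#'
#' @param X strains x genes expression matrix.
#' @param pairs data.frame with `gene_a`, `gene_b` (strain ids).
#' @return list: `pairs` (retained rows with a `pcc` column, `NA` when
#'   undefined), `dropped`, `n_dropped`.
#' @export
pair_profile_correlation <- function(X, pairs) {
  ok <- pairs$gene_a %in% rownames(X) & pairs$gene_b %in% rownames(X)
  kept <- pairs[ok, , drop = FALSE]
  us <- unique(c(kept$gene_a, kept$gene_b))
  ia <- match(kept$gene_a, us); ib <- match(kept$gene_b, us)
  # row-standardize the unique strains once; all pairwise correlations are
  # then one crossproduct of a strains x genes block, never pairs x genes
  Xs <- X[us, , drop = FALSE]
  Xc <- Xs - rowMeans(Xs)
  ss <- sqrt(rowSums(Xc^2))
  zero_var <- ss == 0
  ss[zero_var] <- 1
  C <- tcrossprod(Xc / ss)
  pcc <- C[cbind(ia, ib)]
  pcc[zero_var[ia] | zero_var[ib]] <- NA_real_
  kept$pcc <- pmin(1, pmax(-1, pcc))
  list(pairs = kept, dropped = pairs[!ok, , drop = FALSE],
       n_dropped = sum(!ok))
}

#' Assemble the labelled pair table with all metric columns
#'
#' Joins the interaction labels with one embedded-distance column per
#' supplied embedding (named `<method>_dist`, e.g. `umap_dist`) and with
#' profile correlation (`pcc`). Pairs referencing strains absent from the
#' common universe are dropped and counted. Optionally appends unlabelled
#' pairs (label `NA`) for novel-interaction calling. Output is in canonical
#' pair order, so the assembly is invariant to input row order.
#'
#' @param interactions data.frame `gene_a`, `gene_b`, `label` (logical).
#' @param embeddings named list of `pm_embedding`s; names are ignored, the
#'   embedding's own method tag names the column.
#' @param X expression matrix for `pcc`, or `NULL` to skip.
#' @param unlabeled optional data.frame `gene_a`, `gene_b` of extra pairs to
#'   score with label `NA`.
#' @return data.frame `gene_a`, `gene_b`, `label`, one `*_dist` column per
#'   embedding, `pcc`; attributes `n_dropped` and `dropped`.
#' @export
assemble_labeled_pairs <- function(interactions, embeddings, X = NULL,
                                   unlabeled = NULL) {
  if (length(embeddings) == 0L && is.null(X))
    stop("no metric supplied: need at least one embedding or X")
  tab <- interactions[, c("gene_a", "gene_b", "label")]
  if (!is.null(unlabeled) && nrow(unlabeled) > 0L) {
    extra <- data.frame(gene_a = unlabeled$gene_a, gene_b = unlabeled$gene_b,
                        label = NA, stringsAsFactors = FALSE)
    key <- function(d) paste(d$gene_a, d$gene_b, sep = "\r")
    extra <- extra[!key(extra) %in% key(tab), , drop = FALSE]
    tab <- rbind(tab, extra)
  }
  universe <- Reduce(intersect, c(lapply(embeddings, function(e) e$strain_ids),
                                  if (!is.null(X)) list(rownames(X))))
  ok <- tab$gene_a %in% universe & tab$gene_b %in% universe
  dropped <- tab[!ok, , drop = FALSE]
  tab <- tab[ok, , drop = FALSE]
  for (e in embeddings) {
    res <- pair_embedding_distance(e, tab)
    tab[[paste0(.metric_short(e$method), "_dist")]] <- res$pairs$dist
  }
  if (!is.null(X))
    tab$pcc <- pair_profile_correlation(X, tab)$pairs$pcc
  tab <- tab[order(tab$gene_a, tab$gene_b), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_dropped") <- nrow(dropped)
  attr(tab, "dropped") <- dropped
  tab
}

.metric_short <- function(method) {
  switch(method, random_projection = "randproj", method)
}

#' All unordered strain pairs, canonical order
#'
#' Candidate-pair enumeration for novel-interaction calling. Built
#' blockwise over the first gene so no genes-x-genes intermediate is
#' materialized.
#'
#' @param strains character vector of strain ids.
#' @return data.frame `gene_a`, `gene_b` of all `choose(n, 2)` pairs.
#' @export
all_strain_pairs <- function(strains) {
  s <- sort(unique(strains))
  n <- length(s)
  if (n < 2L) return(data.frame(gene_a = character(0), gene_b = character(0)))
  blocks <- lapply(seq_len(n - 1L), function(i)
    data.frame(gene_a = s[i], gene_b = s[(i + 1L):n],
               stringsAsFactors = FALSE))
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
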