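# Per-cluster differential expression under an equal-variance Gaussian
# model, with genomic-control (lambda GC) correction of the chi-square(1)
# statistics, BH multiple-testing adjustment, and a generic hypergeometric
# over-representation test for user-supplied gene-set annotations.

# chi-square(1) median, the genomic-control null reference (~0.4549364).
.CHI1_MEDIAN <- stats::qchisq(0.5, df = 1)

#' Genomic inflation factor of chi-square(1) statistics
#'
#' \eqn{\lambda_{GC}} = median(observed \eqn{\chi^2}) / median of the
#' \eqn{\chi^2_1} null (\eqn{\approx 0.4549}). Values near 1 indicate a
#' well-calibrated null; values above 1 indicate systematic inflation.
#'
#' @param stats numeric vector of chi-square(1)-scale statistics.
#' @return lambda (positive scalar).
#' @export
lambda_gc <- function(stats) {
  if (length(stats) < 1L) stop("need at least one statistic")
  stats::median(stats, na.rm = TRUE) / .CHI1_MEDIAN
}

#' Genomic-control correction of chi-square statistics
#'
#' Standard convention: statistics are deflated by \eqn{\lambda} only when
#' \eqn{\lambda > 1}; a deflated null (\eqn{\lambda \le 1}) is left
#' untouched. P-values are recomputed from the \eqn{\chi^2_1} tail.
#'
#' @param stats chi-square(1)-scale statistics.
#' @param lambda inflation factor, typically from [lambda_gc()].
#' @return list with `stats` (corrected) and `p` (corrected p-values).
#' @export
gc_correct <- function(stats, lambda = lambda_gc(stats)) {
  corr <- if (lambda > 1) stats / lambda else stats
  list(stats = corr, p = stats::pchisq(corr, df = 1, lower.tail = FALSE),
       lambda = lambda)
}

#' Benjamini-Hochberg q-values
#'
#' Thin wrapper around `stats::p.adjust(method = "BH")`, exposed so every
#' module adjusts identically.
#'
#' @param p p-values in `[0, 1]`.
#' @return q-values, monotone nondecreasing in `p`.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

#' Per-cluster differential expression against the background of deletions
#'
#' For each measured gene, the strains of one cluster are compared with all
#' remaining strains under an equal-variance Gaussian model — the
#' likelihood-ratio contrast of a cluster-membership indicator against an
#' intercept-only model, which reduces to the pooled two-sample F test.
#' The exact F p-value is mapped monotonically onto the \eqn{\chi^2_1}
#' scale (stat = upper \eqn{\chi^2_1} quantile of the p-value), so the
#' statistic is exactly \eqn{\chi^2_1}-distributed under the null and the
#' genomic-control correction applies on its natural scale. \eqn{\lambda}
#' is computed per cluster; BH q-values are computed from the corrected
#' p-values.
#'
#' A gene with zero variance overall carries no evidence: statistic 0,
#' p = 1 by convention.
#'
#' @param X strains x genes expression matrix.
#' @param assignment data.frame with `strain` and cluster labels.
#' @param cluster_id cluster whose members form the foreground group.
#' @param level cluster column (`"main_cluster"` or `"sub_cluster"`).
#' @return data.frame per gene: `gene`, `stat` (chi-square(1) scale), `p`,
#'   `lambda`, `stat_corr`, `p_corr`, `q`, `effect` (mean cluster minus
#'   mean background); attribute `lambda`.
#' @export
cluster_de <- function(X, assignment, cluster_id, level = "main_cluster") {
  validate_expression_matrix(X)
  members <- assignment$strain[assignment[[level]] == cluster_id]
  members <- intersect(members, rownames(X))
  if (length(members) < 2L) stop("cluster needs >= 2 strains")
  in_cl <- rownames(X) %in% members
  if (all(in_cl)) stop("background is empty")
  n1 <- sum(in_cl); n2 <- sum(!in_cl); n <- n1 + n2
  m1 <- colMeans(X[in_cl, , drop = FALSE])
  m2 <- colMeans(X[!in_cl, , drop = FALSE])
  m0 <- colMeans(X)
  ss_tot <- colSums(X^2) - n * m0^2                 # RSS, intercept model
  ss_grp <- n1 * m1^2 + n2 * m2^2 - n * m0^2        # between-group SS
  rss1 <- pmax(ss_tot - ss_grp, 0)                  # RSS, two-group model
  f <- (ss_grp / 1) / (rss1 / (n - 2L))
  p <- stats::pf(f, 1, n - 2L, lower.tail = FALSE)
  # degenerate genes, detected on a relative scale
  msq <- colSums(X^2)
  zero_tot <- ss_tot <= msq * 1e-12
  sep <- !zero_tot & rss1 <= ss_tot * 1e-12   # perfect group separation
  p[zero_tot] <- 1
  p[sep] <- .Machine$double.xmin
  stat <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stat[zero_tot] <- 0
  lam <- lambda_gc(stat)
  corr <- gc_correct(stat, lam)
  out <- data.frame(gene = colnames(X), stat = stat, p = p, lambda = lam,
                    stat_corr = corr$stats, p_corr = corr$p,
                    q = bh_adjust(corr$p), effect = m1 - m2,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "lambda") <- lam
  out
}

#' Differential expression for every cluster
#'
#' @inheritParams cluster_de
#' @return single data.frame with a leading `cluster` column, one
#'   [cluster_de()] block per cluster with >= 2 strains.
#' @export
cluster_de_all <- function(X, assignment, level = "main_cluster") {
  ids <- sort(unique(assignment[[level]]))
  blocks <- lapply(ids, function(cid) {
    members <- assignment$strain[assignment[[level]] == cid]
    if (length(intersect(members, rownames(X))) < 2L) return(NULL)
    cbind(cluster = cid, cluster_de(X, assignment, cid, level))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' One-sided hypergeometric tail test of whether `hit_genes` overlap each
#' annotation term more than expected from the universe, with BH
#' adjustment across terms. A generic stand-in for GO-style enrichment on
#' user-supplied annotations.
#'
#' @param hit_genes character vector, must be a subset of `universe`.
#' @param annotation named list: term -> gene set.
#' @param universe all genes eligible to be hits.
#' @return data.frame per term: `term`, `n_term` (term genes in universe),
#'   `n_hits`, `overlap`, `p`, `q`.
#' @export
overrepresentation <- function(hit_genes, annotation, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe")
  hit_genes <- unique(hit_genes)
  if (!all(hit_genes %in% universe))
    stop("hit_genes must be a subset of the universe")
  N <- length(universe); k <- length(hit_genes)
  rows <- lapply(names(annotation), function(term) {
    term_genes <- intersect(annotation[[term]], universe)
    K <- length(term_genes)
    ov <- length(intersect(term_genes, hit_genes))
    p <- stats::phyper(ov - 1L, K, N - K, k, lower.tail = FALSE)
    data.frame(term = term, n_term = K, n_hits = k, overlap = ov, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
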