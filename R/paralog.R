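# Transcriptional divergence of paralog pairs: embedded distance per pair,
# correlation with external divergence metrics, and flagging of pairs that
# look redundant by genetic interaction yet transcriptionally divergent.

#' Embedded distances for paralog pairs
#'
#' Delegates to [pair_embedding_distance()]; pairs with an absent strain
#' are dropped and counted, never silently.
#'
#' @param embedding a `pm_embedding`.
#' @param paralogs paralog table (`gene_a`, `gene_b`, optional
#'   `divergence_metric`, `gi_score`).
#' @return list: `pairs` (with `umap_dist`-style `dist` column), `dropped`,
#'   `n_dropped`.
#' @export
paralog_distances <- function(embedding, paralogs) {
  pair_embedding_distance(embedding, paralogs)
}

#' Build the per-pair paralog report
#'
#' Joins embedded distance, profile correlation, and whatever external
#' columns (`divergence_metric`, `gi_score`, `theta`, ...) the table
#' carries.
#'
#' @param embedding a `pm_embedding`.
#' @param X expression matrix (for `pcc`), or `NULL` to skip.
#' @param paralogs paralog table.
#' @return data.frame: the retained paralog rows plus `dist` and `pcc`;
#'   attribute `n_dropped`.
#' @export
paralog_report <- function(embedding, X, paralogs) {
  res <- paralog_distances(embedding, paralogs)
  out <- res$pairs
  if (!is.null(X))
    out$pcc <- pair_profile_correlation(X, out)$pairs$pcc
  rownames(out) <- NULL
  attr(out, "n_dropped") <- res$n_dropped
  out
}

#' Correlation between embedded distance and an external divergence metric
#'
#' @param distances numeric vector of per-pair embedded distances.
#' @param metric numeric vector of the external metric, same pairs.
#' @return list: `r` (Pearson correlation over complete pairs), `n`
#'   (complete pairs used). Fewer than 3 complete pairs is an error.
#' @export
metric_correlation <- function(distances, metric) {
  ok <- is.finite(distances) & is.finite(metric)
  if (sum(ok) < 3L) stop("need >= 3 complete pairs, got ", sum(ok))
  list(r = stats::cor(distances[ok], metric[ok]), n = sum(ok))
}

#' Flag paralog pairs that are redundant by GI yet divergent in expression
#'
#' A pair is flagged when its genetic-interaction score is at or below
#' `gi_threshold` (a strong negative interaction, i.e. the double deletion
#' is much sicker than expected — the classical signature of retained
#' redundancy) while its embedded distance lies above the
#' `distance_quantile` of all paralog distances in the report (distinct
#' downstream transcriptional effects). Both thresholds are conventions,
#' exposed as configuration.
#'
#' @param report data.frame from [paralog_report()] with `dist` and
#'   `gi_score` columns.
#' @param gi_threshold GI score at or below which a pair counts as strongly
#'   negative (default -0.5).
#' @param distance_quantile quantile of the report's distances above which
#'   a pair counts as divergent (default 0.75).
#' @return the report with a logical `divergent_redundant` column (`NA`
#'   when `gi_score` or `dist` is missing); attribute `n_flagged`.
#' @export
flag_divergent_redundant <- function(report, gi_threshold = -0.5,
                                     distance_quantile = 0.75) {
  if (is.null(report$gi_score) || is.null(report$dist))
    stop("report needs gi_score and dist columns")
  cut <- stats::quantile(report$dist, distance_quantile, na.rm = TRUE,
                         names = FALSE)
  flag <- report$gi_score <= gi_threshold & report$dist > cut
  out <- report
  out$divergent_redundant <- flag
  attr(out, "distance_cut") <- cut
  attr(out, "n_flagged") <- sum(flag, na.rm = TRUE)
  out
}
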