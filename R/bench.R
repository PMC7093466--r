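# Benchmarking a pairwise interaction score against gold-standard labels:
# ROC and precision/recall curves (implemented from first principles so the
# tie convention is pinned and oracle-testable), FDR-calibrated distance
# cutoffs, novel-interaction calling, and cluster/complex concordance.

.hit_scores <- function(pairs, metric, direction) {
  direction <- match.arg(direction, c("lower_is_hit", "higher_is_hit"))
  s <- pairs[[metric]]
  if (is.null(s)) stop("metric column '", metric, "' not found")
  keep <- !is.na(s) & !is.na(pairs$label)
  s <- s[keep]; lab <- pairs$label[keep]
  if (sum(lab) == 0L || sum(!lab) == 0L)
    stop("need at least one positive and one negative with metric '",
         metric, "'")
  list(score = if (direction == "lower_is_hit") -s else s, label = lab)
}

#' ROC curve and AUC for a pair metric
#'
#' The curve is traced over all distinct score thresholds; tied scores move
#' the curve diagonally in one step, so the trapezoidal AUC gives ties half
#' weight — identical to the Mann-Whitney U estimator with ties counted
#' 1/2.
#'
#' @param pairs labelled-pairs data.frame (see [assemble_labeled_pairs()]).
#' @param metric score column name, e.g. `"umap_dist"` or `"pcc"`.
#' @param direction `"lower_is_hit"` for distances (default),
#'   `"higher_is_hit"` for correlations.
#' @return object of class `pm_roc`: list with `thresholds`, `fpr`, `tpr`
#'   (each starting at the (0, 0) operating point), `auc`, `metric`,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(pairs, metric, direction = "lower_is_hit") {
  hs <- .hit_scores(pairs, metric, direction)
  o <- order(hs$score, decreasing = TRUE)
  s <- hs$score[o]; lab <- hs$label[o]
  P <- sum(lab); N <- sum(!lab)
  # index of the last occurrence of each distinct score value
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(lab)[last]; fp <- cumsum(!lab)[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = s[last], fpr = fpr, tpr = tpr, auc = auc,
                 metric = metric, direction = direction,
                 n_pos = P, n_neg = N),
            class = "pm_roc")
}

#' @export
print.pm_roc <- function(x, ...) {
  cat("ROC [", x$metric, ", ", x$direction, "]: AUC = ",
      format(x$auc, digits = 4), " (", x$n_pos, " pos / ", x$n_neg,
      " neg)\n", sep = "")
  invisible(x)
}

#' Precision/recall curve for a pair metric
#'
#' Precision and recall at every distinct score threshold (ties grouped);
#' area by the step-wise integral \eqn{\sum_i (R_i - R_{i-1}) P_i}.
#'
#' @inheritParams roc_curve
#' @return list of class `pm_pr`: `thresholds`, `recall`, `precision`,
#'   `area`, `metric`, `n_pos`, `n_neg`.
#' @export
pr_curve <- function(pairs, metric, direction = "lower_is_hit") {
  hs <- .hit_scores(pairs, metric, direction)
  o <- order(hs$score, decreasing = TRUE)
  s <- hs$score[o]; lab <- hs$label[o]
  P <- sum(lab); N <- sum(!lab)
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(lab)[last]; fp <- cumsum(!lab)[last]
  recall <- tp / P
  precision <- tp / (tp + fp)
  area <- sum(diff(c(0, recall)) * precision)
  structure(list(thresholds = s[last], recall = recall,
                 precision = precision, area = area, metric = metric,
                 direction = direction, n_pos = P, n_neg = N),
            class = "pm_pr")
}

#' FDR-calibrated distance cutoff among labelled pairs
#'
#' Candidate thresholds are the observed labelled distances. For each
#' threshold `t`, FDR(t) = FP / (TP + FP) among labelled pairs called at
#' distance <= t; the largest `t` with FDR <= `alpha` is returned. Only
#' labelled pairs enter the calibration — unlabelled pairs are later scored
#' against the resulting threshold but never move it. If no threshold
#' qualifies the result says so explicitly (`no_cutoff = TRUE`,
#' `threshold = -Inf`) rather than returning a silent 0.
#'
#' @param pairs labelled-pairs data.frame.
#' @param metric distance column (default `"umap_dist"`).
#' @param alpha target FDR (default 0.05).
#' @return list of class `pm_fdr`: `alpha`, `threshold`, `achieved_fdr`,
#'   `n_called`, `no_cutoff`.
#' @export
fdr_cutoff <- function(pairs, metric = "umap_dist", alpha = 0.05) {
  d <- pairs[[metric]]
  if (is.null(d)) stop("metric column '", metric, "' not found")
  keep <- !is.na(d) & !is.na(pairs$label)
  d <- d[keep]; lab <- pairs$label[keep]
  if (length(d) == 0L) stop("no labelled pairs with metric '", metric, "'")
  o <- order(d)
  d <- d[o]; lab <- lab[o]
  last <- which(!duplicated(d, fromLast = TRUE))
  tp <- cumsum(lab)[last]; fp <- cumsum(!lab)[last]
  fdr <- fp / (tp + fp)
  ok <- which(fdr <= alpha)
  if (length(ok) == 0L) {
    res <- list(alpha = alpha, threshold = -Inf, achieved_fdr = NA_real_,
                n_called = 0L, no_cutoff = TRUE)
  } else {
    i <- max(ok)
    res <- list(alpha = alpha, threshold = d[last][i],
                achieved_fdr = fdr[i], n_called = (tp + fp)[i],
                no_cutoff = FALSE)
  }
  structure(res, class = "pm_fdr")
}

#' @export
print.pm_fdr <- function(x, ...) {
  if (x$no_cutoff) {
    cat("FDR cutoff: no threshold achieves FDR <=", x$alpha, "\n")
  } else {
    cat("FDR cutoff (alpha = ", x$alpha, "): threshold = ",
        format(x$threshold, digits = 4), ", achieved FDR = ",
        format(x$achieved_fdr, digits = 3), ", ", x$n_called,
        " labelled pairs called\n", sep = "")
  }
  invisible(x)
}

#' Call novel interactions: close in the embedding, missed by correlation
#'
#' A pair is called when its embedded distance is at or below the
#' FDR-calibrated threshold (closed bound) and its profile correlation is
#' strictly below `pcc_max` — i.e. proximity flags an interaction that the
#' classical correlation criterion would not confidently call. Pairs with
#' missing `pcc` are excluded and counted.
#'
#' @param pairs pair table including unlabelled pairs (label `NA`).
#' @param threshold distance threshold, typically `fdr_cutoff(...)$threshold`.
#' @param metric distance column (default `"umap_dist"`).
#' @param pcc_max correlation ceiling (default 0.5, exclusive).
#' @return data.frame of called pairs with a `label_status` column
#'   (`"true"`, `"false"`, `"unlabeled"`); attributes `n_called`,
#'   `n_genes` (unique genes among calls), `n_missing_pcc`.
#' @export
call_novel <- function(pairs, threshold, metric = "umap_dist",
                       pcc_max = 0.5) {
  d <- pairs[[metric]]
  if (is.null(d)) stop("metric column '", metric, "' not found")
  if (is.null(pairs$pcc)) stop("pcc column required for novel calling")
  missing_pcc <- is.na(pairs$pcc) & !is.na(d) & d <= threshold
  called <- !is.na(d) & d <= threshold & !is.na(pairs$pcc) &
    pairs$pcc < pcc_max
  out <- pairs[called, , drop = FALSE]
  out$label_status <- ifelse(is.na(out$label), "unlabeled",
                             ifelse(out$label, "true", "false"))
  rownames(out) <- NULL
  attr(out, "n_called") <- nrow(out)
  attr(out, "n_genes") <- length(unique(c(out$gene_a, out$gene_b)))
  attr(out, "n_missing_pcc") <- sum(missing_pcc)
  out
}

#' Complex co-clustering concordance
#'
#' For each catalogued complex, membership is restricted to the strain
#' universe; a complex is eligible when at least two members remain and
#' co-clustered when some cluster holds at least two of them. The member
#' fraction of the best cluster (members in that cluster / members in the
#' universe) is the standard cluster annotation fraction.
#'
#' @param catalog named list complex id -> member gene ids.
#' @param assignment data.frame with `strain` and cluster labels.
#' @param universe strain ids considered (default: all in `assignment`).
#' @param level cluster column to use (`"main_cluster"` or `"sub_cluster"`).
#' @return data.frame per complex: `complex_id`, `members_in_universe`,
#'   `best_cluster`, `n_in_best`, `fraction`, `co_clustered`; attribute
#'   `totals` = list(`n_eligible`, `n_co_clustered`, `fraction`).
#' @export
complex_concordance <- function(catalog, assignment,
                                universe = assignment$strain,
                                level = "main_cluster") {
  lab <- assignment[[level]]
  names(lab) <- assignment$strain
  rows <- lapply(names(catalog), function(cid) {
    members <- intersect(intersect(catalog[[cid]], universe),
                         assignment$strain)
    m <- length(members)
    if (m == 0L)
      return(data.frame(complex_id = cid, members_in_universe = 0L,
                        best_cluster = NA_character_, n_in_best = 0L,
                        fraction = NA_real_, co_clustered = FALSE))
    tab <- sort(table(as.character(lab[members])), decreasing = TRUE)
    data.frame(complex_id = cid, members_in_universe = m,
               best_cluster = names(tab)[1],
               n_in_best = as.integer(tab[1]),
               fraction = as.integer(tab[1]) / m,
               co_clustered = m >= 2L && tab[1] >= 2L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  eligible <- out$members_in_universe >= 2L
  attr(out, "totals") <- list(n_eligible = sum(eligible),
                              n_co_clustered = sum(out$co_clustered),
                              fraction = if (any(eligible))
                                sum(out$co_clustered) / sum(eligible)
                              else NA_real_)
  out
}

#' Overlap between two clusterings of the same strains
#'
#' For each cluster of partition A, finds the best-matching cluster of
#' partition B by containment fraction |A_i ∩ B_j| / |A_i| (the best
#' Jaccard index is reported alongside). Counts clusters with perfect
#' containment (fraction 1: the A-cluster lies wholly inside one B-cluster)
#' and with fraction >= 0.5, and summarizes overall agreement with the
#' adjusted Rand index.
#'
#' @param A,B data.frames with `strain` and cluster labels over the same
#'   strain universe.
#' @param level cluster column to compare.
#' @return data.frame per A-cluster: `cluster_a`, `size`, `best_match`,
#'   `overlap_fraction`, `best_jaccard`; attributes `n_perfect`,
#'   `n_ge_half`, `ari`.
#' @export
clustering_overlap <- function(A, B, level = "main_cluster") {
  if (!setequal(A$strain, B$strain))
    stop("A and B must cluster the same strain universe")
  b <- B[[level]][match(A$strain, B$strain)]
  a <- A[[level]]
  ct <- table(a, b)
  rows <- lapply(rownames(ct), function(ai) {
    inter <- ct[ai, ]
    size <- sum(inter)
    j <- which.max(inter)
    jac <- inter / (size + colSums(ct) - inter)
    data.frame(cluster_a = ai, size = size,
               best_match = colnames(ct)[j],
               overlap_fraction = inter[j] / size,
               best_jaccard = max(jac), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_perfect") <- sum(out$overlap_fraction == 1)
  attr(out, "n_ge_half") <- sum(out$overlap_fraction >= 0.5)
  attr(out, "ari") <- mclust::adjustedRandIndex(a, b)
  out
}
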