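# ROC/PR curves, FDR calibration, novel calling, concordance and overlap.

make_pairs <- function(pos, neg, metric = "umap_dist") {
  n <- length(pos) + length(neg)
  df <- data.frame(gene_a = sprintf("a%03d", seq_len(n)),
                   gene_b = sprintf("b%03d", seq_len(n)),
                   label = rep(c(TRUE, FALSE), c(length(pos), length(neg))))
  df[[metric]] <- c(pos, neg)
  df
}

test_that("ROC handles perfect separation, pure ties, and the 0.75 case", {
  expect_equal(roc_curve(make_pairs(c(1, 2), c(3, 4)), "umap_dist")$auc, 1.0)
  expect_equal(roc_curve(make_pairs(c(2, 2), c(2, 2)), "umap_dist")$auc, 0.5)
  # pos {1,3}, neg {2,4}, lower is hit: U = 3 of 4 comparisons -> 0.75
  expect_equal(roc_curve(make_pairs(c(1, 3), c(2, 4)), "umap_dist")$auc, 0.75)
  expect_error(roc_curve(make_pairs(c(1, 2), numeric(0)), "umap_dist"),
               "positive and one negative")
})

test_that("ROC curve geometry is consistent with its AUC and with pROC", {
  set.seed(21)
  pairs <- make_pairs(runif(40), runif(60) + 0.3)
  r <- roc_curve(pairs, "umap_dist")
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  skip_if_not_installed("pROC")
  ref <- pROC::roc(pairs$label, pairs$umap_dist, direction = ">",
                   quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("direction flips AUC to its complement on tie-free data", {
  set.seed(22)
  pairs <- make_pairs(rnorm(25), rnorm(25) + 1)
  a_lo <- roc_curve(pairs, "umap_dist", "lower_is_hit")$auc
  a_hi <- roc_curve(pairs, "umap_dist", "higher_is_hit")$auc
  expect_equal(a_lo, 1 - a_hi, tolerance = 1e-12)
})

test_that("PR curve: perfect separation, full recall, and the tiny case", {
  pr <- pr_curve(make_pairs(c(1, 2), c(3, 4)), "umap_dist")
  expect_true(all(pr$precision[pr$recall > 0] <= 1))
  expect_equal(pr$precision[which(pr$recall == 1)[1]], 1)  # before negatives
  expect_equal(pr$recall[length(pr$recall)], 1)
  # pos {1}, neg {2,3}: at threshold 1, precision 1 and recall 1
  pr2 <- pr_curve(make_pairs(1, c(2, 3)), "umap_dist")
  expect_equal(pr2$precision[1], 1)
  expect_equal(pr2$recall[1], 1)
  expect_equal(pr2$area, 1)
})

test_that("FDR cutoff reproduces the worked example and its limit cases", {
  pairs <- make_pairs(c(0.1, 0.2, 0.4), c(0.3, 0.5))
  res <- fdr_cutoff(pairs, alpha = 0.05)
  expect_equal(res$threshold, 0.2)
  expect_equal(res$achieved_fdr, 0)
  expect_equal(res$n_called, 2L)
  # perfect separation: threshold = max positive distance, FDR 0
  res2 <- fdr_cutoff(make_pairs(c(0.1, 0.2), c(0.8, 0.9)), alpha = 0.05)
  expect_equal(res2$threshold, 0.2)
  expect_equal(res2$achieved_fdr, 0)
  # alpha = 0 keeps the largest zero-false-positive threshold
  res3 <- fdr_cutoff(pairs, alpha = 0)
  expect_equal(res3$threshold, 0.2)
  # no qualifying threshold is explicit
  res4 <- fdr_cutoff(make_pairs(0.9, 0.1), alpha = 0.05)
  expect_true(res4$no_cutoff)
  expect_identical(res4$threshold, -Inf)
})

test_that("novel calls need both proximity and low correlation", {
  pairs <- data.frame(gene_a = c("a", "a", "b", "c"),
                      gene_b = c("b", "c", "d", "d"),
                      label = c(TRUE, NA, NA, NA),
                      umap_dist = c(0.1, 0.1, 0.15, 0.5),
                      pcc = c(0.9, 0.3, 0.2, 0.1))
  out <- call_novel(pairs, threshold = 0.2)
  expect_equal(paste(out$gene_a, out$gene_b), c("a c", "b d"))
  expect_equal(out$label_status, c("unlabeled", "unlabeled"))
  expect_equal(attr(out, "n_genes"), 4L)   # {a, c, b, d}
  # missing pcc is excluded and counted
  pairs$pcc[2] <- NA
  out2 <- call_novel(pairs, threshold = 0.2)
  expect_equal(nrow(out2), 1L)
  expect_equal(attr(out2, "n_missing_pcc"), 1L)
})

test_that("complex concordance counts co-clustered complexes and fractions", {
  asg <- data.frame(strain = c("g1", "g2", "g3", "g4", "g5"),
                    main_cluster = c(1L, 1L, 2L, 3L, 3L))
  cat <- list(C1 = c("g1", "g2"),           # together in cluster 1
              C2 = c("g1", "g3", "g4"),     # split across 3 clusters
              C3 = c("g5", "gX"))           # one member in universe
  cc <- complex_concordance(cat, asg)
  expect_equal(cc$co_clustered, c(TRUE, FALSE, FALSE))
  expect_equal(cc$fraction, c(1, 1 / 3, 1))
  tot <- attr(cc, "totals")
  expect_equal(tot$n_eligible, 2L)
  expect_equal(tot$n_co_clustered, 1L)
})

test_that("clustering overlap matches the enumerated example and ARI bounds", {
  A <- data.frame(strain = sprintf("s%d", 1:5),
                  main_cluster = c(1L, 1L, 1L, 2L, 2L))
  B <- data.frame(strain = sprintf("s%d", 1:5),
                  main_cluster = c(1L, 1L, 2L, 2L, 2L))
  ov <- clustering_overlap(A, B)
  expect_equal(ov$overlap_fraction, c(2 / 3, 1))
  expect_equal(attr(ov, "n_perfect"), 1L)
  expect_equal(attr(ov, "n_ge_half"), 2L)
  # identical partitions: everything perfect, ARI 1
  ov2 <- clustering_overlap(A, A)
  expect_equal(ov2$overlap_fraction, c(1, 1))
  expect_equal(attr(ov2, "ari"), 1)
  # one cluster split 50/50
  C <- data.frame(strain = sprintf("s%d", 1:4), main_cluster = 1L)
  D <- data.frame(strain = sprintf("s%d", 1:4),
                  main_cluster = c(1L, 1L, 2L, 2L))
  expect_equal(clustering_overlap(C, D)$overlap_fraction, 0.5)
  expect_error(clustering_overlap(A, C), "same strain universe")
})
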