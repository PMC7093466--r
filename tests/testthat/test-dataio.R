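# Readers, writers, validation and pair canonicalization.

test_that("expression matrix round-trips through TSV", {
  X <- named_matrix(rnorm(12), 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(X, p)
  Y <- read_expression_matrix(p)
  expect_equal(dim(Y), c(3L, 4L))
  expect_equal(Y, X, tolerance = 1e-12)
})

test_that("malformed expression input is rejected, naming the cell", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tg01\tg02\tg03", "s1\t1\t2\t3", "s2\t4\tNA\t6"), p)
  expect_error(read_expression_matrix(p), "s2.*g02")
  writeLines(c("strain\tg01\tg02\tg03", "s1\t1\tx\t3", "s2\t4\t5\t6"), p)
  expect_error(read_expression_matrix(p), "s1.*g02")
  expect_error(validate_expression_matrix(named_matrix(c(1, 2, NA, 4), 2)),
               "non-finite")
  expect_error(validate_expression_matrix(
    named_matrix(1:4, 2, strains = c("a", "a"))), "duplicate strain")
})

test_that("pair labels are canonicalized and duplicates rejected", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tlabel", "g2\tg1\ttrue", "g1\tg3\tfalse"), p)
  got <- read_pair_labels(p)
  expect_equal(got$gene_a, c("g1", "g1"))
  expect_equal(got$gene_b, c("g2", "g3"))
  expect_equal(got$label, c(TRUE, FALSE))
  # same pair in both orders is a duplicate
  writeLines(c("gene_a\tgene_b\tlabel", "g2\tg1\ttrue", "g1\tg2\ttrue"), p)
  expect_error(read_pair_labels(p), "duplicate pair")
  writeLines(c("gene_a\tgene_b\tlabel", "g1\tg1\ttrue"), p)
  expect_error(read_pair_labels(p), "self-pair")
  writeLines(c("gene_a\tgene_b\tlabel", "g1\tg2\tmaybe"), p)
  expect_error(read_pair_labels(p), "unknown label")
})

test_that("complex catalog reads and an optional paralog column stays absent", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("complex_id\tgene_id", "C1\tg1", "C1\tg2"), p)
  expect_equal(read_complex_catalog(p), list(C1 = c("g1", "g2")))
  writeLines(c("gene_a\tgene_b\tdivergence_metric",
               "g1\tg2\t0.3", "g3\tg4\t0.7"), p)
  tab <- read_paralog_table(p)
  expect_null(tab$gi_score)
  expect_equal(tab$divergence_metric, c(0.3, 0.7))
})

test_that("catalog_to_pairs enumerates positives and restricted negatives", {
  # single complex: all pairs positive
  got <- catalog_to_pairs(list(C1 = c("g1", "g2", "g3")),
                          c("g1", "g2", "g3"))
  expect_equal(sum(got$label), 3L)
  expect_equal(sum(!got$label), 0L)
  # two complexes: negatives are the cross pairs
  got <- catalog_to_pairs(list(C1 = c("g1", "g2"), C2 = c("g3", "g4")),
                          paste0("g", 1:4))
  key <- paste(got$gene_a, got$gene_b)
  expect_setequal(key[got$label], c("g1 g2", "g3 g4"))
  expect_setequal(key[!got$label],
                  c("g1 g3", "g1 g4", "g2 g3", "g2 g4"))
  # universe restriction removes g4's pairs entirely
  got <- catalog_to_pairs(list(C1 = c("g1", "g2"), C2 = c("g3", "g4")),
                          c("g1", "g2", "g3"))
  key <- paste(got$gene_a, got$gene_b)
  expect_setequal(key[got$label], "g1 g2")
  expect_setequal(key[!got$label], c("g1 g3", "g2 g3"))
  # negatives = "all" widens the pool to unannotated genes
  got <- catalog_to_pairs(list(C1 = c("g1", "g2")), c("g1", "g2", "g9"),
                          negatives = "all")
  expect_equal(sum(!got$label), 2L)
  expect_warning(catalog_to_pairs(list(C1 = c("gX")), c("g1", "g2")),
                 "no catalog gene")
})

test_that("embedding and cluster assignment round-trip", {
  emb <- new_embedding(named_matrix(rnorm(8), 4)[, 1:2], "umap")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_embedding(emb, p)
  back <- read_embedding(p)
  expect_equal(back$method, "umap")
  expect_equal(unname(back$coords), unname(emb$coords), tolerance = 1e-12)
  expect_equal(back$strain_ids, emb$strain_ids)

  asg <- data.frame(strain = c("s1", "s2"), main_cluster = c(1L, 2L),
                    sub_cluster = c("1.1", "2"))
  write_cluster_assignment(asg, p)
  expect_equal(read_cluster_assignment(p), asg)
})

test_that("scored pairs round-trip with unlabeled rows", {
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"),
                      label = c(TRUE, NA), umap_dist = c(0.5, 1.25),
                      pcc = c(0.9, -0.1))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_scored_pairs(pairs, p)
  back <- read_scored_pairs(p)
  expect_equal(back$label, c(TRUE, NA))
  expect_equal(back$umap_dist, pairs$umap_dist)
})
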