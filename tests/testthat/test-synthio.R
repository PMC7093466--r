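# The synthetic deletion-compendium generator: determinism, degenerate
# noiseless behaviour, planted-structure signal, and config validation.

test_that("identical config and seed give bit-identical output", {
  cfg <- tiny_config(seed = 42)
  a <- generate_deleteome(cfg)
  b <- generate_deleteome(cfg)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$truth, b$truth)
  c <- generate_deleteome(tiny_config(seed = 43))
  expect_false(identical(a$matrix, c$matrix))
})

test_that("noiseless degenerate case: same-complex strains have identical rows", {
  cfg <- tiny_config(noise_sd = 0, member_strength_sd = 0)
  sim <- generate_deleteome(cfg)
  for (members in sim$truth$complexes) {
    ref <- sim$matrix[members[1], ]
    for (m in members[-1])
      expect_equal(unname(sim$matrix[m, ]), unname(ref))
  }
  # within-complex gene-space distance 0 and PCC 1
  pp <- sim$truth$positive_pairs
  d <- pair_embedding_distance(highdim_view(sim$matrix), pp)$pairs$dist
  expect_equal(d, rep(0, nrow(pp)))
  pcc <- pair_profile_correlation(sim$matrix, pp)$pairs$pcc
  expect_equal(pcc, rep(1, nrow(pp)), tolerance = 1e-12)
})

test_that("within-complex correlation exceeds between-complex correlation", {
  sim <- generate_deleteome(synth_config(seed = 1))
  X <- sim$matrix
  pos <- sim$truth$positive_pairs
  within <- mean(pair_profile_correlation(X, pos)$pairs$pcc)
  members <- unlist(sim$truth$complexes, use.names = FALSE)
  all_p <- catalog_to_pairs(sim$truth$complexes, rownames(X))
  neg <- all_p[!all_p$label, ][seq_len(2000), ]
  between <- mean(pair_profile_correlation(X, neg)$pairs$pcc)
  expect_gt(within, between)
})

test_that("increasing noise does not increase mean within-complex correlation", {
  sigmas <- c(0.2, 0.6, 1.2)
  mean_pcc <- vapply(sigmas, function(s) {
    mean(vapply(1:10, function(sd) {
      cfg <- synth_config(n_genes = 300, n_complexes = 5,
                          complex_size_range = c(3, 4),
                          n_background_strains = 10, n_paralog_pairs = 0,
                          noise_sd = s, seed = sd)
      sim <- generate_deleteome(cfg)
      mean(pair_profile_correlation(sim$matrix,
                                    sim$truth$positive_pairs)$pairs$pcc)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_pcc) <= 0))
})

test_that("strain budget and angle range are validated", {
  expect_error(synth_config(n_genes = 100, n_complexes = 40),
               "strain budget")
  expect_error(synth_config(divergence_angles = 2.0), "pi/2")
  expect_error(synth_config(gi_overlap = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(n_complexes = -1), ">= 0")
})

test_that("ground truth is internally consistent", {
  sim <- generate_deleteome(tiny_config(seed = 5))
  tr <- sim$truth
  # positive pairs are exactly the within-complex pairs
  expected <- unlist(lapply(tr$complexes, function(m) {
    if (length(m) < 2) return(character(0))
    cmb <- utils::combn(sort(m), 2)
    paste(cmb[1, ], cmb[2, ])
  }), use.names = FALSE)
  got <- paste(tr$positive_pairs$gene_a, tr$positive_pairs$gene_b)
  expect_setequal(got, expected)
  # no strain in two complexes; all strains in the matrix
  memb <- unlist(tr$complexes, use.names = FALSE)
  expect_equal(anyDuplicated(memb), 0L)
  expect_true(all(memb %in% rownames(sim$matrix)))
  expect_true(all(unlist(tr$paralog_pairs[c("gene_a", "gene_b")]) %in%
                    rownames(sim$matrix)))
})

test_that("paralogs at theta = 0 without noise are proportional profiles", {
  cfg <- synth_config(n_genes = 300, n_complexes = 0,
                      n_background_strains = 0, n_paralog_pairs = 3,
                      divergence_angles = 0, noise_sd = 0, seed = 2)
  par <- generate_paralogs(cfg)
  pcc <- pair_profile_correlation(par$matrix, par$records)$pairs$pcc
  expect_equal(pcc, rep(1, 3), tolerance = 1e-12)
})

test_that("paralogs at theta = pi/2 without noise are uncorrelated on average", {
  pccs <- vapply(1:100, function(sd) {
    cfg <- synth_config(n_genes = 300, n_complexes = 0,
                        n_background_strains = 0, n_paralog_pairs = 1,
                        divergence_angles = pi / 2, noise_sd = 0, seed = sd)
    par <- generate_paralogs(cfg)
    pair_profile_correlation(par$matrix, par$records)$pairs$pcc
  }, numeric(1))
  expect_lt(abs(mean(pccs)), 0.05)
})

test_that("simulated gi score tracks redundancy r, not divergence theta", {
  cfg <- synth_config(n_genes = 400, n_complexes = 0,
                      n_background_strains = 0, n_paralog_pairs = 20,
                      divergence_angles = seq(0, pi / 2, length.out = 20),
                      gi_overlap = rep(c(0, 1), 10), seed = 9)
  rec <- generate_paralogs(cfg)$records
  expect_equal(rec$gi_score, -rec$r, tolerance = 0.25)
  expect_gt(abs(cor(rec$gi_score, rec$r)), 0.9)
})
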