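# One seeded, logged, configurable run: simulate (or load) -> reduce ->
# cluster -> score -> benchmark -> differential expression -> paralogs.
# Every stage's result is written as a documented TSV artifact, so each
# stage can be re-run independently from disk.

#' Pipeline run configuration
#'
#' Exactly one of `synth` (a [synth_config()] for simulated input) or
#' `paths` (named list with `expression`, and optionally `complexes`,
#' `pairs`, `paralogs` TSVs) must be supplied. All stage seeds are derived
#' from `seed` by fixed offsets, overriding the seeds inside the stage
#' parameter objects.
#'
#' @param synth optional [synth_config()].
#' @param paths optional named list of input TSV paths.
#' @param reduce a [reduce_params()].
#' @param cluster a [cluster_params()].
#' @param alpha target FDR for the distance cutoff (default 0.05).
#' @param pcc_max correlation ceiling for novel calls (default 0.5).
#' @param methods embedding methods to score; `"umap"` and `"pca"` are
#'   always included.
#' @param call_universe candidate pairs for novel calling: `"all"` strain
#'   pairs (default) or `"labeled"` only.
#' @param seed master seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(synth = NULL, paths = NULL,
                       reduce = reduce_params(), cluster = cluster_params(),
                       alpha = 0.05, pcc_max = 0.5,
                       methods = c("umap", "pca", "tsne", "randproj",
                                   "highdim"),
                       call_universe = c("all", "labeled"), seed = 1L) {
  if (is.null(synth) == is.null(paths))
    stop("supply exactly one of synth= or paths=")
  structure(list(synth = synth, paths = paths, reduce = reduce,
                 cluster = cluster, alpha = alpha, pcc_max = pcc_max,
                 methods = union(c("umap", "pca"), methods),
                 call_universe = match.arg(call_universe),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates (or loads) the deletion compendium, embeds it (PCA feeding
#' UMAP, plus any of t-SNE, random projection and the raw high-dimensional
#' view), clusters the UMAP embedding (kNN + Louvain, with size-triggered
#' sub-clustering) and — for comparison — the 2D PCA view, scores every
#' labelled pair under every metric, benchmarks each metric with ROC and
#' precision/recall curves, calibrates the FDR distance cutoff, calls novel
#' interactions (close in the embedding, correlation below `pcc_max`),
#' computes complex co-clustering concordance and the UMAP-vs-PCA cluster
#' overlap, runs per-cluster differential expression with lambda-GC
#' correction, and builds the paralog divergence report. All artifacts are
#' written under `outdir`; rerunning with the same config reproduces the
#' deterministic artifacts byte for byte.
#'
#' @param config a [run_config()].
#' @param outdir output directory (created).
#' @return invisible list with all in-memory results (`matrix`, `truth`,
#'   `embeddings`, `clusters`, `clusters_pca`, `pairs`, `rocs`, `prs`,
#'   `fdr`, `novel`, `concordance_main`, `concordance_sub`, `overlap`,
#'   `de`, `paralogs`, `files`).
#' @export
run_all <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    p <- file.path(outdir, name)
    files[[length(files) + 1L]] <<- p
    p
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (partial artifacts kept in ", outdir, ")", call. = FALSE))
    elapsed <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
    cat(sprintf("[perturbmap] %-12s %8.2fs\n", name, elapsed),
        file = file.path(outdir, "log.txt"), append = TRUE)
    res
  }

  seed <- config$seed
  rparams <- config$reduce
  rparams$seed <- .child_seed(seed, 12L)
  cparams <- config$cluster
  cparams$seed <- .child_seed(seed, 13L)

  # ---- input ----
  inp <- stage("input", {
    if (!is.null(config$synth)) {
      sc <- config$synth
      sc$seed <- .child_seed(seed, 11L)
      sim <- generate_deleteome(sc)
      write_expression_matrix(sim$matrix, emit("expression.tsv"))
      gt <- write_ground_truth(sim$truth, outdir, config = sc)
      files <- c(files, unname(gt))
      catalog <- sim$truth$complexes
      paralogs <- sim$truth$paralog_pairs
      list(X = sim$matrix, truth = sim$truth, catalog = catalog,
           paralogs = paralogs, interactions = NULL)
    } else {
      X <- read_expression_matrix(config$paths$expression)
      catalog <- if (!is.null(config$paths$complexes))
        read_complex_catalog(config$paths$complexes) else NULL
      interactions <- if (!is.null(config$paths$pairs))
        read_pair_labels(config$paths$pairs) else NULL
      paralogs <- if (!is.null(config$paths$paralogs))
        read_paralog_table(config$paths$paralogs) else NULL
      list(X = X, truth = NULL, catalog = catalog, paralogs = paralogs,
           interactions = interactions)
    }
  })
  X <- inp$X

  # ---- reduce ----
  pca <- stage("pca", {
    npc <- min(rparams$n_pcs_main, nrow(X) - 1L, ncol(X))
    pca_scores(X, npc, center = rparams$center, scale = rparams$scale)
  })
  embeddings <- list(pca = pca)
  embeddings$umap <- stage("umap", embed_umap(pca, rparams))
  if ("tsne" %in% config$methods) {
    tp <- rparams
    tp$perplexity <- min(rparams$perplexity, floor((nrow(X) - 2) / 3))
    embeddings$tsne <- stage("tsne", embed_tsne(pca, tp))
  }
  if ("randproj" %in% config$methods)
    embeddings$randproj <- stage("randproj",
      embed_random_projection(X, rparams$out_dims,
                              seed = .child_seed(seed, 14L)))
  if ("highdim" %in% config$methods)
    embeddings$highdim <- highdim_view(X)
  for (m in setdiff(names(embeddings), "highdim"))
    write_embedding(embeddings[[m]], emit(paste0("embedding_", m, ".tsv")))

  # ---- cluster ----
  clusters <- stage("cluster", {
    g <- build_knn_graph(embeddings$umap, cparams$k_neighbors)
    main <- louvain_cluster(g, cparams$resolution, seed = cparams$seed)
    subcluster(X, main, cparams, rparams)
  })
  write_cluster_assignment(clusters, emit("clusters.tsv"))
  clusters_pca <- stage("cluster_pca", {
    pca2 <- new_embedding(pca$coords[, 1:2, drop = FALSE], "pca")
    g <- build_knn_graph(pca2, cparams$k_neighbors)
    louvain_cluster(g, cparams$resolution, seed = cparams$seed)
  })
  write_cluster_assignment(clusters_pca, emit("clusters_pca.tsv"))

  # ---- score ----
  interactions <- inp$interactions
  if (is.null(interactions)) {
    if (is.null(inp$catalog)) stop("no interaction labels available")
    interactions <- catalog_to_pairs(inp$catalog, rownames(X))
  }
  pairs <- stage("score",
    assemble_labeled_pairs(interactions, embeddings, X))
  write_scored_pairs(pairs, emit("scored_pairs.tsv"))

  # ---- bench ----
  metrics <- c(paste0(vapply(embeddings, function(e)
    .metric_short(e$method), character(1)), "_dist"), "pcc")
  rocs <- list(); prs <- list()
  for (m in metrics) {
    dirn <- if (m == "pcc") "higher_is_hit" else "lower_is_hit"
    rocs[[m]] <- roc_curve(pairs, m, dirn)
    prs[[m]] <- pr_curve(pairs, m, dirn)
    utils::write.table(
      data.frame(threshold = rocs[[m]]$thresholds,
                 fpr = rocs[[m]]$fpr[-1], tpr = rocs[[m]]$tpr[-1]),
      emit(paste0("roc_", m, ".tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(threshold = prs[[m]]$thresholds,
                 recall = prs[[m]]$recall, precision = prs[[m]]$precision),
      emit(paste0("pr_", m, ".tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  fdr <- stage("fdr", fdr_cutoff(pairs, "umap_dist", config$alpha))
  utils::write.table(
    data.frame(alpha = fdr$alpha, threshold = fdr$threshold,
               achieved_fdr = fdr$achieved_fdr, n_called = fdr$n_called),
    emit("fdr_cutoff.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  novel <- stage("novel", {
    if (fdr$no_cutoff) {
      out <- pairs[0, ]
      out$label_status <- character(0)
      out
    } else if (config$call_universe == "all") {
      cand <- assemble_labeled_pairs(
        interactions, embeddings["umap"], X,
        unlabeled = all_strain_pairs(rownames(X)))
      call_novel(cand, fdr$threshold, "umap_dist", config$pcc_max)
    } else {
      call_novel(pairs, fdr$threshold, "umap_dist", config$pcc_max)
    }
  })
  write_scored_pairs(novel, emit("novel_calls.tsv"))

  concordance_main <- concordance_sub <- NULL
  if (!is.null(inp$catalog)) {
    concordance_main <- complex_concordance(inp$catalog, clusters,
                                            level = "main_cluster")
    utils::write.table(concordance_main, emit("concordance_main.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    concordance_sub <- complex_concordance(inp$catalog, clusters,
                                           level = "sub_cluster")
    utils::write.table(concordance_sub, emit("concordance_sub.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  overlap <- clustering_overlap(clusters, clusters_pca)
  utils::write.table(overlap, emit("overlap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # ---- diffex ----
  de <- stage("diffex", cluster_de_all(X, clusters))
  utils::write.table(de, emit("de.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # ---- paralog ----
  paralogs <- NULL
  if (!is.null(inp$paralogs) && nrow(inp$paralogs) > 0L) {
    paralogs <- stage("paralog", {
      rep <- paralog_report(embeddings$umap, X, inp$paralogs)
      if (!is.null(rep$gi_score)) flag_divergent_redundant(rep) else rep
    })
    utils::write.table(paralogs, emit("paralog_report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # ---- manifest (deterministic: no timestamps) ----
  manifest <- c(
    "perturbmap run manifest",
    paste0("package_version\t", as.character(utils::packageVersion("perturbmap"))),
    paste0("r_version\t", R.version.string),
    paste0("master_seed\t", seed),
    paste0("alpha\t", config$alpha),
    paste0("pcc_max\t", config$pcc_max),
    paste0("methods\t", paste(config$methods, collapse = ",")),
    paste0("artifact\t", sort(basename(unlist(files)))))
  writeLines(manifest, file.path(outdir, "run_manifest.txt"))

  invisible(list(matrix = X, truth = inp$truth, embeddings = embeddings,
                 clusters = clusters, clusters_pca = clusters_pca,
                 pairs = pairs, rocs = rocs, prs = prs, fdr = fdr,
                 novel = novel, concordance_main = concordance_main,
                 concordance_sub = concordance_sub, overlap = overlap,
                 de = de, paralogs = paralogs,
                 files = unlist(files)))
}

#' Summarize a completed run directory
#'
#' Reads only the TSV artifacts of [run_all()] and produces a short
#' human-readable report: AUC per metric, the FDR threshold, novel-call
#' counts, complex co-clustering, cluster overlap, and top differentially
#' expressed genes per cluster.
#'
#' @param outdir the run directory.
#' @param top_n DE genes to list per cluster.
#' @return character vector of report lines (also printable with `cat`).
#' @export
summarize_run <- function(outdir, top_n = 5L) {
  need <- function(name) {
    p <- file.path(outdir, name)
    if (!file.exists(p)) stop("missing artifact: ", name)
    p
  }
  lines <- c("perturbmap run summary", strrep("=", 22))
  roc_files <- list.files(outdir, pattern = "^roc_.*\\.tsv$")
  for (f in roc_files) {
    curve <- utils::read.delim(file.path(outdir, f))
    fpr <- c(0, curve$fpr); tpr <- c(0, curve$tpr)
    auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
    metric <- sub("^roc_(.*)\\.tsv$", "\\1", f)
    lines <- c(lines, sprintf("AUC [%s]: %.4f", metric, auc))
  }
  fdr <- utils::read.delim(need("fdr_cutoff.tsv"))
  lines <- c(lines, sprintf("FDR cutoff (alpha = %g): threshold %.4g, %d labelled calls",
                            fdr$alpha, fdr$threshold, fdr$n_called))
  novel <- read_scored_pairs(need("novel_calls.tsv"))
  lines <- c(lines, sprintf("Novel calls: %d pairs, %d unique genes",
                            nrow(novel),
                            length(unique(c(novel$gene_a, novel$gene_b)))))
  if (file.exists(file.path(outdir, "concordance_main.tsv"))) {
    cc <- utils::read.delim(need("concordance_main.tsv"))
    eligible <- sum(cc$members_in_universe >= 2)
    lines <- c(lines, sprintf(
      "Complex co-clustering (main): %d/%d eligible complexes",
      sum(cc$co_clustered), eligible))
  }
  ov <- utils::read.delim(need("overlap.tsv"))
  lines <- c(lines, sprintf(
    "UMAP vs PCA clusters: %d/%d perfect, %d/%d overlap >= 50%%",
    sum(ov$overlap_fraction == 1), nrow(ov),
    sum(ov$overlap_fraction >= 0.5), nrow(ov)))
  cl <- read_cluster_assignment(need("clusters.tsv"))
  lines <- c(lines, sprintf("Clusters: %d main, %d total",
                            length(unique(cl$main_cluster)),
                            length(unique(cl$sub_cluster))))
  de <- utils::read.delim(need("de.tsv"))
  for (cid in sort(unique(de$cluster))) {
    block <- de[de$cluster == cid, ]
    block <- block[order(block$q, block$p_corr), ]
    top <- utils::head(block$gene, top_n)
    lines <- c(lines, sprintf("Cluster %s top DE: %s", cid,
                              paste(top, collapse = ", ")))
  }
  lines
}
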