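# Readers and writers for every on-disk format the pipeline touches.
# Single tabular dialect: tab-separated, UTF-8, '.' decimal, no quoting.

#' Validate a strain-by-gene expression matrix
#'
#' @param X numeric matrix, strains in rows (rownames = strain ids, i.e. the
#'   deleted gene of each strain), measured genes in columns.
#' @return `X`, invisibly, after validation.
#' @export
validate_expression_matrix <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("expression matrix must be a numeric matrix")
  if (nrow(X) < 2L || ncol(X) < 2L)
    stop("expression matrix needs at least 2 strains and 2 genes")
  if (is.null(rownames(X)) || is.null(colnames(X)))
    stop("expression matrix needs strain rownames and gene colnames")
  if (anyDuplicated(rownames(X))) stop("duplicate strain ids")
  if (anyDuplicated(colnames(X))) stop("duplicate gene ids")
  bad <- which(!is.finite(X), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite value at strain '", rownames(X)[bad[1, 1]],
         "', gene '", colnames(X)[bad[1, 2]], "'")
  invisible(X)
}

#' Read an expression matrix from TSV
#'
#' Expects a header row of gene ids and a first column of strain ids. Any
#' missing or non-numeric cell is an error naming the offending strain and
#' gene; nothing is silently coerced.
#'
#' @param path file path.
#' @return validated numeric matrix (strains x genes).
#' @export
read_expression_matrix <- function(path) {
  raw <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = "character", data.table = FALSE)
  if (ncol(raw) < 3L) stop("expected strain column plus >= 2 gene columns")
  strains <- raw[[1]]
  genes <- colnames(raw)[-1]
  vals <- suppressWarnings(
    vapply(raw[-1], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) vals <- matrix(vals, nrow = 1L)
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-numeric or missing cell at strain '", strains[bad[1, 1]],
         "', gene '", genes[bad[1, 2]], "' in ", path)
  dimnames(vals) <- list(strains, genes)
  validate_expression_matrix(vals)
  vals
}

#' Write an expression matrix to TSV
#' @param X validated strains x genes matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(X, path) {
  validate_expression_matrix(X)
  df <- data.frame(strain = rownames(X), X, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Canonicalize unordered gene pairs
#'
#' Stores each pair with `gene_a < gene_b` (lexicographic); rejects
#' self-pairs and duplicates.
#'
#' @param pairs data.frame whose first two columns are gene ids.
#' @return the data.frame with pairs canonicalized and rows sorted.
#' @export
canonicalize_pairs <- function(pairs) {
  a <- as.character(pairs[[1]]); b <- as.character(pairs[[2]])
  if (any(a == b)) stop("self-pair not allowed: ", a[which(a == b)[1]])
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate pair: ", sub("\r", " - ", key[duplicated(key)][1]))
  out <- pairs
  out[[1]] <- a; out[[2]] <- b
  out[order(a, b), , drop = FALSE]
}

#' Read a complex catalog (complex_id, gene_id TSV)
#' @param path two-column TSV with header.
#' @return named list: complex id -> character vector of member gene ids.
#' @export
read_complex_catalog <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("complex catalog needs 2 columns")
  cat <- lapply(split(df[[2]], df[[1]]), unique)
  if (any(lengths(cat) == 0L)) stop("empty complex in catalog")
  cat
}

#' Write a complex catalog
#' @param catalog named list complex id -> member gene ids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_complex_catalog <- function(catalog, path) {
  df <- data.frame(complex_id = rep(names(catalog), lengths(catalog)),
                   gene_id = unlist(catalog, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read labelled interaction pairs
#'
#' Three-column TSV `gene_a`, `gene_b`, `label` with label tokens
#' `true`/`false` (case-insensitive; `1`/`0` also accepted). Pairs are
#' canonicalized; duplicates and self-pairs are errors.
#'
#' @param path file path.
#' @param source_tag optional provenance tag stored as an attribute.
#' @return data.frame `gene_a`, `gene_b`, `label` (logical).
#' @export
read_pair_labels <- function(path, source_tag = basename(path)) {
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 3L) stop("pair label file needs 3 columns")
  tok <- tolower(df[[3]])
  lab <- ifelse(tok %in% c("true", "1"), TRUE,
                ifelse(tok %in% c("false", "0"), FALSE, NA))
  if (anyNA(lab))
    stop("unknown label token '", df[[3]][which(is.na(lab))[1]], "' in ", path)
  out <- canonicalize_pairs(data.frame(gene_a = df[[1]], gene_b = df[[2]],
                                       label = lab,
                                       stringsAsFactors = FALSE))
  attr(out, "source") <- source_tag
  out
}

#' Write labelled interaction pairs
#' @param pairs data.frame `gene_a`, `gene_b`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pair_labels <- function(pairs, path) {
  out <- pairs
  out$label <- tolower(as.character(out$label))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a paralog pair table
#'
#' TSV with columns `gene_a`, `gene_b` and any of the optional numeric
#' columns `divergence_metric`, `gi_score` (negative gi = synthetic-lethal
#' -like). Absent optional columns stay absent — they are never zero-filled.
#'
#' @param path file path.
#' @return canonicalized data.frame.
#' @export
read_paralog_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("paralog table needs at least 2 columns")
  names(df)[1:2] <- c("gene_a", "gene_b")
  num_cols <- setdiff(names(df), c("gene_a", "gene_b"))
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v) && !anyNA(df[[cc]]))
      stop("non-numeric value in paralog column '", cc, "'")
    df[[cc]] <- v
  }
  canonicalize_pairs(df)
}

#' Turn a complex catalog into labelled pairs over a universe
#'
#' Positives are all within-complex pairs restricted to genes present in
#' `universe`. Negatives default to all remaining pairs over genes that
#' carry at least one complex annotation and are in the universe (so genes
#' with no annotation are never labelled non-interacting); set
#' `negatives = "all"` to draw negatives from the full universe instead.
#'
#' @param catalog named list complex id -> member gene ids.
#' @param universe character vector of gene/strain ids available.
#' @param negatives `"annotated"` (default) or `"all"`.
#' @return data.frame `gene_a`, `gene_b`, `label` (logical), canonical order.
#' @export
catalog_to_pairs <- function(catalog, universe,
                             negatives = c("annotated", "all")) {
  negatives <- match.arg(negatives)
  members <- lapply(catalog, function(g) sort(intersect(g, universe)))
  annotated <- sort(unique(unlist(members, use.names = FALSE)))
  if (length(annotated) == 0L)
    warning("no catalog gene present in the universe")
  pos_key <- unique(unlist(lapply(members, function(g) {
    if (length(g) < 2L) return(character(0))
    cmb <- utils::combn(g, 2L)
    paste(cmb[1, ], cmb[2, ], sep = "\r")
  }), use.names = FALSE))
  pool <- if (negatives == "annotated") annotated else sort(unique(universe))
  if (length(pool) < 2L) {
    all_key <- character(0)
  } else {
    cmb <- utils::combn(pool, 2L)
    all_key <- paste(cmb[1, ], cmb[2, ], sep = "\r")
  }
  key <- sort(unique(c(all_key, pos_key)))
  parts <- strsplit(key, "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(parts, `[`, "", 1L),
                    gene_b = vapply(parts, `[`, "", 2L),
                    label = key %in% pos_key,
                    stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Read / write a 2D (or d-D) embedding TSV
#'
#' Columns: `strain`, then one column per embedding dimension; the method
#' tag is stored in a `# method:` comment line.
#'
#' @param embedding an embedding, as returned by [pca_scores()],
#'   [embed_umap()] and friends.
#' @param path file path.
#' @return `read_embedding`: the embedding; `write_embedding`: `path`.
#' @export
write_embedding <- function(embedding, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# method: ", embedding$method), con)
  df <- data.frame(strain = embedding$strain_ids, embedding$coords,
                   check.names = FALSE)
  colnames(df) <- c("strain", paste0("d", seq_len(ncol(embedding$coords))))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_embedding
#' @export
read_embedding <- function(path) {
  first <- readLines(path, n = 1L)
  method <- if (startsWith(first, "# method: "))
    sub("^# method: ", "", first) else "unknown"
  df <- utils::read.delim(path, header = TRUE, comment.char = "#", quote = "")
  coords <- as.matrix(df[-1])
  rownames(coords) <- df[[1]]
  new_embedding(coords, method)
}

#' Read / write a cluster assignment TSV (strain, main_cluster, sub_cluster)
#' @param assignment data.frame as returned by [louvain_cluster()] /
#'   [subcluster()].
#' @param path file path.
#' @return `read_cluster_assignment`: the data.frame; the writer: `path`.
#' @export
write_cluster_assignment <- function(assignment, path) {
  utils::write.table(assignment, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cluster_assignment
#' @export
read_cluster_assignment <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  df$strain <- as.character(df$strain)
  if ("sub_cluster" %in% names(df))
    df$sub_cluster <- as.character(df$sub_cluster)
  df
}

#' Write / read the scored-pairs table
#' @param pairs labelled-pairs data.frame from [assemble_labeled_pairs()].
#' @param path file path.
#' @return reader: the data.frame; writer: `path`, invisibly.
#' @export
write_scored_pairs <- function(pairs, path) {
  out <- pairs
  out$label <- ifelse(is.na(out$label), "unlabeled",
                      tolower(as.character(out$label)))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scored_pairs
#' @export
read_scored_pairs <- function(path) {
  df <- utils::read.delim(path, header = TRUE, quote = "",
                          stringsAsFactors = FALSE)
  df$label <- ifelse(df$label == "unlabeled", NA, df$label == "true")
  df
}
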