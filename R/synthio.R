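# Synthetic deletion-compendium generator with planted complexes, paralog
# pairs and labelled interaction ground truth.

#' Configuration for the synthetic deletion compendium
#'
#' Builds and validates the parameter set for [generate_deleteome()]. The
#' generative model plants protein complexes as groups of deletion strains
#' sharing a sparse transcriptional "signature": member \eqn{i} of complex
#' \eqn{c} has expression profile \eqn{a_i s_c + \epsilon}, where \eqn{s_c}
#' is the complex signature (`signature_targets` nonzero genes drawn
#' \eqn{N(0, \tau^2)}), \eqn{a_i \sim N(1, \mathrm{member\_strength\_sd}^2)}
#' is a per-member scalar, and \eqn{\epsilon} is i.i.d. per-gene Gaussian
#' noise with sd `noise_sd`. Background strains are pure noise (or carry a
#' unique weak signature at scale \eqn{\tau/4} when `weak_background` is
#' set). Paralog pairs mix a fresh signature `s` with an orthogonalized
#' independent signature by a divergence angle \eqn{\theta}
#' (see [generate_paralogs()]).
#'
#' Each strain deletes one distinct measured gene; the strain id is the id
#' of its deleted gene, so the total strain count may not exceed `n_genes`.
#'
#' @param n_genes number of measured genes (columns).
#' @param n_complexes number of planted complexes.
#' @param complex_size_range integer vector `c(min, max)` of members per
#'   complex; sizes are drawn uniformly in this range.
#' @param n_background_strains strains carrying no planted structure.
#' @param signature_targets nonzero genes per complex signature.
#' @param signature_scale sd \eqn{\tau} of nonzero signature entries.
#' @param member_strength_sd sd of the per-member scalar around 1.
#' @param noise_sd per-gene Gaussian noise sd \eqn{\sigma}.
#' @param n_paralog_pairs number of planted paralog pairs (two strains each).
#' @param divergence_angles per-pair divergence angle \eqn{\theta} in
#'   radians, in `[0, pi/2]`; a single value is recycled. `NULL` spaces the
#'   pairs evenly over `[0, pi/2]`.
#' @param gi_overlap per-pair functional redundancy \eqn{r} in `[0, 1]`; the
#'   simulated genetic-interaction score is \eqn{-r} plus small noise,
#'   independent of \eqn{\theta}, so divergence-vs-redundancy discordance
#'   can be planted. `NULL` draws \eqn{r} uniformly (seeded).
#' @param mark_deleted set each strain's own deleted gene to a strongly
#'   negative value in its row (cosmetic realism; off by default).
#' @param weak_background give background strains unique weak signatures
#'   (scale \eqn{\tau/4}) instead of pure noise.
#' @param seed master seed; all child seeds derive from it by fixed offsets.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_genes = 2000L,
                         n_complexes = 40L,
                         complex_size_range = c(3L, 6L),
                         n_background_strains = 200L,
                         signature_targets = 50L,
                         signature_scale = 1.0,
                         member_strength_sd = 0.1,
                         noise_sd = 0.5,
                         n_paralog_pairs = 20L,
                         divergence_angles = NULL,
                         gi_overlap = NULL,
                         mark_deleted = FALSE,
                         weak_background = FALSE,
                         seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_complexes = as.integer(n_complexes),
    complex_size_range = as.integer(complex_size_range),
    n_background_strains = as.integer(n_background_strains),
    signature_targets = as.integer(signature_targets),
    signature_scale = signature_scale,
    member_strength_sd = member_strength_sd,
    noise_sd = noise_sd,
    n_paralog_pairs = as.integer(n_paralog_pairs),
    divergence_angles = divergence_angles,
    gi_overlap = gi_overlap,
    mark_deleted = isTRUE(mark_deleted),
    weak_background = isTRUE(weak_background),
    seed = as.integer(seed)
  )
  counts <- c(cfg$n_genes, cfg$n_complexes, cfg$n_background_strains,
              cfg$signature_targets, cfg$n_paralog_pairs)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (length(cfg$complex_size_range) != 2L ||
      cfg$complex_size_range[1] < 1L ||
      cfg$complex_size_range[1] > cfg$complex_size_range[2])
    stop("complex_size_range must be c(min, max) with 1 <= min <= max")
  if (any(c(cfg$signature_scale, cfg$member_strength_sd, cfg$noise_sd) < 0))
    stop("scales and sds must be non-negative")
  if (!is.null(cfg$divergence_angles)) {
    th <- cfg$divergence_angles
    if (any(!is.finite(th)) || any(th < 0) || any(th > pi / 2 + 1e-12))
      stop("divergence_angles must lie in [0, pi/2]")
  }
  if (!is.null(cfg$gi_overlap)) {
    r <- cfg$gi_overlap
    if (any(!is.finite(r)) || any(r < 0) || any(r > 1))
      stop("gi_overlap must lie in [0, 1]")
  }
  max_strains <- cfg$n_complexes * cfg$complex_size_range[2] +
    cfg$n_background_strains + 2L * cfg$n_paralog_pairs
  if (max_strains > cfg$n_genes)
    stop("strain budget exceeded: up to ", max_strains,
         " strains but only ", cfg$n_genes,
         " genes available as deletion targets")
  structure(cfg, class = "synth_config")
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synth_config:", x$n_complexes, "complexes (size",
      paste(x$complex_size_range, collapse = "-"), "),",
      x$n_background_strains, "background strains,",
      x$n_paralog_pairs, "paralog pairs,",
      x$n_genes, "genes; sigma =", x$noise_sd,
      "tau =", x$signature_scale, "seed =", x$seed, "\n")
  invisible(x)
}

# Child seeds: fixed offsets from the master seed, kept within 32-bit range.
.child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7907 * offset) %% .Machine$integer.max)
}

# Sparse signature: `targets` nonzero genes with N(0, scale^2) entries.
# Caller is responsible for the RNG state.
.draw_signature <- function(n_genes, targets, scale) {
  s <- numeric(n_genes)
  idx <- sample.int(n_genes, targets)
  s[idx] <- stats::rnorm(targets, 0, scale)
  s
}

#' Generate a synthetic deletion compendium with planted ground truth
#'
#' Emits a strain-by-gene expression matrix (rows = deletion strains,
#' columns = measured genes) together with the ground truth needed to score
#' recovery: planted complex memberships, their signatures, the set of
#' within-complex strain pairs (the positive interaction labels), and the
#' paralog records. Identical `config` (including seed) gives bit-identical
#' output.
#'
#' @param config a [synth_config()].
#' @return a list with elements `matrix` (numeric strains x genes matrix
#'   with strain ids as rownames and gene ids as colnames) and `truth`, a
#'   `synth_truth` list with `complexes` (complex id -> member strain ids),
#'   `signatures` (complex id -> gene-indexed numeric vector),
#'   `positive_pairs` (data.frame `gene_a`, `gene_b` of all within-complex
#'   pairs, canonical order), `paralog_pairs` (data.frame `gene_a`,
#'   `gene_b`, `theta`, `r`, `gi_score`) and `seed`.
#' @examples
#' sim <- generate_deleteome(synth_config(n_genes = 300, n_complexes = 5,
#'                                        n_background_strains = 20,
#'                                        n_paralog_pairs = 2, seed = 1))
#' dim(sim$matrix)
#' names(sim$truth$complexes)
#' @export
generate_deleteome <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  ng <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))

  # -- structure: sizes, deleted-gene assignment, signatures, strengths --
  set.seed(.child_seed(config$seed, 1L))
  sizes <- if (config$n_complexes > 0L)
    sample(seq(config$complex_size_range[1], config$complex_size_range[2]),
           config$n_complexes, replace = TRUE) else integer(0)
  n_members <- sum(sizes)
  n_strains <- n_members + config$n_background_strains +
    2L * config$n_paralog_pairs
  deleted <- sample.int(ng, n_strains)   # distinct deletion target per strain
  strain_ids <- gene_ids[deleted]

  complex_ids <- sprintf("cplx%03d", seq_len(config$n_complexes))
  member_of <- rep(complex_ids, times = sizes)
  member_strains <- strain_ids[seq_len(n_members)]
  complexes <- split(member_strains, factor(member_of, levels = complex_ids))

  signatures <- lapply(complex_ids, function(cid)
    .draw_signature(ng, config$signature_targets, config$signature_scale))
  names(signatures) <- complex_ids
  strengths <- stats::rnorm(n_members, 1, config$member_strength_sd)

  # -- deterministic structural part of the matrix --
  X <- matrix(0, n_strains, ng, dimnames = list(strain_ids, gene_ids))
  if (n_members > 0L) {
    sig_mat <- do.call(rbind, signatures[member_of])
    X[seq_len(n_members), ] <- strengths * sig_mat
  }
  bg_rows <- n_members + seq_len(config$n_background_strains)
  if (config$weak_background && length(bg_rows)) {
    for (i in bg_rows)
      X[i, ] <- .draw_signature(ng, config$signature_targets,
                                config$signature_scale / 4)
  }

  # -- paralogs --
  par_rows <- n_members + config$n_background_strains +
    seq_len(2L * config$n_paralog_pairs)
  par_strains <- strain_ids[par_rows]
  par <- .paralog_profiles(config, par_strains,
                           seed = .child_seed(config$seed, 3L))
  if (config$n_paralog_pairs > 0L) X[par_rows, ] <- par$profiles

  # -- noise --
  set.seed(.child_seed(config$seed, 2L))
  if (config$noise_sd > 0)
    X <- X + matrix(stats::rnorm(n_strains * ng, 0, config$noise_sd),
                    n_strains, ng)
  if (config$mark_deleted)
    X[cbind(seq_len(n_strains), deleted)] <- -4 * max(config$signature_scale, 1)

  truth <- structure(list(
    complexes = complexes,
    signatures = signatures,
    positive_pairs = .within_complex_pairs(complexes),
    paralog_pairs = par$records,
    seed = config$seed
  ), class = "synth_truth")
  list(matrix = X, truth = truth)
}

# All within-complex unordered pairs, canonical (lexicographic) order.
.within_complex_pairs <- function(complexes) {
  pieces <- lapply(complexes, function(members) {
    if (length(members) < 2L) return(NULL)
    cmb <- utils::combn(sort(members), 2L)
    data.frame(gene_a = cmb[1, ], gene_b = cmb[2, ],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(pieces, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(gene_a = character(0), gene_b = character(0))
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

# Paralog profiles: pair member A uses signature s, member B uses
# cos(theta) s + sin(theta) s_perp with s_perp an independent signature
# orthogonalized against s and rescaled to |s|. gi_score = -r + noise,
# independent of theta.
.paralog_profiles <- function(config, par_strains, seed) {
  np <- config$n_paralog_pairs
  ng <- config$n_genes
  if (np == 0L) {
    return(list(profiles = matrix(0, 0, ng),
                records = data.frame(gene_a = character(0),
                                     gene_b = character(0),
                                     theta = numeric(0), r = numeric(0),
                                     gi_score = numeric(0))))
  }
  theta <- config$divergence_angles
  if (is.null(theta)) theta <- seq(0, pi / 2, length.out = np)
  theta <- rep_len(theta, np)
  set.seed(seed)
  r <- config$gi_overlap
  if (is.null(r)) r <- stats::runif(np)
  r <- rep_len(r, np)

  profiles <- matrix(0, 2L * np, ng)
  for (j in seq_len(np)) {
    s <- .draw_signature(ng, config$signature_targets, config$signature_scale)
    u <- .draw_signature(ng, config$signature_targets, config$signature_scale)
    perp <- u - sum(u * s) / sum(s * s) * s
    perp <- perp * sqrt(sum(s^2) / sum(perp^2))
    profiles[2L * j - 1L, ] <- s
    profiles[2L * j, ] <- cos(theta[j]) * s + sin(theta[j]) * perp
  }
  gi <- -r + stats::rnorm(np, 0, 0.05)
  a <- par_strains[seq(1, 2L * np, by = 2)]
  b <- par_strains[seq(2, 2L * np, by = 2)]
  swap <- a > b   # canonical pair order; profiles stay with their strain
  records <- data.frame(gene_a = ifelse(swap, b, a),
                        gene_b = ifelse(swap, a, b),
                        theta = theta, r = r, gi_score = gi,
                        stringsAsFactors = FALSE)
  list(profiles = profiles, records = records)
}

#' Generate paralog strain profiles alone
#'
#' Standalone access to the paralog part of the generative model: each pair
#' mixes a fresh sparse signature `s` with an independent signature
#' orthogonalized against `s`, by the pair's divergence angle
#' \eqn{\theta} — member A is \eqn{s + \epsilon}, member B is
#' \eqn{\cos\theta\, s + \sin\theta\, s_\perp + \epsilon}. The simulated
#' genetic-interaction score is \eqn{-r} plus small noise and does not
#' depend on \eqn{\theta}, so redundancy (negative genetic interaction) and
#' transcriptional divergence can be planted independently.
#'
#' @param config a [synth_config()]; `n_paralog_pairs`, `divergence_angles`
#'   and `gi_overlap` control the output.
#' @return list with `matrix` (2 x n_pairs strain profiles, noise added) and
#'   `records` (data.frame `gene_a`, `gene_b`, `theta`, `r`, `gi_score`).
#' @export
generate_paralogs <- function(config) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  ng <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(ng))
  set.seed(.child_seed(config$seed, 1L))
  strains <- gene_ids[sample.int(ng, 2L * config$n_paralog_pairs)]
  par <- .paralog_profiles(config, strains, seed = .child_seed(config$seed, 3L))
  X <- par$profiles
  set.seed(.child_seed(config$seed, 2L))
  if (config$noise_sd > 0 && nrow(X) > 0L)
    X <- X + matrix(stats::rnorm(length(X), 0, config$noise_sd), nrow(X), ng)
  dimnames(X) <- list(strains, gene_ids)
  list(matrix = X, records = par$records)
}

#' Write all ground-truth artifacts of a synthetic run
#'
#' Writes the complex membership table, the positive (within-complex) pair
#' table, the paralog record table and a plain-text run manifest.
#'
#' @param truth the `truth` element returned by [generate_deleteome()].
#' @param dir output directory (created if needed).
#' @param config the [synth_config()] used, recorded in the manifest.
#' @return invisibly, the named vector of file paths written.
#' @export
write_ground_truth <- function(truth, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(complexes = file.path(dir, "complexes.tsv"),
             positive_pairs = file.path(dir, "positive_pairs.tsv"),
             paralogs = file.path(dir, "paralogs.tsv"),
             manifest = file.path(dir, "manifest.txt"))
  memb <- data.frame(
    complex_id = rep(names(truth$complexes), lengths(truth$complexes)),
    strain_id = unlist(truth$complexes, use.names = FALSE))
  utils::write.table(memb, paths["complexes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$positive_pairs, paths["positive_pairs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$paralog_pairs, paths["paralogs"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  lines <- c("perturbmap synthetic run", paste0("seed\t", truth$seed))
  if (!is.null(config)) {
    flat <- vapply(config, function(v)
      paste(format(v, digits = 15), collapse = ","), character(1))
    lines <- c(lines, paste0(names(flat), "\t", flat))
  }
  writeLines(lines, paths["manifest"])
  invisible(paths)
}
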