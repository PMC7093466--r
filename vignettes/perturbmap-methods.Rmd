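---
title: "perturbmap: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{perturbmap: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the science it implements:
the models and their assumptions, every tunable parameter that matters,
what the synthetic-data generator does and does not emulate, the
numerical conventions, and the design decisions taken where the design
was genuinely open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The interaction-inference model

The input is a strains × genes matrix of expression effects on a common
log-ratio scale: one row per single-gene perturbation (e.g. a deletion
strain), one column per measured gene. The working hypothesis is that
perturbations of functionally linked genes — members of one protein
complex or pathway — produce similar rows, and that this similarity is
concentrated in a modest number of directions of the gene space.

The pipeline therefore scores a gene pair by the Euclidean distance of
the two strains in a low-dimensional embedding:

1. **PCA.** Genes are centered (no scaling — the input is already on a
   common scale; `reduce_params(scale = TRUE)` enables scaling). The top
   `n_pcs_main = 100` component scores are computed from the
   eigendecomposition of the smaller Gram matrix, so the full compendium
   never requires a genes × genes covariance. Component signs are fixed
   (largest-magnitude loading positive) to make results deterministic.
2. **UMAP** on the PC scores: cosine metric, `n_neighbors = 10`,
   `min_dist = 0.05`, 2 output dimensions, single-threaded with a fixed
   seed. The cosine metric emphasizes the *pattern* of a response over
   its magnitude, which suits perturbations of the same process executed
   with different strengths.
3. **Louvain clustering** on the k-nearest-neighbour graph (`k = 3`,
   symmetrized union, unweighted edges) of the embedded strains at
   modularity resolution `1e-4`. Since modularity optimization never
   merges disconnected communities, the sparse k = 3 graph still
   produces many clusters at this low resolution; the resolution knob
   controls granularity and is deliberately exposed, because its
   transferable content is the granularity, not the literal value (the
   same number means different things in different Louvain
   implementations). Labels are renumbered by decreasing cluster size.
   Main clusters with more than `subcluster_min_size = 25` strains are
   re-processed on their own (PCA with `n_pcs_sub = 25` components,
   capped at size − 1, then UMAP, kNN, Louvain at the same resolution);
   other strains keep their main label as the sub label. The size rule
   is used as the trigger (rather than a fixed list of cluster ids)
   because it is scale-free and self-documenting.
4. **Pair scoring.** For labelled pairs (gold-standard positives and
   negatives) the package computes the embedded distance under every
   configured space — UMAP, PCA (all retained components), t-SNE, random
   orthonormal projection, and the raw high-dimensional view — plus the
   Pearson correlation (PCC) of the two full profiles. Distances over
   many pairs in high-dimensional spaces are evaluated through the Gram
   matrix of the unique strains, never through a pairs × genes block.
5. **Benchmarking.** ROC and precision/recall curves are computed from
   first principles with a pinned tie convention: the curve is traced
   over distinct score thresholds, so tied scores contribute diagonal
   steps and the trapezoidal AUC equals the Mann–Whitney U estimator
   with ties counted half. (The test suite checks this equivalence
   against an independent U implementation and against pROC.)
6. **FDR calibration and novel calls.** Candidate thresholds are the
   observed labelled distances; FDR(t) = FP/(TP+FP) among labelled pairs
   with d ≤ t, and the largest t with FDR ≤ α (= 0.05) is selected.
   Only labelled pairs calibrate the threshold; unlabelled pairs are then
   scored against it. A novel call is a pair with d ≤ t (closed bound)
   and PCC < 0.5 (open bound): proximity in the embedding that the
   classical correlation criterion would miss. When no threshold
   qualifies, the result says so explicitly rather than returning 0 —
   distance 0 means "co-located", the opposite of "nothing called".

### Assumptions

* Rows are comparable (already normalized); the package performs no
  normalization beyond gene centering.
* Similar transcriptional consequences imply functional linkage. This is
  the biological premise, not something the package can verify; the
  benchmarking stage exists precisely to quantify how well it holds
  against external labels.
* Negative labels derived from a complex catalog are restricted, by
  default, to genes carrying at least one complex annotation
  (`catalog_to_pairs(negatives = "annotated")`), so genes about which
  the catalog says nothing are never labelled "non-interacting";
  `negatives = "all"` widens the pool for users who want it.

## Differential expression and enrichment

For each cluster, every gene is tested for a mean shift between the
cluster's strains and all remaining strains under an equal-variance
Gaussian model — the likelihood-ratio contrast of a cluster-membership
indicator against an intercept-only model, which reduces to the pooled
two-sample F test. The exact F p-value is mapped monotonically onto the
χ²(1) scale (statistic = upper χ²(1) quantile of the p-value). The
mapping is chosen over the asymptotic LRT statistic because it is
*exactly* χ²(1)-distributed under the null, which is the natural scale
for genomic control: λ_GC = median(χ²)/0.4549; statistics are deflated by
λ only when λ > 1 (the standard convention — a deflated null is left
alone), p-values recomputed, and BH q-values taken per cluster. λ is
computed per cluster rather than globally so that one inflated contrast
cannot deflate another cluster's statistics. A gene with zero overall
variance carries no evidence: statistic 0, p = 1 by convention.

Gene-set over-representation is a one-sided hypergeometric tail test on
user-supplied term → gene annotations with BH adjustment across terms —
a deliberate generic stand-in for ontology-specific enrichment tools; no
term hierarchy or propagation is modelled.

## Paralog divergence

Each paralog pair gets its embedded distance and profile correlation,
joined with whatever external columns the user supplies (a divergence
metric, a genetic-interaction score). `flag_divergent_redundant()` marks
pairs with a strong negative genetic interaction (gi ≤ `gi_threshold`,
default −0.5 — the classical signature of retained redundancy) whose
embedded distance nevertheless lies above the `distance_quantile`
(default 0.75) of all paralog distances. Both defaults are conventions,
not literature values, and are exposed as arguments; the flag is
monotone in the quantile (raising it never adds pairs).

## The synthetic compendium

The generator exists so that every downstream stage is testable with
planted ground truth. Its model:

* **Complexes.** `n_complexes = 40` groups of 3–6 strains. Complex c has
  a sparse signature s_c: `signature_targets = 50` genes with
  N(0, τ² = 1) effects — sparse so that complexes have distinct
  downstream target sets, as pathway-specific responses do. Member i's
  row is a_i·s_c + ε with a_i ~ N(1, 0.1²) (members perturb the shared
  program with different strengths) and ε i.i.d. N(0, σ² = 0.25)
  per gene.
* **Background.** `n_background_strains = 200` rows of pure noise by
  default; a flag gives each a unique weak signature (τ/4) instead, for
  fixtures where exact zero rows would be degenerate.
* **Paralogs.** `n_paralog_pairs = 20` pairs; member A uses a fresh
  signature s, member B uses cos θ·s + sin θ·s⊥ with s⊥ an independent
  signature orthogonalized against s and rescaled to ‖s‖. The simulated
  genetic-interaction score is −r plus N(0, 0.05²) noise, *independent*
  of θ, so divergence-vs-redundancy discordance can be planted at will.
  When θ and r are not supplied, θ is spaced evenly over [0, π/2] and r
  is drawn uniformly under the seed.
* **Strain identity.** Each strain deletes one distinct measured gene
  and is named after it; an optional flag writes a strongly negative
  value into the strain's own column (cosmetic realism, off by default).
* **Seeding.** One master seed; every stochastic component derives its
  own child seed by a fixed offset, so identical config + seed gives
  bit-identical output.

What it deliberately does **not** emulate: array/batch effects,
growth-rate confounding, missing values, overlapping complex membership,
correlated noise between genes, and realistic effect-size distributions.
Consequently, passing tests on this generator demonstrate the pipeline's
mechanics — signal recovery, calibration, determinism — not performance
on real compendia, where noise structure and signal strength differ.

Two signal-strength facts about the defaults are worth knowing, because
they bound what any analysis of such data can do. First, with complexes
of at most 6 members and per-gene noise sd 0.5, a signature gene's
two-sample z-statistic is about 4.9·|s|; since |s| is half-normal, a
sizable minority of each signature is statistically invisible, and the
top-50 gene list of a cluster's differential-expression ranking
plateaus around 60–75% true signature genes — an information limit, not
an implementation artifact. Second, a *two*-strain signature (a paralog
pair) contributes spectral energy below the detection edge of the PCA
step at these dimensions, so paralog placement in the embedding retains
only part of the planted divergence signal: discordant pairs are
flagged far more often than concordant ones, but per-pair flagging is
stochastic across seeds. Complexes, with 3–6 members, sit above that
edge — which is why their recovery is robust (embedding-distance AUC
≈ 0.97 across seeds, computed by the acceptance script).

## Numerical choices and conventions

* Pairs are stored canonically (lexicographically smaller gene first);
  self-pairs and duplicates are rejected at parse time.
* Missing metric values propagate as NA, never as 0.
* kNN distance ties are broken by strain-id order, so graphs are
  deterministic even with duplicated coordinates.
* UMAP and t-SNE run single-threaded under a fixed seed; identical
  input, seed and library version give identical coordinates. Changing
  the seed changes coordinates but leaves benchmark AUCs within
  stochastic tolerance (the acceptance script reports the 5-seed mean).
* t-SNE perplexity defaults to 30 and is validated against 3·perplexity
  < n − 1; the pipeline caps it automatically for small inputs.
* TSVs serialize doubles at 15 significant digits; write→read
  round-trips are identity to 10⁻¹² relative tolerance, and rerunning a
  pipeline with the same config reproduces artifacts byte for byte.
* The Louvain vertex order is shuffled under the seed before clustering
  (the algorithm is order-dependent), then mapped back.

## Problem sizes

The test suite exercises module behaviour on small fixtures (tens of
strains), the recovery properties on the default 422-strain × 2000-gene
compendium over seeds 1–5, and one full-scale run of ~1480 strains ×
6170 genes (200 complexes, 500 background strains, 40 paralog pairs),
which completes in about two minutes on a single CPU. The acceptance
script uses the default compendium and five consecutive seeds derived
from `--seed`.

## Known limitations

* Louvain is the only community-detection method; Leiden or others would
  be drop-in replacements at the `louvain_cluster()` surface but are not
  provided.
* No confidence intervals on AUC; the curves are point estimates.
* "Perfect overlap" between two clusterings is formalized as containment
  fraction 1.0 (one cluster wholly inside a single counterpart); the
  best Jaccard index and the adjusted Rand index are reported alongside
  for readers who prefer symmetric measures.
* The over-representation test treats annotation terms independently.
* Real-data preprocessing (normalization of raw arrays or counts) is out
  of scope; the expression matrix is assumed ready.
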