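---
title: "Methods: dissecting a tumor microenvironment atlas with tmetools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dissecting a tumor microenvironment atlas with tmetools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tmetools re-implements, as a tested and reusable pipeline, the
computational layer used to dissect the cellular microenvironment of a
multi-site tumor atlas (non-tumor liver, primary tumor, portal-vein tumor
thrombus, metastatic lymph node) profiled by droplet scRNA-seq, together
with marker-sum deconvolution of bulk cohorts. This vignette documents
the models, the tunable parameters and their defaults, the synthetic
world the test suite runs on, and the numerical choices made where the
design was genuinely open.

## Data model and normalization

Counts are genes × cells UMI matrices (`ExpressionMatrix`, backed by
sparse `dgCMatrix`). Cells carry cluster, tissue (closed set NTL / PT /
PVTT / MLN), patient and lineage labels. Quality control removes cells
with fewer than 200 UMIs, fewer than 200 or more than 8000 detected
genes, or more than 10% mitochondrial UMIs (gene-symbol prefix `MT-`,
configurable); the report lists the *first* failing rule per cell in the
fixed order low_umi, low_genes, high_genes, high_mito — the order is a
package convention, the thresholds are the analysis' stated values.

Normalization is library-size scaling to `scale = 10,000` counts per
cell followed by `log2(1 + x)`. The upstream analysis works on
"log2(Normalized Counts)" without printing its scaling constant; 10,000
is the convention of the toolkit that analysis used, and both `scale`
and `pseudocount` are exposed. With pseudocount 1 the transform maps 0
to 0 and preserves sparsity, and doubling all counts of a cell leaves
its normalized profile unchanged (library-size cancellation).

## Marker genes

`find_markers()` admits a gene as a cluster marker iff

1. two-sided Wilcoxon rank-sum p (cluster vs all other cells, normalized
   layer), Bonferroni-corrected over **all** genes in the matrix, is
   below `alpha = 0.01`;
2. linear-scale mean expression ratio is at least `min_fc = 2`; and
3. the detected fraction (normalized value > 0) is at least
   `min_pct_diff = 0.20` higher in the cluster.

The rank-sum test uses the normal approximation with tie correction and
no continuity correction — appropriate at the group sizes involved and
identical (to 1e-12) to `wilcox.test(exact = FALSE, correct = FALSE)`,
which the test suite uses as an independent oracle. Whether the original
fold change was computed on the log or linear scale is unstated; linear
was chosen (`2^x − 1` before averaging, with an epsilon of 1e-9 guarding
empty denominators) and is the package-wide convention, including in the
weighted similarity score. "Detected" means any UMI; the source analysis
does not define detection.

## Tissue preference (Ro/e)

For each (cluster, tissue) cell of the contingency table,
`ro_e_table()` reports Ro/e = observed / expected with expected = row ×
column / N, plus a two-sided chi-squared test. The analysis does not say
whether p-values are per-dot 2×2 or per-cluster omnibus; since the
dot-plots color each dot by its own p, the 2×2 collapse (cluster vs
rest) × (tissue vs rest), df = 1, is the default, with an omnibus option
(`omnibus = TRUE`). No continuity correction by default (the convention
of the statistic's originating literature); `correct = TRUE` enables
Yates. Patients are pooled, as the figure captions imply.

## Cluster similarity

Two schemes, for two data situations:

* `weighted_fc_similarity()` — when only marker tables are available:
  S[q, r] = Σ over shared markers of FC_q · FC_r. Fold changes are
  capped (default 100) so one near-zero-denominator gene cannot dominate.
* `classifier_similarity()` — when expression is available: a
  ridge-penalized multinomial logistic regression (glmnet, fixed
  `lambda = 0.01`, per-gene standardization, no cross-validation so the
  fit is deterministic) predicts reference clusters; S[q, r] is the mean
  predicted probability of reference class r over query cluster q, so
  rows sum to 1. Default features are the union of the top-50 markers
  per reference cluster. The penalty strength and feature rule are
  package choices; the source describes only "a logistic regression
  model".

## CTL exhaustion staging

`kmeans_states()` partitions cytotoxic T cells by k-means (default
`k = 5`, 25 restarts, seeded) on the normalized effector-gene submatrix
and relabels subclusters KM1..KMk by decreasing mean effector
expression, tracing the continuous loss of effector molecules; ties fall
back to center index. `flag_states()` flags the bottom subcluster
exhausted; the next-lowest is pre-exhausted iff the fraction of its
markers (vs the other CTL subclusters) contained in the exhausted
subcluster's marker set reaches `overlap_threshold = 0.5` — an
operationalization of "shares a high portion of signature genes", for
which no number is printed; the containment is asymmetric by design.
The exhaustion panel defaults to CTLA4, PDCD1, LAG3, CD27, CD52, ICOS;
the effector default (GZMB, PRF1, GNLY, IFNG, NKG7) is a conventional
placeholder to be overridden with the dataset's own panel.

## Ligand–receptor interactions

For each ordered pair of eligible clusters and each curated L-R pair,
the interaction intensity is mean(normalized ligand | sender) ×
mean(normalized receptor | receiver). Eligibility in a tissue requires
at least 5 cells and 10% of the base population (default: same-lineage
cells in that tissue; `fraction_base = "all"` is available since the
original wording is ambiguous about non-immune clusters). Pairs with
either mean below 1 (the log2-normalized-counts floor) are
expression-filtered before testing.

Significance comes from permuting the cluster tags of all cells jointly
(`n_perm = 1000`), recomputing every intensity each time: p_raw is the
fraction of permutations reaching the observed intensity. The original
wording "larger than the real value" (strict) makes p = 0 attainable;
the default tail is `ge` (a permutation equal to the observed counts
against it), with `tail = "gt"` reproducing the strict reading and an
optional `(count+1)/(n+1)` estimator, off by default. Bonferroni is
applied within each cluster pair across its tested L-R pairs ("across
the hundreds of L-R pairs"); a global family is selectable. A pair is
significant when intensity > 1 and adjusted p < 0.01.

The communication network weights the number of significant pairs per
directed cluster pair by cell numbers; the exact formula is unprinted,
so the default is count × (n_L · n_R) / N² with `cells_sum` and raw
`count` alternatives recorded in the output. The ligand–pathway network
reports Spearman correlations between ligand expression and per-cell
pathway scores (edges at p < 0.01, signed rho). Pathway scores are an
input; `pathway_activity()` ships a generic mean-z-score fallback since
GSVA internals are out of scope.

## Bulk deconvolution, TLS scoring, TME subtypes

The abundance of a subtype in a bulk sample is the **sum of log-TPM of
its marker genes**; normalized abundance divides by the summed abundance
of all patient-shared immune/stromal subtypes (columns then sum to 1).
TLS scoring uses the shipped 9-gene and 12-gene signatures with a median
split (ties go to the group named by `tie`, default low). Exhausted
T-cell abundance uses the six-marker panel. TME subtypes come from
k-means on the normalized abundances (default `k = 7`, 100 restarts,
seeded), without row standardization — the source clusters normalized
abundances directly; z-scoring is an option. No automatic k selection is
asserted; `tme_k_scan()` provides a silhouette diagnostic only.

## Clustering robustness

`nmi()` uses I(A;B) normalized by the arithmetic mean of the entropies
(natural logs); min/max/geometric variants are selectable since the
source cites only "the NMI index". Bijectively-relabeled identical
partitions return exactly 1 (detected from the contingency structure,
avoiding float round-off). `downsample_robustness()` re-clusters
without-replacement subsamples at fractions 1/2–1/5 × 100 replicates
(replicate seeds derived from the master seed by a counter);
`leave_one_patient_out()` holds out each patient. Re-clustering is a
callback: graph clustering itself is out of scope, and the shipped
reference callback (`make_kmeans_callback()`) runs k-means on top
principal components recomputed per subset. Whether the original
protocol recomputed the embedding per subsample is unstated; the
callback contract leaves that to the caller.

## The synthetic world

`simulate_cells()` draws counts from a negative binomial with gene-level
baselines (log-normal across genes, or explicit via `gene_means`),
multiplied by planted fold changes for cluster markers and L-R plants
(ligand shifted in the sender cluster, receptor in the receiver —
sufficient to make the product statistic significant). Tissue and
patient labels are multinomial per cluster. Decoy L-R pairs are built
from genes with no planted structure, so tag permutation is an exact
null and calibration can be measured. `simulate_bulk()` mixes
linear-scale cluster profiles convexly, log-transforms, and adds
Gaussian noise on the log scale.

The generator deliberately omits batch effects, doublets, ambient RNA
and patient-level expression variation. A green test therefore
establishes that the statistics behave as specified under their own
assumptions (NB counts, exchangeable cells under the null, convex bulk
mixtures) — not that they are robust to the artifacts of real data.

Two world-building notes. First, the `gene_means` override exists
because the detection-percentage rule is vacuous in a world where every
gene is well detected everywhere: worlds probing that rule state their
marker genes at a lowly-detected baseline, as cell-identity genes are in
real droplet data. Second, the exhaustion-gradient world keeps the
effector block a small fraction of the library; when planted effector
counts dominate a cell's library, size normalization saturates the top
of the gradient and adjacent high states become indistinguishable — a
property of the normalization, not of k-means.

## Numerical choices and degenerate inputs

* Bonferroni is exact: p_adj = min(1, p_raw × m).
* All k-means calls are seeded with explicit restart counts;
  Hartigan-Wong is swapped for Lloyd in the saturated k = n case, which
  it refuses.
* QC reasons report the first failing rule; all-zero genes are skipped
  silently in marker calling; constant genes get rank-sum p = 1;
  constant ligand vectors are skipped with a warning in the
  ligand–pathway network.
* `qc_filter` warns (does not error) when nothing survives;
  `normalize_counts` refuses zero-total cells with advice to run QC.
* Duplicate L-R rows collapse with a warning; duplicate bulk gene rows
  are summed with a warning.

## Known limitations

Batch correction, graph clustering, CNV inference, TF-activity scoring,
trajectory inference and survival modelling are intentionally out of
scope; labels and scores are exported for off-the-shelf tools. The
classifier similarity assumes shared feature genes measured on
comparable scales in both datasets. Marker-sum deconvolution is a rank
statistic, not a calibrated proportion estimate — its scores order
samples by subtype content but are not comparable across subtypes.
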