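# tmetools

Tumor-microenvironment analysis from single-cell and bulk RNA-seq.

Multi-site tumor atlases (non-tumor liver, primary tumor, portal-vein
tumor thrombus, metastatic lymph node) raise a recurring set of
questions: which cell clusters prefer which tissue, what genes mark
them, which clusters talk to each other through ligand–receptor pairs,
how exhausted are the cytotoxic T cells, and how does the single-cell
picture project onto large bulk cohorts. tmetools packages the
statistics behind those questions for analysts who want them reusable,
seeded and tested — together with a synthetic-data generator with
planted ground truth, so every stage is verifiable without access to
controlled patient data.

## What it computes

| Stage | Statistic |
|---|---|
| QC / normalization | UMI/gene/mito filters; log2(1 + x·10⁴/total) |
| Markers | Wilcoxon rank-sum + Bonferroni, FC ≥ 2, detection diff ≥ 20% |
| Tissue preference | Ro/e = observed/expected cells, 2×2 chi-squared |
| Cluster similarity | Σ shared-marker FC products; ridge-classifier transfer |
| Exhaustion | k-means on effector genes, KM1..KMk ordered by effector loss |
| Interactions | intensity = mean(lig)·mean(rec); cluster-tag permutation test |
| Deconvolution | subtype abundance = Σ marker log-TPM; TLS scores; k-means TME subtypes |
| Robustness | NMI under down-sampling (1/2–1/5 × 100) and leave-one-patient-out |

The core interaction statistic: for sender cluster L and receiver R and
an L-R pair (g_l, g_r),

    I = mean(normalized g_l | L) × mean(normalized g_r | R)

with p from 1000 joint permutations of cluster tags, Bonferroni
adjustment per cluster pair, and significance at I > 1, adjusted
p < 0.01; pairs with either mean < 1 (log2 normalized counts) are
filtered. Ro/e > 1 marks tissue enrichment; NMI(A,B) =
I(A;B)/mean(H(A),H(B)).

## Worked example

```r
library(tmetools)

cl <- data.frame(name = c("CTL", "Treg", "Mac"),
                 lineage = c("T/NK", "T/NK", "myeloid"), n_cells = 300)
cl$tissue_probs <- list(c(NTL = .7, PT = .3, PVTT = 0, MLN = 0),
                        c(NTL = .2, PT = .8, PVTT = 0, MLN = 0),
                        c(NTL = .4, PT = .6, PVTT = 0, MLN = 0))
mk <- data.frame(cluster = rep(c("CTL", "Treg", "Mac"), each = 5),
                 gene = sprintf("G%04d", 1:15), fold_change = 4)
lr <- data.frame(ligand = "G0021", receptor = "G0022",
                 source_cluster = "Mac", target_cluster = "CTL", effect = 4)
cfg <- sim_config(n_genes = 100, clusters = cl, markers = mk,
                  baseline_mean = 1, lr_plants = lr, seed = 7)
sim <- simulate_cells(cfg)
mat <- normalize_counts(qc_filter(sim$mat,
         qc_thresholds(min_umi = 50, min_genes = 20))$mat)
ann <- sim$ann[sim$ann$cell_id %in% mat$cell_ids, ]

head(find_markers(mat, ann, "CTL"), 3)
#>       cluster  gene fold_change pct_in pct_out    p_raw    p_adj
#> G0004     CTL G0004        4.58  0.817   0.468 2.33e-53 2.33e-51
#> G0005     CTL G0005        4.27  0.663   0.285 1.57e-38 1.57e-36
#> G0003     CTL G0003        4.15  0.747   0.355 7.25e-46 7.25e-44
```

The planted fold-4 markers come back with fold changes near 4, near-total
detection inside the cluster, and Bonferroni-adjusted p-values far below
0.01. Tissue preference recovers the planted NTL enrichment of CTLs
(70% configured vs 43% margin → Ro/e 1.6):

```r
head(preference_flags(ro_e_table(ann)), 4)
#>   cluster tissue observed expected  ro_e    chi2        p preference
#> 1     CTL    NTL      209      130 1.604 125.934 3.18e-29   enriched
#> 2     CTL     PT       91      170 0.536 125.934 3.18e-29   depleted
#> 3     Mac    NTL      125      130 0.959   0.579 4.47e-01    neutral
#> 4     Mac     PT      175      170 1.031   0.579 4.47e-01    neutral
```

The permutation test calls the planted Mac→CTL axis with the largest
intensity (59.0, p_adj < 0.001); echoes through other cluster pairs that
share the shifted genes are weaker:

```r
pairs <- lr_pair_set(c("G0021", "G0031"), c("G0022", "G0032"))
res <- lr_permutation_test(mat, ann, pairs, n_perm = 1000, seed = 7)
subset(res, significant & cluster_l == "Mac" & cluster_r == "CTL")
#>   cluster_l cluster_r ligand receptor intensity p_raw p_adj significant
#> 7       Mac       CTL  G0021    G0022        59     0     0        TRUE
```

An end-to-end run over all stages, writing TSV artifacts and a JSON
manifest:

```r
run_pipeline(list(seed = 1L), "artifacts/")
```

or from the shell: `Rscript inst/cli/tmetools.R pipeline --out artifacts
--seed 1`.

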