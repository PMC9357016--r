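#' Clusters eligible for interaction analysis in a tissue
#'
#' A cluster is eligible when it has at least `min_cells` cells in the
#' tissue and makes up at least `min_fraction` of the base population
#' there. The base population defaults to cells of the same lineage in
#' the tissue (`fraction_base = "lineage"`); `"all"` uses every cell in
#' the tissue; `min_fraction = 0` disables the fraction rule.
#'
#' @param ann annotation data.frame.
#' @param tissue tissue label.
#' @param min_cells minimum cluster size in the tissue.
#' @param min_fraction minimum fraction of the base population.
#' @param fraction_base "lineage" or "all".
#' @return character vector of eligible cluster labels.
#' @export
eligible_clusters <- function(ann, tissue, min_cells = 5,
                              min_fraction = 0.10,
                              fraction_base = c("lineage", "all")) {
  fraction_base <- match.arg(fraction_base)
  if (!tissue %in% ann$tissue) stop("unknown tissue: ", tissue)
  sub <- ann[ann$tissue == tissue, , drop = FALSE]
  sizes <- table(sub$cluster)
  frac <- if (fraction_base == "all") {
    sizes / nrow(sub)
  } else {
    base <- table(sub$lineage)
    lin_of <- tapply(sub$lineage, sub$cluster, function(l) l[1])
    sizes / as.numeric(base[lin_of[names(sizes)]])
  }
  names(sizes)[sizes >= min_cells & frac >= min_fraction]
}

#' Interaction intensity of one L-R pair between two clusters
#'
#' Intensity = mean normalized ligand expression in the sender cluster
#' times mean normalized receptor expression in the receiver cluster.
#' When either mean falls below `min_expr` (the log2-normalized-counts
#' floor of 1) the pair is filtered: NA is returned rather than a
#' testable intensity.
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param ann matching annotation.
#' @param cluster_l,cluster_r sender and receiver cluster labels.
#' @param ligand,receptor gene ids.
#' @param min_expr expression floor on both means.
#' @return intensity, or NA when expression-filtered.
#' @export
interaction_intensity <- function(mat, ann, cluster_l, cluster_r, ligand,
                                  receptor, min_expr = 1) {
  ann <- match_annotation(mat, ann)
  norm <- norm_layer(mat)
  for (g in c(ligand, receptor)) {
    if (!g %in% mat$gene_ids) stop("gene absent: ", g)
  }
  il <- ann$cluster == cluster_l
  ir <- ann$cluster == cluster_r
  if (!any(il)) stop("empty cluster: ", cluster_l)
  if (!any(ir)) stop("empty cluster: ", cluster_r)
  ml <- mean(norm[ligand, il])
  mr <- mean(norm[receptor, ir])
  if (ml < min_expr || mr < min_expr) return(NA_real_)
  ml * mr
}

#' Permutation test for ligand-receptor interactions
#'
#' For every ordered pair of eligible clusters and every L-R pair,
#' computes the product-of-means intensity, then permutes the cluster
#' tags of all cells `n_perm` times, recomputing all intensities each
#' time. The raw p-value is the fraction of permutations whose intensity
#' reaches (`tail = "ge"`, default) or strictly exceeds (`tail = "gt"`)
#' the observed one; Bonferroni adjustment is applied within each cluster
#' pair across its tested L-R pairs (`family = "cluster_pair"`) or over
#' all tests (`"global"`). A pair is significant when intensity >
#' `intensity_cut` and adjusted p < `alpha`. Pairs whose ligand or
#' receptor mean falls below `min_expr` in the respective cluster are
#' expression-filtered and excluded from testing and from the Bonferroni
#' family.
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param ann matching annotation.
#' @param pairs L-R pair table (columns ligand, receptor).
#' @param clusters clusters to test (default: all in `ann`; apply
#'   [eligible_clusters()] upstream for the tissue-specific rule).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param tail "ge" (default) or "gt" (strict, can yield p = 0).
#' @param add_one use the small-sample estimator (count+1)/(n_perm+1).
#' @param min_expr expression floor.
#' @param intensity_cut,alpha significance rule.
#' @param family Bonferroni family.
#' @param include_self include sender == receiver cluster pairs.
#' @return data.frame(cluster_l, cluster_r, ligand, receptor, intensity,
#'   p_raw, p_adj, significant), one row per tested combination.
#' @export
lr_permutation_test <- function(mat, ann, pairs, clusters = NULL,
                                n_perm = 1000, seed = 1L,
                                tail = c("ge", "gt"), add_one = FALSE,
                                min_expr = 1, intensity_cut = 1,
                                alpha = 0.01,
                                family = c("cluster_pair", "global"),
                                include_self = TRUE) {
  tail <- match.arg(tail)
  family <- match.arg(family)
  if (n_perm < 1) stop("n_perm must be >= 1")
  ann <- match_annotation(mat, ann)
  if (is.null(clusters)) clusters <- sort(unique(ann$cluster))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  keep <- ann$cluster %in% clusters
  labels <- factor(ann$cluster[keep], levels = clusters)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  miss <- setdiff(genes, mat$gene_ids)
  if (length(miss)) stop("L-R genes absent from matrix: ",
                         paste(miss, collapse = ", "))
  expr <- as.matrix(norm_layer(mat)[genes, keep, drop = FALSE])
  k <- length(clusters)
  sizes <- as.numeric(table(labels))
  if (any(sizes == 0)) stop("requested cluster has no cells")
  group_means <- function(lab) {
    ind <- matrix(0, length(lab), k)
    ind[cbind(seq_along(lab), as.integer(lab))] <- 1
    sweep(expr %*% ind, 2, sizes, "/")
  }
  m_obs <- group_means(labels)
  li <- match(pairs$ligand, genes)
  ri <- match(pairs$receptor, genes)
  np <- nrow(pairs)
  # observed intensities: np x k x k (sender x receiver)
  obs <- array(NA_real_, c(np, k, k))
  for (p in seq_len(np)) obs[p, , ] <- outer(m_obs[li[p], ], m_obs[ri[p], ])
  # expression filter mask on observed means
  filt <- array(FALSE, c(np, k, k))
  for (p in seq_len(np)) {
    filt[p, , ] <- outer(m_obs[li[p], ] < min_expr,
                         m_obs[ri[p], ] < min_expr, `|`)
  }
  count <- array(0L, c(np, k, k))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      mp <- group_means(sample(labels))
      for (p in seq_len(np)) {
        ip <- outer(mp[li[p], ], mp[ri[p], ])
        hit <- if (tail == "ge") ip >= obs[p, , ] else ip > obs[p, , ]
        count[p, , ] <- count[p, , ] + hit
      }
    }
  })
  p_raw <- if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  grid <- expand.grid(pair = seq_len(np), l = seq_len(k), r = seq_len(k),
                      KEEP.OUT.ATTRS = FALSE)
  if (!include_self) grid <- grid[grid$l != grid$r, , drop = FALSE]
  idx <- as.matrix(grid)
  res <- data.frame(cluster_l = clusters[grid$l],
                    cluster_r = clusters[grid$r],
                    ligand = pairs$ligand[grid$pair],
                    receptor = pairs$receptor[grid$pair],
                    intensity = obs[idx], p_raw = p_raw[idx],
                    filtered = filt[idx], stringsAsFactors = FALSE)
  res <- res[order(res$cluster_l, res$cluster_r, -res$intensity), ]
  tested <- !res$filtered
  res$p_raw[!tested] <- NA_real_
  m_family <- if (family == "global") {
    rep(sum(tested), nrow(res))
  } else {
    key <- paste(res$cluster_l, res$cluster_r, sep = "\r")
    as.numeric(stats::ave(tested, key, FUN = sum))
  }
  res$p_adj <- ifelse(tested, pmin(1, res$p_raw * m_family), NA_real_)
  res$significant <- tested & res$intensity > intensity_cut &
    res$p_adj < alpha
  res$filtered <- NULL                # filtered rows kept with NA p-values
  rownames(res) <- NULL
  res
}

#' Cellular communication network between clusters
#'
#' Aggregates significant L-R pairs per ordered cluster pair into a
#' directed edge weight: the number of significant pairs weighted by the
#' clusters' cell numbers in the tissue. Weighting modes:
#' `cells_product` = count x (n_l x n_r) / N^2, `cells_sum` = count x
#' (n_l + n_r) / N, `count` = raw count.
#'
#' @param result output of [lr_permutation_test()].
#' @param ann annotation data.frame.
#' @param tissue tissue the result was computed in (sizes are taken from
#'   this tissue's cells).
#' @param weighting weighting mode.
#' @return data.frame(cluster_l, cluster_r, n_significant, weight,
#'   tissue), rows with at least one significant pair.
#' @export
communication_network <- function(result, ann, tissue,
                                  weighting = c("cells_product",
                                                "cells_sum", "count")) {
  weighting <- match.arg(weighting)
  sub <- ann[ann$tissue == tissue, , drop = FALSE]
  sizes <- table(sub$cluster)
  n_total <- nrow(sub)
  sig <- result[result$significant, , drop = FALSE]
  if (!nrow(sig)) {
    return(data.frame(cluster_l = character(), cluster_r = character(),
                      n_significant = integer(), weight = numeric(),
                      tissue = character(), stringsAsFactors = FALSE))
  }
  agg <- stats::aggregate(list(n_significant = sig$significant),
                          by = list(cluster_l = sig$cluster_l,
                                    cluster_r = sig$cluster_r), FUN = sum)
  n_l <- as.numeric(sizes[agg$cluster_l])
  n_r <- as.numeric(sizes[agg$cluster_r])
  n_l[is.na(n_l)] <- 0; n_r[is.na(n_r)] <- 0
  agg$weight <- switch(weighting,
    cells_product = agg$n_significant * (n_l * n_r) / n_total^2,
    cells_sum = agg$n_significant * (n_l + n_r) / n_total,
    count = agg$n_significant)
  agg$tissue <- tissue
  agg
}

#' Per-cell pathway activity scores
#'
#' Generic stand-in for per-cell gene-set scoring: for each set, the mean
#' across member genes of the per-gene z-score (normalized expression
#' standardized across the scored cells). Genes with zero variance
#' contribute 0.
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param gene_sets named list of gene id vectors.
#' @param cells cell ids to score (default all).
#' @return cells x pathways matrix.
#' @export
pathway_activity <- function(mat, gene_sets, cells = NULL) {
  if (is.null(cells)) cells <- mat$cell_ids
  ci <- match(cells, mat$cell_ids)
  if (anyNA(ci)) stop("unknown cell ids")
  norm <- norm_layer(mat)
  out <- matrix(NA_real_, length(cells), length(gene_sets),
                dimnames = list(cells, names(gene_sets)))
  for (s in seq_along(gene_sets)) {
    g <- intersect(gene_sets[[s]], mat$gene_ids)
    if (!length(g)) stop("gene set has no genes in matrix: ",
                         names(gene_sets)[s])
    x <- as.matrix(norm[g, ci, drop = FALSE])
    mu <- rowMeans(x)
    sd_ <- apply(x, 1, stats::sd)
    z <- (x - mu) / ifelse(sd_ > 0, sd_, Inf)
    out[, s] <- colMeans(z)
  }
  out
}

#' Ligand-pathway bipartite correlation network
#'
#' Spearman correlation between each ligand's normalized expression and
#' each pathway activity score across a cell subset; an edge is reported
#' when p < `alpha`. Constant ligand vectors are skipped with a warning.
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param cells cell ids (e.g. the malignant hepatocyte subset).
#' @param ligands ligand gene ids.
#' @param pathway_scores cells x pathways matrix ([pathway_activity()]
#'   output or an external score table) indexed by the same cells.
#' @param alpha edge significance cut.
#' @return data.frame(ligand, pathway, rho, p, edge).
#' @export
ligand_pathway_network <- function(mat, cells, ligands, pathway_scores,
                                   alpha = 0.01) {
  ci <- match(cells, mat$cell_ids)
  if (anyNA(ci)) stop("unknown cell ids")
  if (!all(cells %in% rownames(pathway_scores))) {
    stop("pathway_scores must be indexed by the same cells")
  }
  ps <- pathway_scores[cells, , drop = FALSE]
  norm <- norm_layer(mat)
  out <- list()
  for (lg in ligands) {
    if (!lg %in% mat$gene_ids) stop("ligand absent: ", lg)
    x <- as.numeric(norm[lg, ci])
    if (stats::sd(x) == 0) {
      warning("constant ligand vector, skipping: ", lg)
      next
    }
    for (pw in colnames(ps)) {
      ct <- suppressWarnings(
        stats::cor.test(x, ps[, pw], method = "spearman", exact = FALSE))
      out[[length(out) + 1]] <- data.frame(
        ligand = lg, pathway = pw, rho = unname(ct$estimate),
        p = ct$p.value, edge = ct$p.value < alpha,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(ligand = character(), pathway = character(),
                      rho = numeric(), p = numeric(), edge = logical()))
  }
  do.call(rbind, out)
}
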