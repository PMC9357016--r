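#' Identify marker genes of a cluster
#'
#' Three-criterion rule: a gene is a marker of a cluster when (i) its
#' two-sided Wilcoxon rank-sum p-value (in-cluster vs all other cells on
#' the normalized layer), Bonferroni-adjusted over ALL genes in the
#' matrix, is below `alpha`; (ii) its linear-scale mean expression is at
#' least `min_fc`-fold higher in the cluster; and (iii) the fraction of
#' cells detecting it (normalized value > 0) is at least `min_pct_diff`
#' higher in the cluster. Output sorted by fold change, descending.
#'
#' Fold change is computed on the linear scale as
#' `(mean(2^x - 1) + eps) / (mean(2^x - 1) + eps)` with `eps = 1e-9`
#' guarding empty denominators. The rank-sum test uses the normal
#' approximation with tie correction and no continuity correction.
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param ann matching annotation (needs a `cluster` column).
#' @param cluster cluster label to contrast against all remaining cells.
#' @param min_fc minimum linear fold change.
#' @param min_pct_diff minimum detection-percentage difference.
#' @param alpha adjusted-p threshold.
#' @param cells optional subset of cell ids to restrict the contrast to.
#' @return data.frame(cluster, gene, fold_change, pct_in, pct_out, p_raw,
#'   p_adj), one row per admitted gene.
#' @export
find_markers <- function(mat, ann, cluster, min_fc = 2,
                         min_pct_diff = 0.20, alpha = 0.01, cells = NULL) {
  ann <- match_annotation(mat, ann)
  keep <- if (is.null(cells)) rep(TRUE, length(mat$cell_ids))
          else mat$cell_ids %in% cells
  if (!cluster %in% ann$cluster[keep]) {
    stop("unknown cluster label: ", cluster)
  }
  in_group <- keep & ann$cluster == cluster
  out_group <- keep & ann$cluster != cluster
  if (sum(in_group) < 3 || sum(out_group) < 3) {
    stop("need >= 3 cells in the cluster and in its complement")
  }
  marker_contrast(mat, in_group, out_group, cluster, min_fc, min_pct_diff,
                  alpha)
}

# shared core of find_markers / contrast_signature
marker_contrast <- function(mat, in_group, out_group, label, min_fc,
                            min_pct_diff, alpha) {
  norm <- norm_layer(mat)
  n_genes <- nrow(norm)
  x_in <- as.matrix(norm[, in_group, drop = FALSE])
  x_out <- as.matrix(norm[, out_group, drop = FALSE])
  nz_in <- rowSums(x_in > 0)
  nz_out <- rowSums(x_out > 0)
  nonzero <- nz_in + nz_out > 0          # all-zero genes skipped silently
  p_raw <- rep(NA_real_, n_genes)
  p_raw[nonzero] <- rank_sum_p(x_in[nonzero, , drop = FALSE],
                               x_out[nonzero, , drop = FALSE])
  p_adj <- pmin(1, p_raw * n_genes)      # Bonferroni over all genes
  eps <- 1e-9
  mean_lin_in <- rowMeans(2^x_in - 1)
  mean_lin_out <- rowMeans(2^x_out - 1)
  fc <- (mean_lin_in + eps) / (mean_lin_out + eps)
  pct_in <- nz_in / ncol(x_in)
  pct_out <- nz_out / ncol(x_out)
  admit <- nonzero & !is.na(p_adj) & p_adj < alpha & fc >= min_fc &
    (pct_in - pct_out) >= min_pct_diff
  admit[is.na(admit)] <- FALSE
  res <- data.frame(cluster = rep(label, sum(admit)),
                    gene = mat$gene_ids[admit],
                    fold_change = fc[admit], pct_in = pct_in[admit],
                    pct_out = pct_out[admit], p_raw = p_raw[admit],
                    p_adj = p_adj[admit], stringsAsFactors = FALSE)
  res[order(-res$fold_change), , drop = FALSE]
}

# vectorized two-sided Wilcoxon rank-sum (normal approximation, tie
# correction, no continuity correction); rows are genes, x|y column blocks
rank_sum_p <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y); n <- n1 + n2
  xy <- cbind(x, y)
  p <- numeric(nrow(xy))
  for (g in seq_len(nrow(xy))) {
    r <- rank(xy[g, ])
    u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    t_tab <- table(xy[g, ])
    tie_term <- sum(t_tab^3 - t_tab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    p[g] <- if (sigma2 <= 0) 1 else {
      z <- (u - n1 * n2 / 2) / sqrt(sigma2)
      2 * stats::pnorm(-abs(z))
    }
  }
  pmin(p, 1)
}

#' Marker tables for every cluster
#'
#' Convenience loop over [find_markers()] for all clusters with enough
#' cells; clusters with fewer than 3 cells on either side are skipped
#' with a message.
#'
#' @inheritParams find_markers
#' @return combined marker data.frame.
#' @export
find_all_markers <- function(mat, ann, min_fc = 2, min_pct_diff = 0.20,
                             alpha = 0.01) {
  ann_m <- match_annotation(mat, ann)
  out <- list()
  for (cl in sort(unique(ann_m$cluster))) {
    n_in <- sum(ann_m$cluster == cl)
    if (n_in < 3 || length(ann_m$cluster) - n_in < 3) {
      message("skipping cluster ", cl, ": too few cells")
      next
    }
    out[[cl]] <- find_markers(mat, ann, cl, min_fc, min_pct_diff, alpha)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Contrast signature between two groups of clusters
#'
#' Markers of the pooled `group_a` cells against the pooled `group_b`
#' cells under the same three-criterion admission rule; used e.g. to
#' derive genes specific to pro-metastatic versus pro-tumorigenic
#' malignant cell clusters.
#'
#' @inheritParams find_markers
#' @param group_a,group_b disjoint, nonempty sets of cluster labels.
#' @return marker data.frame with `cluster` set to "group_a".
#' @export
contrast_signature <- function(mat, ann, group_a, group_b, min_fc = 2,
                               min_pct_diff = 0.20, alpha = 0.01) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (length(intersect(group_a, group_b))) {
    stop("group_a and group_b overlap")
  }
  ann <- match_annotation(mat, ann)
  in_group <- ann$cluster %in% group_a
  out_group <- ann$cluster %in% group_b
  if (sum(in_group) < 3 || sum(out_group) < 3) {
    stop("need >= 3 cells per pooled group")
  }
  marker_contrast(mat, in_group, out_group, "group_a", min_fc,
                  min_pct_diff, alpha)
}
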