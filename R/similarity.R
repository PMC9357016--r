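#' Weighted shared-marker fold-change similarity
#'
#' For each (query cluster, reference cluster) pair, multiplies the linear
#' fold changes of their shared marker genes and sums the products:
#' S[q, r] = sum over shared g of FC_q(g) * FC_r(g). Designed for
#' comparing against external datasets where only marker tables are
#' published. Fold changes are capped at `fc_cap` so a single
#' near-zero-denominator gene cannot dominate the sum.
#'
#' @param markers_q,markers_r marker tables (columns cluster, gene,
#'   fold_change) for the query and reference datasets.
#' @param fc_cap ceiling applied to fold changes before multiplying.
#' @return matrix (query clusters x reference clusters) with attribute
#'   `method = "weighted_fc"`.
#' @export
weighted_fc_similarity <- function(markers_q, markers_r, fc_cap = 100) {
  for (m in list(markers_q, markers_r)) {
    stopifnot(all(c("cluster", "gene", "fold_change") %in% names(m)))
    if (anyDuplicated(paste(m$cluster, m$gene, sep = "\r"))) {
      stop("duplicated (cluster, gene) rows in marker table")
    }
  }
  qs <- sort(unique(markers_q$cluster))
  rs <- sort(unique(markers_r$cluster))
  s <- matrix(0, length(qs), length(rs), dimnames = list(qs, rs))
  fq <- pmin(markers_q$fold_change, fc_cap)
  fr <- pmin(markers_r$fold_change, fc_cap)
  for (i in seq_along(qs)) {
    qi <- markers_q$cluster == qs[i]
    for (j in seq_along(rs)) {
      rj <- markers_r$cluster == rs[j]
      shared <- intersect(markers_q$gene[qi], markers_r$gene[rj])
      if (length(shared)) {
        s[i, j] <- sum(fq[qi][match(shared, markers_q$gene[qi])] *
                         fr[rj][match(shared, markers_r$gene[rj])])
      }
    }
  }
  attr(s, "method") <- "weighted_fc"
  s
}

#' Classifier-transfer cluster similarity
#'
#' Trains a ridge-penalized multinomial logistic regression to predict
#' reference cluster labels from normalized expression of `feature_genes`,
#' then scores each query cluster as the mean predicted probability of
#' each reference class over its cells. Rows sum to 1 (softmax).
#'
#' @param reference,query list(mat = ExpressionMatrix with normalized
#'   layer, ann = annotation).
#' @param feature_genes genes used as features; default: union of top
#'   `top_n` reference markers per cluster.
#' @param lambda ridge penalty (fixed; no cross-validation so results are
#'   deterministic).
#' @param top_n markers per reference cluster when deriving features.
#' @return matrix (query clusters x reference clusters), rows summing to
#'   1, attribute `method = "classifier"`.
#' @export
classifier_similarity <- function(reference, query, feature_genes = NULL,
                                  lambda = 0.01, top_n = 50) {
  ref_ann <- match_annotation(reference$mat, reference$ann)
  qry_ann <- match_annotation(query$mat, query$ann)
  if (length(unique(ref_ann$cluster)) < 2) {
    stop("reference needs >= 2 clusters")
  }
  if (is.null(feature_genes)) {
    mk <- find_all_markers(reference$mat, reference$ann)
    feature_genes <- unique(unlist(lapply(split(mk, mk$cluster), function(d)
      utils::head(d$gene[order(-d$fold_change)], top_n))))
    feature_genes <- intersect(feature_genes, query$mat$gene_ids)
    if (!length(feature_genes)) stop("no shared feature genes")
  } else {
    miss_r <- setdiff(feature_genes, reference$mat$gene_ids)
    miss_q <- setdiff(feature_genes, query$mat$gene_ids)
    if (length(c(miss_r, miss_q))) {
      stop("feature genes missing: ",
           paste(unique(c(miss_r, miss_q)), collapse = ", "))
    }
  }
  xr <- t(as.matrix(norm_layer(reference$mat)[feature_genes, , drop = FALSE]))
  xq <- t(as.matrix(norm_layer(query$mat)[feature_genes, , drop = FALSE]))
  if (ncol(xr) == 1) {            # glmnet needs >= 2 columns
    xr <- cbind(xr, 0)
    xq <- cbind(xq, 0)
  }
  yr <- factor(ref_ann$cluster)
  fit <- glmnet::glmnet(xr, yr, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  prob <- drop(stats::predict(fit, newx = xq, type = "response"))
  qs <- sort(unique(qry_ann$cluster))
  s <- t(vapply(qs, function(q) {
    colMeans(prob[qry_ann$cluster == q, , drop = FALSE])
  }, numeric(ncol(prob))))
  rownames(s) <- qs
  attr(s, "method") <- "classifier"
  s
}
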