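#' Default exhaustion and effector gene sets
#'
#' The exhaustion set is the canonical T-cell exhaustion marker panel
#' (CTLA4, PDCD1, LAG3, CD27, CD52, ICOS); the effector set is a
#' conventional cytotoxic panel and should be overridden with the
#' dataset's own effector molecules where known.
#' @export
EXHAUSTION_GENES <- c("CTLA4", "PDCD1", "LAG3", "CD27", "CD52", "ICOS")

#' @rdname EXHAUSTION_GENES
#' @export
EFFECTOR_GENES <- c("GZMB", "PRF1", "GNLY", "IFNG", "NKG7")

#' K-means subclustering of CTLs by effector-molecule expression
#'
#' Partitions a cytotoxic T-cell subset into `k` subclusters by k-means on
#' the normalized effector-gene submatrix, then relabels the subclusters
#' KM1..KMk in decreasing order of mean effector expression, so the
#' sequence KM1 -> KMk traces a continuous loss of effector molecules.
#' Ties in mean effector score are broken by original k-means cluster
#' index.
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param ann matching annotation.
#' @param cells cell ids of the CTL subset (default: all cells).
#' @param effector_genes effector molecule gene set.
#' @param k number of subclusters.
#' @param n_init random restarts of k-means.
#' @param seed integer seed (labels are deterministic given it).
#' @return list(labels = named KM labels per cell, summary = per-subcluster
#'   data.frame(subcluster, n_cells, effector_score, exhaustion_score),
#'   cells, effector_genes) of class `exhaustion_result`.
#' @export
kmeans_states <- function(mat, ann, cells = NULL,
                          effector_genes = EFFECTOR_GENES, k = 5,
                          n_init = 25, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  if (!length(effector_genes)) stop("empty effector gene set")
  miss <- setdiff(effector_genes, mat$gene_ids)
  if (length(miss)) stop("effector genes absent: ",
                         paste(miss, collapse = ", "))
  if (is.null(cells)) cells <- mat$cell_ids
  ci <- match(cells, mat$cell_ids)
  if (anyNA(ci)) stop("unknown cell ids in CTL subset")
  if (length(cells) < k) stop("fewer cells than k")
  x <- t(as.matrix(norm_layer(mat)[effector_genes, ci, drop = FALSE]))
  k_eff <- min(k, nrow(unique(x)))
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(x, centers = k_eff, nstart = n_init, iter.max = 100,
                  algorithm = if (k_eff < nrow(x)) "Hartigan-Wong"
                              else "Lloyd")))
  eff_mean <- rowMeans(km$centers)
  ord <- order(-eff_mean, seq_along(eff_mean))   # tie-break: center index
  new_label <- integer(length(eff_mean))
  new_label[ord] <- seq_along(ord)
  labels <- paste0("KM", new_label[km$cluster])
  names(labels) <- cells
  exh_present <- intersect(EXHAUSTION_GENES, mat$gene_ids)
  exh_mat <- if (length(exh_present)) {
    as.matrix(norm_layer(mat)[exh_present, ci, drop = FALSE])
  }
  lev <- paste0("KM", seq_along(ord))
  summary <- data.frame(
    subcluster = lev,
    n_cells = as.integer(table(factor(labels, levels = lev))),
    effector_score = eff_mean[ord],
    exhaustion_score = if (is.null(exh_mat)) NA_real_ else
      vapply(lev, function(l) mean(exh_mat[, labels == l, drop = FALSE]),
             0),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(labels = labels, summary = summary, cells = cells,
                 effector_genes = effector_genes),
            class = "exhaustion_result")
}

#' Flag exhausted and pre-exhausted CTL subclusters
#'
#' The lowest-effector subcluster (KMk) is flagged exhausted. The
#' next-lowest (KM(k-1)) is flagged pre-exhausted iff the fraction of its
#' marker genes (computed against the rest of the CTLs with
#' [find_markers()]) that also appear among the exhausted subcluster's
#' markers reaches `overlap_threshold` — operationalizing "shares a high
#' portion of signature genes" as asymmetric containment. With k = 2 no
#' pre-exhausted state is ever assigned.
#'
#' @param result an `exhaustion_result` from [kmeans_states()].
#' @param mat,ann the data the result was computed on.
#' @param overlap_threshold containment fraction required (default 0.5).
#' @param marker_args list of overrides passed to [find_markers()].
#' @return the result with `summary$state` filled and `overlap` (the
#'   containment fraction of the pre-exhausted candidate, NA when k = 2).
#' @export
flag_states <- function(result, mat, ann, overlap_threshold = 0.5,
                        marker_args = list()) {
  stopifnot(inherits(result, "exhaustion_result"))
  k <- nrow(result$summary)
  lev <- result$summary$subcluster
  states <- rep("non_exhausted", k)
  states[k] <- "exhausted"
  overlap <- NA_real_
  if (k > 2) {
    sub_ann <- data.frame(cell_id = result$cells,
                          cluster = unname(result$labels),
                          tissue = "PT", patient = "P1", lineage = "T/NK",
                          stringsAsFactors = FALSE)
    sub_idx <- match(result$cells, mat$cell_ids)
    sub_mat <- expression_matrix(
      mat$counts[, sub_idx, drop = FALSE], gene_ids = mat$gene_ids,
      cell_ids = result$cells,
      normalized = norm_layer(mat)[, sub_idx, drop = FALSE])
    # subclusters too small to contrast contribute no markers
    mk <- function(cl) tryCatch(
      do.call(find_markers, c(list(sub_mat, sub_ann, cl), marker_args))$gene,
      error = function(e) character(0))
    exhausted_markers <- mk(lev[k])
    cand_markers <- mk(lev[k - 1])
    overlap <- if (length(cand_markers)) {
      length(intersect(cand_markers, exhausted_markers)) /
        length(cand_markers)
    } else {
      0
    }
    if (overlap >= overlap_threshold) states[k - 1] <- "pre_exhausted"
  }
  result$summary$state <- states
  result$overlap <- overlap
  result
}

#' @export
print.exhaustion_result <- function(x, ...) {
  cat("CTL exhaustion subclustering (", length(x$cells), " cells)\n",
      sep = "")
  print(x$summary)
  invisible(x)
}
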