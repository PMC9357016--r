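#' Marker-sum abundance scores from bulk expression
#'
#' The abundance of a cell subtype in a bulk sample is the sum of
#' log-transformed TPM of its marker genes: score[s, j] =
#' sum over g in markers(s) of logTPM[g, j]. Marker genes absent from the
#' cohort are skipped and reported.
#'
#' @param expr genes x samples log-TPM matrix.
#' @param marker_sets named list mapping subtype -> marker gene ids.
#' @return subtypes x samples matrix with attribute `missing_genes`
#'   (named list) and `layer = "absolute"`.
#' @export
abundance_scores <- function(expr, marker_sets) {
  stopifnot(is.list(marker_sets), !is.null(names(marker_sets)))
  out <- matrix(0, length(marker_sets), ncol(expr),
                dimnames = list(names(marker_sets), colnames(expr)))
  missing <- list()
  for (s in names(marker_sets)) {
    g <- intersect(marker_sets[[s]], rownames(expr))
    if (!length(g)) stop("subtype with no marker genes in cohort: ", s)
    dropped <- setdiff(marker_sets[[s]], g)
    if (length(dropped)) missing[[s]] <- dropped
    out[s, ] <- colSums(expr[g, , drop = FALSE])
  }
  attr(out, "missing_genes") <- missing
  attr(out, "layer") <- "absolute"
  out
}

#' Normalize abundances over patient-shared subtypes
#'
#' Divides each subtype's absolute abundance by the per-sample sum of the
#' abundances of all patient-shared immune/stromal subtypes, so normalized
#' columns (restricted to `shared_subtypes`) sum to 1.
#'
#' @param abs_scores absolute abundance matrix from [abundance_scores()].
#' @param shared_subtypes subtypes forming the denominator (default: all
#'   rows).
#' @return normalized matrix over `shared_subtypes`, attribute
#'   `layer = "normalized"`.
#' @export
normalize_abundance <- function(abs_scores, shared_subtypes = NULL) {
  if (is.null(shared_subtypes)) shared_subtypes <- rownames(abs_scores)
  if (!length(shared_subtypes)) stop("shared_subtypes is empty")
  miss <- setdiff(shared_subtypes, rownames(abs_scores))
  if (length(miss)) stop("unknown subtypes: ", paste(miss, collapse = ", "))
  sub <- abs_scores[shared_subtypes, , drop = FALSE]
  denom <- colSums(sub)
  if (any(denom <= 0)) {
    stop("zero abundance denominator in sample(s): ",
         paste(colnames(sub)[denom <= 0], collapse = ", "))
  }
  out <- sweep(sub, 2, denom, "/")
  attr(out, "layer") <- "normalized"
  out
}

#' Gene-signature score per bulk sample
#'
#' Marker-sum score over one signature; with the shipped TLS signatures
#' ([TLS_SIGNATURE_9] / [TLS_SIGNATURE_12]) this reproduces tertiary
#' lymphoid structure scoring. Genes absent from the cohort are skipped
#' with a warning.
#'
#' @param expr genes x samples log-TPM matrix.
#' @param gene_set character vector of gene ids.
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, gene_set) {
  g <- intersect(gene_set, rownames(expr))
  if (!length(g)) stop("no signature genes present in cohort")
  if (length(g) < length(gene_set)) {
    warning("signature genes absent from cohort: ",
            paste(setdiff(gene_set, g), collapse = ", "))
  }
  colSums(expr[g, , drop = FALSE])
}

#' Median split into high / low groups
#'
#' Labels a sample "high" when its score exceeds the cohort median;
#' samples exactly at the median go to the group named by `tie`.
#'
#' @param scores named numeric vector.
#' @param tie "low" (default) or "high".
#' @return named character vector of "high"/"low".
#' @export
median_split <- function(scores, tie = c("low", "high")) {
  tie <- match.arg(tie)
  med <- stats::median(scores)
  lab <- ifelse(scores > med, "high",
                ifelse(scores < med, "low", tie))
  stats::setNames(lab, names(scores))
}

#' 9-gene and 12-gene tertiary lymphoid structure signatures
#'
#' Widely used TLS detection signatures: a 9-gene immune cell-specific
#' panel and a 12-gene chemokine panel.
#' @export
TLS_SIGNATURE_9 <- c("CD79B", "CD1D", "CCR6", "LAT", "SKAP1", "CETP",
                     "EIF1AY", "RBP5", "PTGDS")

#' @rdname TLS_SIGNATURE_9
#' @export
TLS_SIGNATURE_12 <- c("CCL2", "CCL3", "CCL4", "CCL5", "CCL8", "CCL18",
                      "CCL19", "CCL21", "CXCL9", "CXCL10", "CXCL11",
                      "CXCL13")

#' Exhausted T-cell abundance in bulk samples
#'
#' Marker-sum score over the canonical exhaustion panel
#' ([EXHAUSTION_GENES]); members absent from the cohort are skipped with
#' a warning.
#'
#' @param expr genes x samples log-TPM matrix.
#' @param genes marker panel override.
#' @return named numeric vector of per-sample scores.
#' @export
exhaustion_abundance <- function(expr, genes = EXHAUSTION_GENES) {
  signature_score(expr, genes)
}

#' Tumor microenvironment subtypes by k-means on abundances
#'
#' Partitions samples by k-means on their (normalized) cell-subtype
#' abundance profiles. Abundances are used as-is (no per-subtype
#' z-scoring) unless `standardize = TRUE`.
#'
#' @param norm_scores subtypes x samples abundance matrix.
#' @param k number of TME subtypes.
#' @param n_init k-means restarts.
#' @param seed integer seed.
#' @param standardize z-score each subtype row first.
#' @return list(labels = named "TME1".."TMEk" per sample, centroids =
#'   subtypes x k matrix in abundance units, withinss = total
#'   within-cluster sum of squares). Subtype numbering is by decreasing
#'   cluster size (ties by centroid order).
#' @export
tme_subtypes <- function(norm_scores, k = 7, n_init = 100, seed = 1L,
                         standardize = FALSE) {
  if (k < 2) stop("k must be >= 2")
  x <- t(norm_scores)
  if (k > nrow(x)) stop("k exceeds number of samples")
  if (standardize) x <- scale(x)
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(x, centers = k, nstart = n_init, iter.max = 100,
                  # Hartigan-Wong refuses the saturated k == n case
                  algorithm = if (k < nrow(x)) "Hartigan-Wong"
                              else "Lloyd")))
  ord <- order(-km$size, seq_len(k))
  relab <- integer(k); relab[ord] <- seq_len(k)
  labels <- stats::setNames(paste0("TME", relab[km$cluster]), rownames(x))
  centroids <- t(km$centers)[, ord, drop = FALSE]
  colnames(centroids) <- paste0("TME", seq_len(k))
  list(labels = labels, centroids = centroids,
       withinss = km$tot.withinss)
}

#' Silhouette-style diagnostic scan over k
#'
#' Mean silhouette width of [tme_subtypes()] partitions for a range of k,
#' as a diagnostic only (no automatic selection is asserted).
#'
#' @param norm_scores subtypes x samples matrix.
#' @param ks candidate k values.
#' @param seed integer seed.
#' @return data.frame(k, mean_silhouette).
#' @export
tme_k_scan <- function(norm_scores, ks = 2:10, seed = 1L) {
  x <- t(norm_scores)
  d <- as.matrix(stats::dist(x))
  res <- lapply(ks, function(k) {
    if (k > nrow(x) - 1) return(NULL)
    lab <- tme_subtypes(norm_scores, k = k, seed = seed)$labels
    sil <- vapply(seq_len(nrow(x)), function(i) {
      own <- lab == lab[i]
      a <- mean(d[i, own & seq_len(nrow(x)) != i])
      b <- min(vapply(setdiff(unique(lab), lab[i]),
                      function(l) mean(d[i, lab == l]), 0))
      if (is.nan(a)) 0 else (b - a) / max(a, b)
    }, 0)
    data.frame(k = k, mean_silhouette = mean(sil))
  })
  do.call(rbind, res)
}
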