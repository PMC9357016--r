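#' Normalized mutual information between two labelings
#'
#' NMI = I(A;B) / mean(H(A), H(B)) with natural logs; 1 for identical
#' partitions (up to relabeling), near 0 for independent ones. When both
#' labelings are constant the partitions are identical and 1 is returned;
#' when exactly one is constant, 0.
#'
#' @param a,b label vectors of equal length.
#' @param normalization "mean" (arithmetic, default), "min", "max" or
#'   "geometric" entropy normalization.
#' @return NMI in [0, 1].
#' @export
nmi <- function(a, b, normalization = c("mean", "min", "max",
                                        "geometric")) {
  normalization <- match.arg(normalization)
  if (length(a) != length(b)) stop("label vectors differ in length")
  if (!length(a)) stop("empty label vectors")
  tab <- table(a, b)
  # identical partitions up to relabeling: exactly one nonzero cell per
  # row and column; return 1 exactly, bypassing float round-off
  if (nrow(tab) == ncol(tab) &&
        all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)) {
    return(1)
  }
  n <- sum(tab)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  ha <- -sum(pi_[pi_ > 0] * log(pi_[pi_ > 0]))
  hb <- -sum(pj_[pj_ > 0] * log(pj_[pj_ > 0]))
  if (ha == 0 && hb == 0) return(1)
  denom <- switch(normalization,
                  mean = (ha + hb) / 2,
                  min = min(ha, hb),
                  max = max(ha, hb),
                  geometric = sqrt(ha * hb))
  if (denom == 0) return(0)
  max(0, min(1, mi / denom))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between partitions; 1 for identical
#' partitions, ~0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return ARI (can be slightly negative under anti-correlation).
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expect <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expect) return(1)
  (sum_ij - expect) / (maxi - expect)
}

#' Clustering robustness under down-sampling
#'
#' Repeatedly samples cells without replacement at each fraction,
#' re-clusters them with the supplied callback, and scores the resulting
#' labels against the benchmark labels (restricted to the sampled cells)
#' by NMI. Replicate seeds are derived from `seed` via a counter, so the
#' sampling stream is reproducible.
#'
#' @param mat ExpressionMatrix (passed through to the callback).
#' @param benchmark_labels named label vector covering all cells.
#' @param cluster_fn callback `function(mat, cells, seed)` returning a
#'   label vector for `cells` (see [make_kmeans_callback()]).
#' @param fractions sampling fractions in (0, 1].
#' @param n_reps replicates per fraction.
#' @param seed master seed.
#' @return data.frame(protocol, condition, replicate, n_cells, nmi).
#' @export
downsample_robustness <- function(mat, benchmark_labels, cluster_fn,
                                  fractions = c(1 / 2, 1 / 3, 1 / 4,
                                                1 / 5),
                                  n_reps = 100, seed = 1L) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  all_cells <- mat$cell_ids
  if (!all(all_cells %in% names(benchmark_labels))) {
    stop("benchmark labels must cover all cells")
  }
  rows <- list()
  ctr <- 0L
  for (f in fractions) {
    for (r in seq_len(n_reps)) {
      ctr <- ctr + 1L
      rep_seed <- seed + ctr
      cells <- with_seed(rep_seed, sample(all_cells,
                                          max(1, round(f * length(all_cells)))))
      lab <- cluster_fn(mat, cells, rep_seed)
      rows[[ctr]] <- data.frame(
        protocol = "downsample", condition = format(f, digits = 4),
        replicate = r, n_cells = length(cells),
        nmi = nmi(lab, benchmark_labels[cells]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Clustering robustness under leave-one-patient-out
#'
#' Holds out one patient at a time, re-clusters the remaining cells with
#' the callback, and scores against the benchmark on the retained cells.
#'
#' @param mat ExpressionMatrix.
#' @param ann matching annotation (needs `patient`).
#' @param benchmark_labels named label vector covering all cells.
#' @param cluster_fn callback as in [downsample_robustness()].
#' @param seed seed forwarded to the callback (one offset per patient).
#' @return data.frame(protocol, condition = held-out patient, replicate,
#'   n_cells, nmi).
#' @export
leave_one_patient_out <- function(mat, ann, benchmark_labels, cluster_fn,
                                  seed = 1L) {
  ann <- match_annotation(mat, ann)
  patients <- sort(unique(ann$patient))
  if (length(patients) < 2) stop("need >= 2 patients")
  rows <- lapply(seq_along(patients), function(i) {
    cells <- mat$cell_ids[ann$patient != patients[i]]
    lab <- cluster_fn(mat, cells, seed + i)
    data.frame(protocol = "leave_one_out", condition = patients[i],
               replicate = 1L, n_cells = length(cells),
               nmi = nmi(lab, benchmark_labels[cells]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Reference k-means clustering callback
#'
#' Ships a simple re-clustering callback for the robustness protocols:
#' k-means on the top principal components of the normalized submatrix of
#' the requested cells (the embedding is recomputed per subset). Graph
#' clustering used on real atlases can be substituted by any callback
#' with the same signature.
#'
#' @param k number of clusters.
#' @param n_pcs principal components retained.
#' @param n_init k-means restarts.
#' @return `function(mat, cells, seed)` returning labels named by cell.
#' @export
make_kmeans_callback <- function(k, n_pcs = 10, n_init = 10) {
  function(mat, cells, seed) {
    ci <- match(cells, mat$cell_ids)
    x <- t(as.matrix(norm_layer(mat)[, ci, drop = FALSE]))
    keep <- which(apply(x, 2, stats::sd) > 0)
    npc <- min(n_pcs, length(keep) - 1, nrow(x) - 1)
    emb <- if (npc >= 2) {
      stats::prcomp(x[, keep, drop = FALSE], rank. = npc,
                    center = TRUE, scale. = FALSE)$x
    } else {
      x
    }
    k_eff <- min(k, nrow(unique(emb)))
    km <- with_seed(seed, suppressWarnings(
      stats::kmeans(emb, centers = k_eff, nstart = n_init,
                    iter.max = 100,
                    algorithm = if (k_eff < nrow(emb)) "Hartigan-Wong"
                                else "Lloyd")))
    stats::setNames(paste0("K", km$cluster), cells)
  }
}

#' Summarize a robustness report
#'
#' @param report output of [downsample_robustness()] or
#'   [leave_one_patient_out()].
#' @return data.frame(protocol, condition, n, mean_nmi, sd_nmi).
#' @export
summarize_robustness <- function(report) {
  agg <- stats::aggregate(report$nmi,
                          by = list(protocol = report$protocol,
                                    condition = report$condition),
                          FUN = function(v) c(n = length(v), mean = mean(v),
                                              sd = stats::sd(v)))
  data.frame(protocol = agg$protocol, condition = agg$condition,
             n = agg$x[, "n"], mean_nmi = agg$x[, "mean"],
             sd_nmi = agg$x[, "sd"], stringsAsFactors = FALSE)
}
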