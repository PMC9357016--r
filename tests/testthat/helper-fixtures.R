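# shared fixture builders; everything generated in code, seeded

# small dense count matrix wrapped as ExpressionMatrix
tiny_mat <- function(counts, genes = NULL, cells = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(counts)))
  cells <- cells %||% sprintf("c%d", seq_len(ncol(counts)))
  expression_matrix(counts, gene_ids = genes, cell_ids = cells)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# annotation with defaults for unneeded factors
make_ann <- function(cell_id, cluster, tissue = "PT", patient = "P1",
                     lineage = "T/NK") {
  data.frame(cell_id = cell_id, cluster = cluster, tissue = tissue,
             patient = patient, lineage = lineage,
             stringsAsFactors = FALSE)
}

# k equal clusters with `n_mk` planted FC markers each, normalized
marker_fixture <- function(n_clusters = 2, n_per = 200, n_genes = 60,
                           n_mk = 5, fc = 4, baseline = 2, seed = 42,
                           dispersion = 2, tissue_probs = NULL,
                           lr_plants = NULL) {
  nm <- paste0("CL", seq_len(n_clusters))
  cl <- data.frame(name = nm, lineage = "T/NK", n_cells = n_per,
                   stringsAsFactors = FALSE)
  if (!is.null(tissue_probs)) cl$tissue_probs <- tissue_probs
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  mk <- do.call(rbind, lapply(seq_len(n_clusters), function(i) {
    data.frame(cluster = nm[i],
               gene = gene_ids[((i - 1) * n_mk + 1):(i * n_mk)],
               fold_change = fc, stringsAsFactors = FALSE)
  }))
  cfg <- sim_config(n_genes = n_genes, clusters = cl, markers = mk,
                    baseline_mean = baseline, dispersion = dispersion,
                    lr_plants = lr_plants, seed = seed)
  sim <- simulate_cells(cfg)
  sim$mat <- normalize_counts(sim$mat)
  sim$config <- cfg
  sim
}

# brute-force three-rule marker oracle built on stats::wilcox.test
oracle_markers <- function(mat, ann, cluster, min_fc = 2,
                           min_pct_diff = 0.20, alpha = 0.01) {
  x <- as.matrix(mat$normalized)
  ann <- ann[match(mat$cell_ids, ann$cell_id), ]
  inn <- ann$cluster == cluster
  admitted <- character(0)
  for (g in seq_len(nrow(x))) {
    xi <- x[g, inn]; xo <- x[g, !inn]
    if (all(c(xi, xo) == 0)) next
    p <- stats::wilcox.test(xi, xo, exact = FALSE,
                            correct = FALSE)$p.value
    p_adj <- min(1, p * nrow(x))
    fc <- (mean(2^xi - 1) + 1e-9) / (mean(2^xo - 1) + 1e-9)
    pct <- mean(xi > 0) - mean(xo > 0)
    if (!is.nan(p_adj) && p_adj < alpha && fc >= min_fc &&
          pct >= min_pct_diff) {
      admitted <- c(admitted, mat$gene_ids[g])
    }
  }
  admitted
}

# gradient world: k states with decreasing effector expression; the two
# lowest states share an exhaustion signature
gradient_fixture <- function(n_states = 5, n_per = 120, seed = 51,
                             effector_fc = c(16, 8, 4, 2, 1),
                             share_signature = TRUE) {
  nm <- paste0("ST", seq_len(n_states))
  cl <- data.frame(name = nm, lineage = "T/NK", n_cells = n_per,
                   stringsAsFactors = FALSE)
  # a broad background keeps the effector block a minor library
  # fraction, so library-size normalization does not saturate the top
  # of the gradient
  gene_ids <- sprintf("G%04d", 1:500)
  eff <- gene_ids[1:12]
  sig <- gene_ids[13:24]  # exhaustion-like signature genes
  mk <- do.call(rbind, c(
    lapply(seq_len(n_states), function(i) {
      data.frame(cluster = nm[i], gene = eff,
                 fold_change = effector_fc[i])
    }),
    list(data.frame(cluster = nm[n_states], gene = sig,
                    fold_change = 30),
         if (share_signature) {
           data.frame(cluster = nm[n_states - 1], gene = sig,
                      fold_change = 30)
         } else {
           data.frame(cluster = nm[n_states - 1],
                      gene = gene_ids[25:36], fold_change = 30)
         })))
  # signature genes are lowly detected at baseline (as exhaustion
  # markers are outside exhausted cells); everything else sits at a
  # dense, well-detected level
  means <- rep(3, 500)
  means[13:36] <- 0.2
  cfg <- sim_config(n_genes = 500, clusters = cl, markers = mk,
                    gene_means = means, dispersion = 20, seed = seed)
  sim <- simulate_cells(cfg)
  sim$mat <- normalize_counts(sim$mat)
  sim$effector <- eff
  sim
}

# brute-force oracle: loop over cells to build the table, then closed-form
# 2x2 chi-square per (cluster, tissue)
oracle_ro_e <- function(ann) {
  clusters <- sort(unique(ann$cluster))
  tissues <- sort(unique(ann$tissue))
  n <- nrow(ann)
  out <- list()
  for (cl in clusters) for (ti in tissues) {
    a <- b <- c_ <- d <- 0
    for (i in seq_len(n)) {
      hit_c <- ann$cluster[i] == cl
      hit_t <- ann$tissue[i] == ti
      if (hit_c && hit_t) a <- a + 1
      else if (hit_c) b <- b + 1
      else if (hit_t) c_ <- c_ + 1
      else d <- d + 1
    }
    expected <- (a + b) * (a + c_) / n
    chi2 <- n * (a * d - b * c_)^2 /
      ((a + b) * (c_ + d) * (a + c_) * (b + d))
    out[[paste(cl, ti)]] <- c(obs = a, expected = expected,
                              ro_e = a / expected, chi2 = chi2)
  }
  out
}
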