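#' Simulation configuration for synthetic single-cell data
#'
#' Describes a stated world for the generator: negative-binomial clustered
#' counts with gene-level log-normal baseline means, planted cluster
#' markers at fixed fold changes, per-cluster tissue/patient composition,
#' and optional planted ligand-receptor co-expression between cluster
#' pairs.
#'
#' @param n_genes number of genes (ids G0001...).
#' @param clusters data.frame with columns name, lineage, n_cells and
#'   optional list-columns tissue_probs, patient_probs (named numeric
#'   vectors summing to 1; defaults: uniform over NTL/PT and patients
#'   P1-P3).
#' @param markers data.frame with columns cluster, gene, fold_change
#'   (>= 1) and optional detection_boost in [0,1] (probability that a
#'   sampled zero in a marker-bearing cell is bumped to one count).
#' @param baseline_mean median of the log-normal distribution of per-gene
#'   NB means.
#' @param baseline_sdlog log-sd of the per-gene baseline means.
#' @param dispersion NB size parameter (smaller = more overdispersed).
#' @param lr_plants data.frame with columns ligand, receptor,
#'   source_cluster, target_cluster, effect (>= 1): the ligand mean is
#'   multiplied by `effect` in the source cluster and the receptor mean in
#'   the target cluster.
#' @param gene_means optional explicit per-gene baseline NB means (length
#'   `n_genes`), replacing the log-normal draw; lets a world state e.g.
#'   lowly-detected marker genes directly.
#' @param seed integer master seed.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_genes, clusters, markers = NULL,
                       baseline_mean = 0.5, baseline_sdlog = 1,
                       dispersion = 2, lr_plants = NULL,
                       gene_means = NULL, seed = 1L) {
  stopifnot(n_genes >= 1, is.data.frame(clusters),
            all(c("name", "lineage", "n_cells") %in% names(clusters)))
  if (anyDuplicated(clusters$name)) stop("duplicate cluster names")
  if (any(clusters$n_cells < 1)) stop("n_cells must be >= 1")
  if (is.null(clusters$tissue_probs)) {
    clusters$tissue_probs <- replicate(nrow(clusters),
      c(NTL = 0.5, PT = 0.5, PVTT = 0, MLN = 0), simplify = FALSE)
  }
  if (is.null(clusters$patient_probs)) {
    clusters$patient_probs <- replicate(nrow(clusters),
      c(P1 = 1 / 3, P2 = 1 / 3, P3 = 1 / 3), simplify = FALSE)
  }
  for (i in seq_len(nrow(clusters))) {
    tp <- clusters$tissue_probs[[i]]
    if (abs(sum(tp) - 1) > 1e-9) stop("tissue_probs must sum to 1")
    if (length(setdiff(names(tp), TISSUE_LEVELS))) {
      stop("tissue_probs names must be drawn from NTL/PT/PVTT/MLN")
    }
    if (abs(sum(clusters$patient_probs[[i]]) - 1) > 1e-9) {
      stop("patient_probs must sum to 1")
    }
  }
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(markers)) {
    stopifnot(all(c("cluster", "gene", "fold_change") %in% names(markers)))
    if (is.null(markers$detection_boost)) markers$detection_boost <- 0
    if (any(markers$fold_change < 1)) stop("fold_change must be >= 1")
    bad <- setdiff(markers$gene, gene_ids)
    if (length(bad)) stop("marker gene not in gene set: ",
                          paste(bad, collapse = ", "))
    if (length(setdiff(markers$cluster, clusters$name))) {
      stop("marker cluster not in cluster set")
    }
  }
  if (!is.null(lr_plants)) {
    need <- c("ligand", "receptor", "source_cluster", "target_cluster",
              "effect")
    stopifnot(all(need %in% names(lr_plants)))
    bad <- setdiff(c(lr_plants$ligand, lr_plants$receptor), gene_ids)
    if (length(bad)) stop("planted L-R gene not in gene set: ",
                          paste(bad, collapse = ", "))
    if (any(lr_plants$effect < 1)) stop("L-R effect must be >= 1")
  }
  if (!is.null(gene_means)) {
    if (length(gene_means) != n_genes || any(gene_means <= 0)) {
      stop("gene_means must be ", n_genes, " positive values")
    }
    gene_means <- stats::setNames(as.numeric(gene_means), gene_ids)
  }
  structure(list(n_genes = n_genes, gene_ids = gene_ids,
                 clusters = clusters, markers = markers,
                 baseline_mean = baseline_mean,
                 baseline_sdlog = baseline_sdlog, dispersion = dispersion,
                 lr_plants = lr_plants, gene_means = gene_means,
                 seed = as.integer(seed)),
            class = "sim_config")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  code
}

#' Simulate clustered single-cell counts with planted ground truth
#'
#' Counts are NB(mean = baseline x planted fold change, size =
#' dispersion); each gene's baseline mean is log-normal across genes and
#' shared by all cells. Tissue and patient labels are drawn independently
#' per cell from the cluster's configured proportions. Identical seeds
#' give bit-identical output.
#'
#' @param config a [sim_config()].
#' @return list(mat = ExpressionMatrix (counts only), ann = annotation
#'   data.frame, truth = list(planted_markers, tissue_enrichment,
#'   planted_lr, gene_means)).
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cl <- config$clusters
  with_seed(config$seed, {
    gene_means <- if (!is.null(config$gene_means)) {
      config$gene_means
    } else {
      stats::setNames(
        stats::rlnorm(config$n_genes,
                      meanlog = log(config$baseline_mean),
                      sdlog = config$baseline_sdlog),
        config$gene_ids)
    }
    blocks <- vector("list", nrow(cl))
    ann_blocks <- vector("list", nrow(cl))
    for (i in seq_len(nrow(cl))) {
      n_c <- cl$n_cells[i]
      mu <- gene_means
      if (!is.null(config$markers)) {
        mk <- config$markers[config$markers$cluster == cl$name[i], ]
        mu[mk$gene] <- mu[mk$gene] * mk$fold_change
      }
      if (!is.null(config$lr_plants)) {
        lp <- config$lr_plants
        lig <- lp$ligand[lp$source_cluster == cl$name[i]]
        rec <- lp$receptor[lp$target_cluster == cl$name[i]]
        eff_l <- lp$effect[lp$source_cluster == cl$name[i]]
        eff_r <- lp$effect[lp$target_cluster == cl$name[i]]
        if (length(lig)) mu[lig] <- mu[lig] * eff_l
        if (length(rec)) mu[rec] <- mu[rec] * eff_r
      }
      m <- matrix(stats::rnbinom(config$n_genes * n_c,
                                 mu = rep(mu, times = n_c),
                                 size = config$dispersion),
                  nrow = config$n_genes)
      if (!is.null(config$markers)) {
        mk <- config$markers[config$markers$cluster == cl$name[i] &
                               config$markers$detection_boost > 0, ]
        for (j in seq_len(nrow(mk))) {
          g <- match(mk$gene[j], config$gene_ids)
          z <- which(m[g, ] == 0)
          if (length(z)) {
            bump <- stats::runif(length(z)) < mk$detection_boost[j]
            m[g, z[bump]] <- 1L
          }
        }
      }
      blocks[[i]] <- m
      tp <- cl$tissue_probs[[i]]
      pp <- cl$patient_probs[[i]]
      ann_blocks[[i]] <- data.frame(
        cluster = cl$name[i],
        tissue = sample(names(tp), n_c, replace = TRUE, prob = tp),
        patient = sample(names(pp), n_c, replace = TRUE, prob = pp),
        lineage = cl$lineage[i], stringsAsFactors = FALSE)
    }
    counts <- do.call(cbind, blocks)
    ann <- do.call(rbind, ann_blocks)
    ann <- data.frame(cell_id = sprintf("C%05d", seq_len(nrow(ann))), ann,
                      stringsAsFactors = FALSE)
    mat <- expression_matrix(counts, gene_ids = config$gene_ids,
                             cell_ids = ann$cell_id)
    truth <- list(
      planted_markers = config$markers,
      tissue_enrichment = expected_ro_e(cl),
      planted_lr = config$lr_plants,
      gene_means = gene_means)
    list(mat = mat, ann = ann, truth = truth)
  })
}

# design-level R_O/E implied by configured cluster sizes and tissue mixes
expected_ro_e <- function(clusters) {
  tiss <- TISSUE_LEVELS
  p <- t(vapply(clusters$tissue_probs,
                function(tp) { v <- stats::setNames(numeric(4), tiss)
                               v[names(tp)] <- tp; v },
                numeric(4)))
  w <- clusters$n_cells / sum(clusters$n_cells)
  marginal <- colSums(p * w)
  ro <- sweep(p, 2, marginal, "/")
  ro[, marginal == 0] <- NA_real_
  rownames(ro) <- clusters$name
  ro
}

#' Simulate bulk samples as convex mixtures of cluster profiles
#'
#' Each sample is a convex combination, on the linear scale, of per-cluster
#' mean expression profiles, log2(1+x)-transformed, with optional Gaussian
#' noise added on the log scale (clamped at zero so values stay
#' log-TPM-like, i.e. nonnegative).
#'
#' @param signatures genes x clusters matrix of linear-scale profiles.
#' @param fractions samples x clusters matrix of convex weights (rows sum
#'   to 1 within 1e-9; no negative entries).
#' @param noise_sd log-scale Gaussian noise sd.
#' @param seed integer seed.
#' @return genes x samples matrix of log2-scale expression.
#' @export
simulate_bulk <- function(signatures, fractions, noise_sd = 0.1, seed = 1L) {
  signatures <- as.matrix(signatures)
  fractions <- as.matrix(fractions)
  if (ncol(signatures) != ncol(fractions)) {
    stop("fractions columns must match signature clusters")
  }
  if (any(fractions < 0)) stop("negative mixture fractions")
  if (any(abs(rowSums(fractions) - 1) > 1e-9)) {
    stop("fraction rows must sum to 1")
  }
  with_seed(seed, {
    lin <- signatures %*% t(fractions)
    expr <- log2(1 + lin)
    if (noise_sd > 0) {
      expr <- expr + matrix(stats::rnorm(length(expr), sd = noise_sd),
                            nrow = nrow(expr))
      expr[expr < 0] <- 0
    }
    rownames(expr) <- rownames(signatures)
    colnames(expr) <- if (!is.null(rownames(fractions))) {
      rownames(fractions)
    } else {
      sprintf("S%03d", seq_len(nrow(fractions)))
    }
    expr
  })
}

#' Mean linear-scale expression profile per cluster
#'
#' Un-logs the normalized layer (2^x - 1) and averages within clusters;
#' the natural signature input for [simulate_bulk()].
#'
#' @param mat ExpressionMatrix with normalized layer.
#' @param ann matching annotation.
#' @return genes x clusters matrix.
#' @export
cluster_signatures <- function(mat, ann) {
  ann <- match_annotation(mat, ann)
  norm <- norm_layer(mat)
  lin <- norm
  lin@x <- 2^lin@x - 1
  groups <- factor(ann$cluster)
  ind <- Matrix::sparseMatrix(i = seq_along(groups),
                              j = as.integer(groups), x = 1,
                              dims = c(length(groups), nlevels(groups)))
  sizes <- as.numeric(table(groups))
  prof <- as.matrix(lin %*% ind) / rep(sizes, each = nrow(lin))
  colnames(prof) <- levels(groups)
  rownames(prof) <- mat$gene_ids
  prof
}

#' Simulate an L-R pair table with planted and decoy pairs
#'
#' Planted pairs are those co-expression-shifted by the simulator
#' (`lr_plants` in the config); decoys pair genes that carry no planted
#' structure, so permutation p-values for them are exactly null-calibrated.
#'
#' @param config a [sim_config()].
#' @param n_decoys number of decoy pairs to add.
#' @param decoy_genes optional pool of gene ids to draw decoys from
#'   (default: all genes without planted marker or L-R structure).
#' @return L-R pair data.frame ([lr_pair_set()]) with a logical `planted`
#'   column.
#' @export
simulate_lr_pairs <- function(config, n_decoys = 45L, decoy_genes = NULL) {
  stopifnot(inherits(config, "sim_config"))
  used <- unique(c(config$markers$gene, config$lr_plants$ligand,
                   config$lr_plants$receptor))
  pool <- if (is.null(decoy_genes)) setdiff(config$gene_ids, used)
          else decoy_genes
  if (length(pool) < 2 && n_decoys > 0) stop("decoy gene pool too small")
  with_seed(config$seed + 1L, {
    lig <- sample(pool, n_decoys, replace = TRUE)
    rec <- sample(pool, n_decoys, replace = TRUE)
  })
  planted <- config$lr_plants
  df <- rbind(
    if (!is.null(planted)) data.frame(ligand = planted$ligand,
                                      receptor = planted$receptor,
                                      source = "planted",
                                      stringsAsFactors = FALSE),
    if (n_decoys > 0) data.frame(ligand = lig, receptor = rec,
                                 source = "decoy",
                                 stringsAsFactors = FALSE))
  out <- lr_pair_set(df$ligand, df$receptor, df$source)
  out$planted <- out$source == "planted"
  out
}
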