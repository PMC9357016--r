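#' Default end-to-end pipeline configuration
#'
#' Nested parameter blocks mirroring every stage's defaults; thresholds
#' default to the analysis' stated values (QC 200 UMIs / 200-8000 genes /
#' 10% mito; markers adj p < 0.01, FC >= 2, pct diff >= 20%; interactions
#' 1000 permutations, intensity > 1, adj p < 0.01; 5 exhaustion states;
#' down-sampling fractions 1/2-1/5 x 100 replicates; 7 TME subtypes).
#' The `simulate` block describes the default synthetic fixture.
#'
#' @param seed master seed; every stage derives its randomness from it.
#' @return nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_genes = 400L, n_cells_per_cluster = 150L,
                    marker_fc = 4, markers_per_cluster = 10L,
                    baseline_mean = 1, dispersion = 2,
                    n_decoy_pairs = 30L),
    qc = list(min_umi = 200L, min_genes = 200L, max_genes = 8000L,
              max_mito_fraction = 0.10, mito_gene_prefix = "MT-"),
    normalize = list(scale = 10000, pseudocount = 1),
    markers = list(min_fc = 2, min_pct_diff = 0.20, alpha = 0.01),
    preference = list(enrich_cut = 1, alpha = 0.05),
    sharing = list(threshold = 0.60),
    exhaustion = list(k = 5L, overlap_threshold = 0.5),
    interactions = list(tissue = "PT", n_perm = 1000L, min_cells = 5L,
                        min_fraction = 0.10, min_expr = 1,
                        intensity_cut = 1, alpha = 0.01),
    deconvolution = list(n_bulk = 60L, noise_sd = 0.1, k = 7L,
                         n_init = 100L, markers_per_subtype = 10L),
    robustness = list(fractions = c(1 / 2, 1 / 3, 1 / 4, 1 / 5),
                      n_reps = 100L, k = 6L, n_pcs = 10L)
  ), class = "pipeline_config")
}

# reject unknown keys anywhere in the nested config
validate_config <- function(config, template = default_pipeline_config()) {
  walk <- function(cfg, tpl, path) {
    unknown <- setdiff(names(cfg), names(tpl))
    if (length(unknown)) {
      stop("unknown config key", if (length(unknown) > 1) "s", ": ",
           paste0(path, unknown, collapse = ", "))
    }
    for (nm in names(cfg)) {
      if (is.list(tpl[[nm]])) walk(cfg[[nm]], tpl[[nm]],
                                   paste0(path, nm, "."))
    }
  }
  walk(config, template, "")
  merged <- template
  for (nm in names(config)) {
    merged[[nm]] <- if (is.list(template[[nm]])) {
      utils::modifyList(template[[nm]], config[[nm]])
    } else {
      config[[nm]]
    }
  }
  merged
}

# the default synthetic fixture: six lineage-spanning clusters with
# planted markers, tissue enrichments, and two planted L-R axes
default_sim_config <- function(p) {
  n_mk <- p$simulate$markers_per_cluster
  cl_names <- c("CTL", "Treg", "Bcell", "Mac", "Hep1", "Hep2")
  lineages <- c("T/NK", "T/NK", "B", "myeloid", "hepatocyte",
                "hepatocyte")
  tissue_probs <- list(
    c(NTL = 0.6, PT = 0.3, PVTT = 0.05, MLN = 0.05),
    c(NTL = 0.2, PT = 0.6, PVTT = 0.1, MLN = 0.1),
    c(NTL = 0.3, PT = 0.5, PVTT = 0.05, MLN = 0.15),
    c(NTL = 0.25, PT = 0.55, PVTT = 0.1, MLN = 0.1),
    c(NTL = 0.1, PT = 0.7, PVTT = 0.15, MLN = 0.05),
    c(NTL = 0.05, PT = 0.25, PVTT = 0.35, MLN = 0.35))
  patient_probs <- replicate(6, c(P1 = 0.4, P2 = 0.35, P3 = 0.25),
                             simplify = FALSE)
  clusters <- data.frame(name = cl_names, lineage = lineages,
                         n_cells = p$simulate$n_cells_per_cluster,
                         stringsAsFactors = FALSE)
  clusters$tissue_probs <- tissue_probs
  clusters$patient_probs <- patient_probs
  gene_ids <- sprintf("G%04d", seq_len(p$simulate$n_genes))
  markers <- do.call(rbind, lapply(seq_along(cl_names), function(i) {
    data.frame(cluster = cl_names[i],
               gene = gene_ids[((i - 1) * n_mk + 1):(i * n_mk)],
               fold_change = p$simulate$marker_fc,
               stringsAsFactors = FALSE)
  }))
  n_used <- 6 * n_mk
  lr <- data.frame(
    ligand = gene_ids[n_used + 1:2], receptor = gene_ids[n_used + 3:4],
    source_cluster = c("Mac", "Hep1"), target_cluster = c("CTL", "Mac"),
    effect = 4, stringsAsFactors = FALSE)
  sim_config(n_genes = p$simulate$n_genes, clusters = clusters,
             markers = markers, baseline_mean = p$simulate$baseline_mean,
             dispersion = p$simulate$dispersion, lr_plants = lr,
             seed = p$seed)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> qc -> normalize -> markers -> tissue preference ->
#' cluster sharing -> similarity -> exhaustion -> interactions ->
#' deconvolution -> robustness on the configured synthetic fixture,
#' writing one TSV artifact per stage plus a JSON run manifest into
#' `out_dir`. All randomness flows from `config$seed`, so two runs with
#' the same config produce byte-identical numeric artifacts.
#'
#' @param config (partial) configuration; merged over
#'   [default_pipeline_config()], unknown keys rejected before any stage
#'   runs.
#' @param out_dir artifact directory (created).
#' @return invisibly, a named vector of artifact paths.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  p <- validate_config(config,
                       default_pipeline_config(
                         if (!is.null(config$seed)) config$seed else 1L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- c()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv(df, path)
    art[[name]] <<- path
  }

  sim_cfg <- default_sim_config(p)
  sim <- simulate_cells(sim_cfg)
  write_expression(sim$mat, out_dir)
  write_annotation(sim$ann, file.path(out_dir, "annotation.tsv"))

  qc <- qc_filter(sim$mat, do.call(qc_thresholds, p$qc))
  emit(qc$report, "qc_report.tsv")
  ann <- sim$ann[sim$ann$cell_id %in% qc$mat$cell_ids, , drop = FALSE]
  mat <- do.call(normalize_counts, c(list(qc$mat), p$normalize))

  mk <- find_all_markers(mat, ann, min_fc = p$markers$min_fc,
                         min_pct_diff = p$markers$min_pct_diff,
                         alpha = p$markers$alpha)
  emit(mk, "markers.tsv")

  pref <- preference_flags(ro_e_table(ann), p$preference$enrich_cut,
                           p$preference$alpha)
  emit(pref, "tissue_preference.tsv")
  emit(classify_cluster_sharing(ann, p$sharing$threshold),
       "cluster_sharing.tsv")

  sim_mat <- weighted_fc_similarity(mk, mk)
  emit(data.frame(query = rownames(sim_mat)[row(sim_mat)],
                  reference = colnames(sim_mat)[col(sim_mat)],
                  score = as.numeric(sim_mat)), "similarity.tsv")

  ctl_cells <- ann$cell_id[ann$lineage == "T/NK"]
  effector <- sim_cfg$markers$gene[sim_cfg$markers$cluster == "CTL"]
  exh <- kmeans_states(mat, ann, cells = ctl_cells,
                       effector_genes = effector,
                       k = p$exhaustion$k, seed = p$seed)
  exh <- flag_states(exh, mat, ann,
                     overlap_threshold = p$exhaustion$overlap_threshold)
  emit(exh$summary, "exhaustion_summary.tsv")
  emit(data.frame(cell_id = names(exh$labels),
                  subcluster = unname(exh$labels)), "exhaustion_cells.tsv")

  pairs <- simulate_lr_pairs(sim_cfg,
                             n_decoys = p$simulate$n_decoy_pairs)
  elig <- eligible_clusters(ann, p$interactions$tissue,
                            min_cells = p$interactions$min_cells,
                            min_fraction = p$interactions$min_fraction)
  pt_cells <- ann$cell_id[ann$tissue == p$interactions$tissue]
  idx <- match(pt_cells, mat$cell_ids)
  pt_mat <- expression_matrix(mat$counts[, idx, drop = FALSE],
                              gene_ids = mat$gene_ids,
                              cell_ids = pt_cells,
                              normalized = mat$normalized[, idx,
                                                          drop = FALSE])
  inter <- lr_permutation_test(
    pt_mat, ann[idx, , drop = FALSE], pairs, clusters = elig,
    n_perm = p$interactions$n_perm, seed = p$seed,
    min_expr = p$interactions$min_expr,
    intensity_cut = p$interactions$intensity_cut,
    alpha = p$interactions$alpha)
  emit(inter, "interactions.tsv")
  emit(communication_network(inter, ann, p$interactions$tissue),
       "communication_network.tsv")

  sigs <- cluster_signatures(mat, ann)
  n_bulk <- p$deconvolution$n_bulk
  fr <- with_seed(p$seed + 101L, {
    raw <- matrix(stats::rgamma(n_bulk * ncol(sigs), shape = 1),
                  nrow = n_bulk)
    raw / rowSums(raw)
  })
  colnames(fr) <- colnames(sigs)
  bulk <- simulate_bulk(sigs, fr, noise_sd = p$deconvolution$noise_sd,
                        seed = p$seed + 102L)
  sets <- lapply(split(mk, mk$cluster), function(d)
    utils::head(d$gene[order(-d$fold_change)],
                p$deconvolution$markers_per_subtype))
  ab <- abundance_scores(bulk, sets)
  nab <- normalize_abundance(ab)
  emit(data.frame(subtype = rownames(nab), nab, check.names = FALSE),
       "abundance_normalized.tsv")
  k_tme <- min(p$deconvolution$k, ncol(nab))
  tme <- tme_subtypes(nab, k = k_tme, n_init = p$deconvolution$n_init,
                      seed = p$seed + 103L)
  emit(data.frame(sample = names(tme$labels),
                  subtype = unname(tme$labels)), "tme_subtypes.tsv")

  bench <- stats::setNames(ann$cluster, ann$cell_id)
  cb <- make_kmeans_callback(k = p$robustness$k,
                             n_pcs = p$robustness$n_pcs)
  rob <- downsample_robustness(mat, bench, cb,
                               fractions = p$robustness$fractions,
                               n_reps = p$robustness$n_reps,
                               seed = p$seed + 104L)
  rob <- rbind(rob, leave_one_patient_out(mat, ann, bench, cb,
                                          seed = p$seed + 105L))
  emit(rob, "robustness.tsv")
  emit(summarize_robustness(rob), "robustness_summary.tsv")

  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(p), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  manifest <- list(package = "tmetools",
                   version = as.character(utils::packageVersion("tmetools")),
                   seed = p$seed,
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   artifacts = names(art))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(unlist(art))
}

#' Command-line interface
#'
#' Subcommand dispatcher for the pipeline and its stages. Flags use
#' `--name value` syntax; `--seed` is honored everywhere. Subcommands:
#' `pipeline --out DIR [--seed N] [--n-perm N] [--n-reps N]`,
#' `simulate --out DIR [--seed N] [--preset default|calibration-null]`,
#' `qc --mtx F --genes F --barcodes F --out DIR`,
#' `markers --mtx F --genes F --barcodes F --annotation F --out FILE`,
#' `preference --annotation F --out FILE`,
#' `nmi --labels-a F --labels-b F`.
#'
#' @param args character vector (default: command line).
#' @return exit status, invisibly (0 on success).
#' @export
tme_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: tmetools <pipeline|simulate|qc|markers|preference|",
            "nmi> [--flag value ...]")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_flags(args[-1])
  seed <- as.integer(opts[["seed"]] %||% 1L)
  status <- 0L
  switch(cmd,
    pipeline = {
      cfg <- list(seed = seed)
      if (!is.null(opts[["n-perm"]])) {
        cfg$interactions <- list(n_perm = as.integer(opts[["n-perm"]]))
      }
      if (!is.null(opts[["n-reps"]])) {
        cfg$robustness <- list(n_reps = as.integer(opts[["n-reps"]]))
      }
      run_pipeline(cfg, need_opt(opts, "out"))
    },
    simulate = {
      out <- need_opt(opts, "out")
      p <- default_pipeline_config(seed)
      cfg <- default_sim_config(p)
      if (identical(opts[["preset"]], "calibration-null")) {
        cfg$markers <- NULL
        cfg$lr_plants <- NULL
      }
      sim <- simulate_cells(cfg)
      write_expression(sim$mat, out)
      write_annotation(sim$ann, file.path(out, "annotation.tsv"))
      write_lr_pairs(simulate_lr_pairs(cfg, n_decoys = 45L),
                     file.path(out, "lr_pairs.csv"))
    },
    qc = {
      mat <- read_expression(need_opt(opts, "mtx"),
                             need_opt(opts, "genes"),
                             need_opt(opts, "barcodes"))
      res <- qc_filter(mat)
      out <- need_opt(opts, "out")
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_expression(res$mat, out, prefix = "filtered_")
      write_tsv(res$report, file.path(out, "qc_report.tsv"))
    },
    markers = {
      mat <- read_expression(need_opt(opts, "mtx"),
                             need_opt(opts, "genes"),
                             need_opt(opts, "barcodes"))
      ann <- read_annotation(need_opt(opts, "annotation"))
      mat <- normalize_counts(qc_filter(mat)$mat)
      ann <- ann[ann$cell_id %in% mat$cell_ids, , drop = FALSE]
      write_tsv(find_all_markers(mat, ann), need_opt(opts, "out"))
    },
    preference = {
      ann <- read_annotation(need_opt(opts, "annotation"))
      write_tsv(preference_flags(ro_e_table(ann)),
                need_opt(opts, "out"))
    },
    nmi = {
      a <- readLines(need_opt(opts, "labels-a"))
      b <- readLines(need_opt(opts, "labels-b"))
      cat(format(nmi(a, b), digits = 10), "\n")
    },
    {
      message("unknown subcommand: ", cmd)
      status <- 1L
    })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_flags <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("expected --flag, got: ", args[i])
    if (i + 1 > length(args)) stop("missing value for ", args[i])
    opts[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  opts
}

need_opt <- function(opts, name) {
  if (is.null(opts[[name]])) stop("missing required flag --", name)
  opts[[name]]
}
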