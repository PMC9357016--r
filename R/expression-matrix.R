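#' Construct an ExpressionMatrix
#'
#' Container for a genes x cells UMI count matrix plus an optional
#' log2-scale normalized layer with the same dimensions. Counts are stored
#' sparse (`dgCMatrix`); the normalized layer shares the sparsity pattern
#' because the transform maps 0 to 0.
#'
#' @param counts genes x cells matrix of nonnegative integer UMI counts
#'   (base matrix or any Matrix class; coerced to `dgCMatrix`).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   rownames of `counts`).
#' @param cell_ids character vector of unique cell barcodes (defaults to
#'   colnames of `counts`).
#' @param normalized optional normalized layer, same shape as `counts`.
#' @return An object of class `ExpressionMatrix`.
#' @export
expression_matrix <- function(counts, gene_ids = rownames(counts),
                              cell_ids = colnames(counts), normalized = NULL) {
  counts <- as_dgc(counts)
  if (is.null(gene_ids) || is.null(cell_ids)) {
    stop("gene_ids and cell_ids are required (or set dimnames on counts)")
  }
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts)) {
    stop("length(gene_ids) does not match nrow(counts)")
  }
  if (length(cell_ids) != ncol(counts)) {
    stop("length(cell_ids) does not match ncol(counts)")
  }
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  v <- counts@x
  if (length(v) && (min(v) < 0 || any(v != round(v)))) {
    stop("counts must be nonnegative integers")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (!is.null(normalized)) {
    normalized <- as_dgc(normalized)
    if (!identical(dim(normalized), dim(counts))) {
      stop("normalized layer shape differs from counts")
    }
    if (length(normalized@x) && min(normalized@x) < 0) {
      stop("normalized entries must be >= 0")
    }
    dimnames(normalized) <- dimnames(counts)
  }
  structure(list(gene_ids = gene_ids, cell_ids = cell_ids,
                 counts = counts, normalized = normalized),
            class = "ExpressionMatrix")
}

# coerce base or Matrix classes to numeric dgCMatrix
as_dgc <- function(m) {
  if (is.matrix(m)) {
    storage.mode(m) <- "double"
    m <- Matrix::Matrix(m, sparse = TRUE)
  }
  methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cells (%s normalized layer)\n",
              length(x$gene_ids), length(x$cell_ids),
              if (is.null(x$normalized)) "no" else "with"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a MatrixMarket expression triplet
#'
#' Reads the conventional `matrix.mtx` + `genes.tsv` + `barcodes.tsv`
#' triplet into an [expression_matrix()]. The first column of each TSV is
#' used as the identifier; additional columns are ignored.
#'
#' @param matrix_path path to the MatrixMarket coordinate file.
#' @param genes_path path to a TSV whose rows correspond to matrix rows.
#' @param barcodes_path path to a TSV whose rows correspond to matrix
#'   columns.
#' @return ExpressionMatrix with counts populated and no normalized layer.
#' @export
read_expression <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  hdr <- readLines(matrix_path, n = 1L)
  if (!grepl("^%%MatrixMarket", hdr)) {
    stop("format error in ", matrix_path, ": missing MatrixMarket header")
  }
  m <- Matrix::readMM(matrix_path)
  genes <- utils::read.delim(genes_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.delim(barcodes_path, header = FALSE,
                                stringsAsFactors = FALSE)[[1]]
  if (length(genes) != nrow(m)) {
    stop("format error in ", genes_path, ": ", length(genes),
         " gene rows for a matrix with ", nrow(m), " rows")
  }
  if (length(barcodes) != ncol(m)) {
    stop("format error in ", barcodes_path, ": ", length(barcodes),
         " barcode rows for a matrix with ", ncol(m), " columns")
  }
  expression_matrix(m, gene_ids = genes, cell_ids = barcodes)
}

#' Write an ExpressionMatrix as a MatrixMarket triplet
#'
#' Inverse of [read_expression()]; round-trips (gene_ids, cell_ids, counts)
#' bit-exactly. The normalized layer is not serialized.
#'
#' @param mat ExpressionMatrix.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default "".
#' @return Invisibly, the three file paths.
#' @export
write_expression <- function(mat, dir, prefix = "") {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mp <- file.path(dir, paste0(prefix, "matrix.mtx"))
  gp <- file.path(dir, paste0(prefix, "genes.tsv"))
  bp <- file.path(dir, paste0(prefix, "barcodes.tsv"))
  Matrix::writeMM(mat$counts, mp)
  writeLines(mat$gene_ids, gp)
  writeLines(mat$cell_ids, bp)
  invisible(c(matrix = mp, genes = gp, barcodes = bp))
}

#' Quality-control thresholds
#'
#' Defaults follow the common droplet scRNA-seq practice of removing
#' presumptive empty droplets, doublets, and dying cells: at least 200
#' UMIs, between 200 and 8000 detected genes, and at most 10% of UMIs from
#' mitochondrial genes.
#'
#' @param min_umi minimum total UMIs per cell.
#' @param min_genes,max_genes detected-gene bounds (count of genes with
#'   nonzero UMIs).
#' @param max_mito_fraction maximum mitochondrial UMI fraction in [0,1].
#' @param mito_gene_prefix gene-symbol prefix marking mitochondrial genes.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_umi = 200L, min_genes = 200L,
                          max_genes = 8000L, max_mito_fraction = 0.10,
                          mito_gene_prefix = "MT-") {
  if (min_genes > max_genes) stop("min_genes > max_genes")
  if (max_mito_fraction < 0 || max_mito_fraction > 1) {
    stop("max_mito_fraction must lie in [0,1]")
  }
  structure(list(min_umi = min_umi, min_genes = min_genes,
                 max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix),
            class = "qc_thresholds")
}

#' Filter low-quality cells
#'
#' Retains cells with total UMIs >= `min_umi`, detected genes within
#' `[min_genes, max_genes]`, and mitochondrial UMI fraction <=
#' `max_mito_fraction`. The report lists each removed cell with the first
#' failing rule in the fixed order low_umi, low_genes, high_genes,
#' high_mito.
#'
#' @param mat ExpressionMatrix.
#' @param thresholds a [qc_thresholds()] object.
#' @return list(mat = filtered ExpressionMatrix, report = data.frame with
#'   columns cell_id, reason).
#' @export
qc_filter <- function(mat, thresholds = qc_thresholds()) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  counts <- mat$counts
  total <- Matrix::colSums(counts)
  ngene <- Matrix::colSums(counts > 0)
  mito <- startsWith(mat$gene_ids, thresholds$mito_gene_prefix)
  mito_frac <- if (any(mito)) {
    ifelse(total > 0, Matrix::colSums(counts[mito, , drop = FALSE]) / total, 0)
  } else {
    rep(0, length(total))
  }
  reason <- rep(NA_character_, length(total))
  reason[mito_frac > thresholds$max_mito_fraction] <- "high_mito"
  reason[ngene > thresholds$max_genes] <- "high_genes"
  reason[ngene < thresholds$min_genes] <- "low_genes"
  reason[total < thresholds$min_umi] <- "low_umi"
  keep <- is.na(reason)
  if (!any(keep)) warning("qc_filter removed every cell")
  report <- data.frame(cell_id = mat$cell_ids[!keep],
                       reason = reason[!keep],
                       stringsAsFactors = FALSE)
  out <- expression_matrix(counts[, keep, drop = FALSE],
                           gene_ids = mat$gene_ids,
                           cell_ids = mat$cell_ids[keep])
  list(mat = out, report = report)
}

#' Library-size normalize counts to a log2 scale
#'
#' Scales each cell to `scale` total counts, then applies
#' `log2(pseudocount + x)`: `normalized[g,c] = log2(pseudocount +
#' counts[g,c] * scale / total[c])`. With the default pseudocount of 1,
#' zeros map to zero and sparsity is preserved.
#'
#' @param mat ExpressionMatrix with counts.
#' @param scale target library size per cell.
#' @param pseudocount added inside the log.
#' @return ExpressionMatrix with the normalized layer filled.
#' @export
normalize_counts <- function(mat, scale = 10000, pseudocount = 1) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  total <- Matrix::colSums(mat$counts)
  if (any(total == 0)) {
    stop("cells with zero total counts present; run qc_filter first")
  }
  norm <- mat$counts
  # dgCMatrix stores columns contiguously: scale @x per column
  percol <- diff(norm@p)
  norm@x <- log2(pseudocount + norm@x * scale / rep.int(total, percol))
  expression_matrix(mat$counts, gene_ids = mat$gene_ids,
                    cell_ids = mat$cell_ids, normalized = norm)
}

#' Classify clusters as patient-shared or patient-specific
#'
#' A cluster is patient-specific when more than `threshold` of its cells
#' come from a single patient; otherwise it is shared.
#'
#' @param ann cell annotation data.frame with columns `cluster`, `patient`.
#' @param threshold dominant-patient fraction above which a cluster is
#'   patient-specific (strict inequality).
#' @return data.frame(cluster, class, dominant_patient, dominant_fraction,
#'   n_cells).
#' @export
classify_cluster_sharing <- function(ann, threshold = 0.60) {
  stopifnot(all(c("cluster", "patient") %in% names(ann)))
  tab <- table(ann$cluster, ann$patient)
  if (any(rowSums(tab) == 0)) stop("empty cluster in annotation")
  frac <- sweep(tab, 1, rowSums(tab), "/")
  idx <- max.col(frac, ties.method = "first")
  dom_frac <- frac[cbind(seq_len(nrow(frac)), idx)]
  data.frame(
    cluster = rownames(tab),
    class = ifelse(dom_frac > threshold, "patient_specific", "shared"),
    dominant_patient = colnames(tab)[idx],
    dominant_fraction = as.numeric(dom_frac),
    n_cells = as.integer(rowSums(tab)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Read / write per-cell annotations
#'
#' Annotation TSVs have a header row and columns cell_id, cluster, tissue,
#' patient, lineage. Tissue labels are validated against the closed set
#' NTL, PT, PVTT, MLN.
#'
#' @param path TSV path.
#' @return data.frame with the five annotation columns.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
  ann
}

#' @rdname read_annotation
#' @param ann annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  validate_annotation(ann)
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

TISSUE_LEVELS <- c("NTL", "PT", "PVTT", "MLN")

validate_annotation <- function(ann) {
  need <- c("cell_id", "cluster", "tissue", "patient", "lineage")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(ann$cell_id)) stop("duplicate cell_id in annotation")
  bad <- setdiff(unique(ann$tissue), TISSUE_LEVELS)
  if (length(bad)) stop("unknown tissue labels: ", paste(bad, collapse = ", "))
  invisible(ann)
}

# annotation rows aligned to, and covering, a matrix's cells
match_annotation <- function(mat, ann) {
  validate_annotation(ann)
  idx <- match(mat$cell_ids, ann$cell_id)
  if (anyNA(idx)) {
    stop("annotation missing ", sum(is.na(idx)), " cells, e.g. ",
         mat$cell_ids[which(is.na(idx))[1]])
  }
  ann[idx, , drop = FALSE]
}

# normalized layer or informative error
norm_layer <- function(mat) {
  if (is.null(mat$normalized)) {
    stop("normalized layer absent; run normalize_counts() first")
  }
  mat$normalized
}
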