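#' Read a GMT gene-set file
#'
#' @param path GMT path (tab-separated: name, description, genes...).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3) stop("malformed GMT line: ", f[1])
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[`, "", 1)
  sets
}

#' Write gene sets as GMT
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a ligand-receptor pair table
#'
#' CSV with columns ligand, receptor and an optional source annotation.
#' Duplicate (ligand, receptor) rows are collapsed with a warning.
#'
#' @param path CSV path.
#' @return data.frame(ligand, receptor, source).
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(df))) {
    stop("L-R pair table needs columns ligand, receptor")
  }
  if (!"source" %in% names(df)) df$source <- "unspecified"
  lr_pair_set(df$ligand, df$receptor, df$source)
}

#' @rdname read_lr_pairs
#' @param pairs L-R pair data.frame.
#' @export
write_lr_pairs <- function(pairs, path) {
  utils::write.csv(pairs, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an L-R pair set
#'
#' @param ligand,receptor character vectors of gene ids.
#' @param source provenance annotation per pair.
#' @return data.frame(ligand, receptor, source, self_pair) with unique
#'   (ligand, receptor) rows; self pairs (ligand == receptor) are kept and
#'   flagged.
#' @export
lr_pair_set <- function(ligand, receptor, source = "unspecified") {
  if (any(!nzchar(ligand)) || any(!nzchar(receptor))) {
    stop("empty gene id in L-R pairs")
  }
  df <- data.frame(ligand = as.character(ligand),
                   receptor = as.character(receptor),
                   source = source, stringsAsFactors = FALSE)
  key <- paste(df$ligand, df$receptor, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)), " duplicate L-R pair rows")
    df <- df[!duplicated(key), , drop = FALSE]
  }
  df$self_pair <- df$ligand == df$receptor
  rownames(df) <- NULL
  df
}

#' Read / write a bulk expression cohort
#'
#' Genes x samples table of log-transformed TPM, TSV with a header row of
#' sample ids and gene ids in the first column. Duplicate gene rows are
#' summed on load with a warning.
#'
#' @param path TSV path.
#' @return list(expr = genes x samples numeric matrix, meta = per-sample
#'   metadata data.frame or NULL).
#' @export
read_bulk_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  genes <- df[[1]]
  expr <- as.matrix(df[, -1, drop = FALSE])
  mode(expr) <- "double"
  if (anyDuplicated(genes)) {
    warning("summed ", sum(duplicated(genes)), " duplicate gene rows")
    expr <- rowsum(expr, group = genes)
  } else {
    rownames(expr) <- genes
  }
  if (any(!is.finite(expr))) stop("non-finite values in bulk cohort")
  list(expr = expr, meta = NULL)
}

#' @rdname read_bulk_cohort
#' @param expr genes x samples matrix.
#' @export
write_bulk_cohort <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# uniform TSV writers for result tables
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
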