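test_that("read_expression parses 1-based MTX triplets and validates", {
  d <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 2", "1 1 5", "3 2 2"),
             file.path(d, "matrix.mtx"))
  writeLines(c("gA", "gB", "gC"), file.path(d, "genes.tsv"))
  writeLines(c("c1", "c2"), file.path(d, "barcodes.tsv"))
  m <- read_expression(file.path(d, "matrix.mtx"),
                       file.path(d, "genes.tsv"),
                       file.path(d, "barcodes.tsv"))
  expect_equal(unname(as.matrix(m$counts)),
               matrix(c(5, 0, 0, 0, 0, 2), nrow = 3))
  expect_null(m$normalized)

  # empty triplet body with a declared shape gives the zero matrix
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "3 2 0"), file.path(d, "matrix.mtx"))
  m0 <- read_expression(file.path(d, "matrix.mtx"),
                        file.path(d, "genes.tsv"),
                        file.path(d, "barcodes.tsv"))
  expect_equal(sum(m0$counts), 0)
  expect_equal(dim(m0), c(3L, 2L))

  # barcode count mismatching the declared columns names the file
  writeLines(c("c1", "c2", "c3"), file.path(d, "barcodes.tsv"))
  expect_error(read_expression(file.path(d, "matrix.mtx"),
                               file.path(d, "genes.tsv"),
                               file.path(d, "barcodes.tsv")),
               "barcodes.tsv")
})

test_that("write_expression round-trips bit-exactly", {
  set.seed(7)
  m <- tiny_mat(matrix(rpois(60, 1), 10, 6))
  d <- withr::local_tempdir()
  p <- write_expression(m, d)
  m2 <- read_expression(p["matrix"], p["genes"], p["barcodes"])
  expect_identical(m2$gene_ids, m$gene_ids)
  expect_identical(m2$cell_ids, m$cell_ids)
  expect_equal(as.matrix(m2$counts), as.matrix(m$counts))
})

test_that("expression_matrix enforces its invariants", {
  expect_error(tiny_mat(matrix(c(1, -1, 0, 2), 2, 2)), "nonnegative")
  expect_error(tiny_mat(matrix(c(1, 0.5, 0, 2), 2, 2)), "integer")
  expect_error(tiny_mat(matrix(0, 2, 2), genes = c("a", "a")),
               "duplicate")
  expect_error(expression_matrix(matrix(0L, 2, 2),
                                 gene_ids = c("a", "b"),
                                 cell_ids = c("x", "y"),
                                 normalized = matrix(0, 3, 2)), "shape")
})

test_that("qc_filter applies the four rules with first-failure reasons", {
  # genes: 1 mito + 4 regular; craft per-cell profiles
  counts <- cbind(
    low_umi   = c(0, 50, 50, 30, 20),    # 150 UMIs < 200
    high_mito = c(36, 100, 80, 50, 34),  # 12% mito
    ok        = c(0, 200, 150, 100, 50), # 500 UMIs, 0% mito
    low_genes = c(0, 500, 0, 0, 0))      # 1 detected gene
  mat <- tiny_mat(counts, genes = c("MT-ND1", "gA", "gB", "gC", "gD"),
                  cells = colnames(counts))
  th <- qc_thresholds(min_umi = 200, min_genes = 2, max_genes = 5,
                      max_mito_fraction = 0.10)
  res <- qc_filter(mat, th)
  expect_equal(res$mat$cell_ids, "ok")
  expect_equal(res$report$reason[match(c("low_umi", "high_mito",
                                         "low_genes"),
                                       res$report$cell_id)],
               c("low_umi", "high_mito", "low_genes"))
  # idempotence: filtering the filtered matrix removes nothing
  res2 <- qc_filter(res$mat, th)
  expect_equal(nrow(res2$report), 0L)
  expect_equal(res2$mat$cell_ids, res$mat$cell_ids)
})

test_that("qc_filter warns rather than errors when nothing survives", {
  mat <- tiny_mat(matrix(c(1L, 1L), 1, 2))
  expect_warning(res <- qc_filter(mat, qc_thresholds(min_umi = 10,
                                                     min_genes = 1,
                                                     max_genes = 10)),
                 "every cell")
  expect_equal(length(res$mat$cell_ids), 0L)
})

test_that("normalize_counts implements log2(1 + scaled) exactly", {
  counts <- matrix(c(10, 990, 0, 100), 2, 2)
  m <- normalize_counts(tiny_mat(counts))
  # count 10 of 1000 total at scale 10000 -> log2(101)
  expect_equal(m$normalized[1, 1], log2(101))
  expect_equal(m$normalized[1, 2], 0)   # zero count -> log2(1) = 0
  # library-size cancellation: doubling a cell's counts changes nothing
  m2 <- normalize_counts(tiny_mat(counts * 2L))
  expect_equal(as.matrix(m2$normalized), as.matrix(m$normalized))
  # zero-total cell is refused with advice
  expect_error(normalize_counts(tiny_mat(matrix(c(1L, 0L), 1, 2))),
               "qc_filter")
})

test_that("normalization preserves within-gene rank order at equal depth", {
  # all cells share the same total, so the transform is monotone per gene
  counts <- matrix(rep(0:9, each = 5), 5, 10) + 1L
  m <- normalize_counts(tiny_mat(counts))
  expect_equal(order(as.numeric(m$normalized[1, ])), 1:10)
})

test_that("classify_cluster_sharing uses the >60% dominant rule", {
  ann <- make_ann(sprintf("c%d", 1:201),
                  cluster = c(rep("A", 100), rep("B", 100), "C"),
                  patient = c(rep("P1", 70), rep("P2", 30),
                              rep(c("P1", "P2"), 50), "P9"))
  out <- classify_cluster_sharing(ann)
  expect_equal(out$class[out$cluster == "A"], "patient_specific")
  expect_equal(out$dominant_fraction[out$cluster == "A"], 0.70)
  expect_equal(out$class[out$cluster == "B"], "shared")      # 50/50
  expect_equal(out$class[out$cluster == "C"], "patient_specific")
  expect_equal(out$dominant_fraction[out$cluster == "C"], 1.0)
  # exactly at threshold is shared (strict >)
  ann2 <- make_ann(sprintf("c%d", 1:10), cluster = "A",
                   patient = rep(c("P1", "P2"), c(6, 4)))
  expect_equal(classify_cluster_sharing(ann2)$class, "shared")
})

test_that("annotation io validates the closed tissue set", {
  d <- withr::local_tempdir()
  ann <- make_ann(c("c1", "c2"), c("A", "B"), tissue = c("PT", "MLN"))
  p <- write_annotation(ann, file.path(d, "ann.tsv"))
  expect_equal(read_annotation(p), ann, ignore_attr = TRUE)
  ann$tissue[1] <- "LIVER"
  expect_error(write_annotation(ann, file.path(d, "bad.tsv")),
               "unknown tissue")
})
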