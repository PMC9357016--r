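test_that("eligible_clusters applies cell-count and fraction rules", {
  ann <- make_ann(sprintf("c%d", 1:120),
                  cluster = rep(c("A", "B", "C"), c(4, 16, 100)),
                  tissue = "PT",
                  lineage = rep(c("T/NK", "T/NK", "T/NK"), c(4, 16, 100)))
  expect_setequal(eligible_clusters(ann, "PT"), c("B", "C"))  # A: 4 cells
  # with the fraction rule disabled only min_cells matters
  expect_setequal(eligible_clusters(ann, "PT", min_fraction = 0),
                  c("B", "C"))
  # B is 16/120 = 13% of T/NK; raising the bar drops it
  expect_setequal(eligible_clusters(ann, "PT", min_fraction = 0.5), "C")
  expect_error(eligible_clusters(ann, "MLN"), "unknown tissue")
})

test_that("interaction_intensity is the product of means with a floor", {
  # construct normalized means directly via counts at equal depth
  counts <- rbind(c(8L, 8L, 0L, 0L), c(0L, 0L, 8L, 8L),
                  c(92L, 92L, 92L, 92L))
  mat <- normalize_counts(tiny_mat(counts, genes = c("lig", "rec", "pad")))
  ann <- make_ann(mat$cell_ids, rep(c("L", "R"), each = 2))
  ml <- mean(mat$normalized["lig", 1:2])
  mr <- mean(mat$normalized["rec", 3:4])
  expect_equal(interaction_intensity(mat, ann, "L", "R", "lig", "rec"),
               ml * mr)
  # receptor mean in the sender cluster is 0 -> floor filters
  expect_true(is.na(interaction_intensity(mat, ann, "L", "R", "rec",
                                          "lig")))
  expect_error(interaction_intensity(mat, ann, "L", "R", "nope", "rec"),
               "absent")
})

test_that("intensity is bilinear in the sender cluster's ligand level", {
  f <- marker_fixture(n_clusters = 2, n_per = 50, n_genes = 20,
                      baseline = 5, seed = 61)
  i1 <- interaction_intensity(f$mat, f$ann, "CL1", "CL2", "G0015",
                              "G0016", min_expr = 0)
  mat2 <- f$mat
  norm2 <- mat2$normalized
  idx <- which(f$ann$cluster == "CL1")
  norm2["G0015", idx] <- norm2["G0015", idx] * 3
  mat2 <- expression_matrix(mat2$counts, gene_ids = mat2$gene_ids,
                            cell_ids = mat2$cell_ids, normalized = norm2)
  i2 <- interaction_intensity(mat2, f$ann, "CL1", "CL2", "G0015",
                              "G0016", min_expr = 0)
  expect_equal(i2, 3 * i1, tolerance = 1e-12)
})

test_that("permutation p-values are seeded, degenerate for constants", {
  f <- marker_fixture(n_clusters = 2, n_per = 60, n_genes = 20,
                      baseline = 5, seed = 62)
  # constant gene: every permuted intensity equals the observed one
  norm2 <- f$mat$normalized
  norm2["G0019", ] <- 2
  norm2["G0020", ] <- 3
  mat2 <- expression_matrix(f$mat$counts, gene_ids = f$mat$gene_ids,
                            cell_ids = f$mat$cell_ids, normalized = norm2)
  pairs <- lr_pair_set("G0019", "G0020")
  r <- lr_permutation_test(mat2, f$ann, pairs, n_perm = 50, seed = 5)
  expect_true(all(r$p_raw == 1))
  expect_true(all(r$intensity == 6))
  # same seed -> identical; different seed -> close (MC error)
  pairs2 <- lr_pair_set(c("G0011", "G0012"), c("G0013", "G0014"))
  a <- lr_permutation_test(f$mat, f$ann, pairs2, n_perm = 200, seed = 7)
  b <- lr_permutation_test(f$mat, f$ann, pairs2, n_perm = 200, seed = 7)
  expect_identical(a, b)
  c_ <- lr_permutation_test(f$mat, f$ann, pairs2, n_perm = 200, seed = 8)
  expect_lt(max(abs(a$p_raw - c_$p_raw), na.rm = TRUE),
            4 * sqrt(0.25 / 200) + 1e-9)
})

test_that("strict tail and +1 estimator behave as documented", {
  lr <- data.frame(ligand = "G0017", receptor = "G0018",
                   source_cluster = "CL1", target_cluster = "CL2",
                   effect = 6)
  f <- marker_fixture(n_clusters = 2, n_per = 150, n_genes = 20,
                      baseline = 3, seed = 63, lr_plants = lr)
  pairs <- lr_pair_set("G0017", "G0018")
  ge <- lr_permutation_test(f$mat, f$ann, pairs, n_perm = 100, seed = 1)
  gt <- lr_permutation_test(f$mat, f$ann, pairs, n_perm = 100, seed = 1,
                            tail = "gt")
  p1 <- lr_permutation_test(f$mat, f$ann, pairs, n_perm = 100, seed = 1,
                            add_one = TRUE)
  row <- ge$cluster_l == "CL1" & ge$cluster_r == "CL2"
  expect_lte(gt$p_raw[row], ge$p_raw[row])
  expect_equal(p1$p_raw[row], (ge$p_raw[row] * 100 + 1) / 101)
  expect_error(lr_permutation_test(f$mat, f$ann, pairs, n_perm = 0),
               "n_perm")
})

test_that("planted L-R axis is significant; significance sets nest", {
  lr <- data.frame(ligand = "G0031", receptor = "G0032",
                   source_cluster = "CL1", target_cluster = "CL2",
                   effect = 4)
  f <- marker_fixture(n_clusters = 2, n_per = 300, n_genes = 40,
                      baseline = 2, seed = 64, lr_plants = lr)
  pairs <- lr_pair_set(c("G0031", "G0035", "G0036"),
                       c("G0032", "G0037", "G0038"))
  r <- lr_permutation_test(f$mat, f$ann, pairs, n_perm = 200, seed = 2)
  hit <- r[r$cluster_l == "CL1" & r$cluster_r == "CL2" &
             r$ligand == "G0031", ]
  expect_true(hit$significant)
  # loosening both cuts only grows the significant set
  strict <- r$significant
  loose <- !is.na(r$p_adj) & r$intensity > 0.5 &
    pmin(1, r$p_raw * 3) < 0.05
  expect_true(all(!strict | loose))
})

test_that("communication network weighting algebra", {
  res <- data.frame(cluster_l = c("A", "A", "A", "B"),
                    cluster_r = c("B", "B", "B", "A"),
                    ligand = "x", receptor = "y",
                    intensity = 2, p_raw = 0, p_adj = 0,
                    significant = c(TRUE, TRUE, TRUE, FALSE))
  ann <- make_ann(sprintf("c%d", 1:100),
                  cluster = rep(c("A", "B"), c(20, 80)), tissue = "PT")
  count <- communication_network(res, ann, "PT", weighting = "count")
  expect_equal(count$weight, 3)
  prod_ <- communication_network(res, ann, "PT")
  expect_equal(prod_$weight, 3 * (20 * 80) / 100^2)
  sum_ <- communication_network(res, ann, "PT", weighting = "cells_sum")
  expect_equal(sum_$weight, 3 * (20 + 80) / 100)
  # no significant rows -> empty edge list
  res$significant <- FALSE
  expect_equal(nrow(communication_network(res, ann, "PT")), 0L)
})

test_that("ligand-pathway network: monotone, anti-monotone, null", {
  f <- marker_fixture(n_clusters = 2, n_per = 60, n_genes = 20,
                      baseline = 4, seed = 65)
  cells <- f$mat$cell_ids
  x <- as.numeric(f$mat$normalized["G0011", ])
  scores <- cbind(mono = rank(x), anti = -rank(x))
  rownames(scores) <- cells
  net <- ligand_pathway_network(f$mat, cells, "G0011", scores)
  expect_equal(net$rho[net$pathway == "mono"], 1)
  expect_equal(net$rho[net$pathway == "anti"], -1)
  expect_true(all(net$edge))
  # constant ligand is skipped with a warning
  norm2 <- f$mat$normalized; norm2["G0012", ] <- 1
  mat2 <- expression_matrix(f$mat$counts, gene_ids = f$mat$gene_ids,
                            cell_ids = f$mat$cell_ids, normalized = norm2)
  expect_warning(out <- ligand_pathway_network(mat2, cells, "G0012",
                                               scores), "constant")
  expect_equal(nrow(out), 0L)
})

test_that("pathway_activity scores separate planted marker sets", {
  f <- marker_fixture(n_clusters = 2, n_per = 80, seed = 66)
  sets <- list(cl1 = f$config$markers$gene[
    f$config$markers$cluster == "CL1"])
  act <- pathway_activity(f$mat, sets)
  inn <- f$ann$cluster == "CL1"
  expect_gt(mean(act[inn, "cl1"]), mean(act[!inn, "cl1"]))
})
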