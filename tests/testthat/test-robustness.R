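test_that("nmi: identity, relabeling, symmetry, degenerate cases", {
  a <- rep(c("x", "y", "z"), times = c(5, 3, 2))
  expect_equal(nmi(a, a), 1.0)
  relab <- c(x = "1", y = "2", z = "3")[a]          # bijective rename
  expect_equal(nmi(a, relab), 1.0)
  set.seed(81)
  b <- sample(letters[1:4], 10, replace = TRUE)
  expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
  # identical permutation of both vectors changes nothing
  p <- sample(10)
  expect_equal(nmi(a[p], b[p]), nmi(a, b), tolerance = 1e-12)
  # one constant labeling against a non-degenerate one gives 0
  expect_equal(nmi(rep("k", 10), b), 0)
  expect_equal(nmi(rep("k", 10), rep("j", 10)), 1)
  expect_error(nmi(a, b[1:5]), "length")
})

test_that("nmi normalization variants order sensibly", {
  set.seed(82)
  a <- sample(letters[1:3], 200, replace = TRUE)
  b <- ifelse(stats::runif(200) < 0.8, a, sample(letters[1:5], 200,
                                                 replace = TRUE))
  v <- vapply(c("min", "geometric", "mean", "max"),
              function(m) nmi(a, b, normalization = m), 0)
  expect_true(all(diff(v) <= 1e-12))   # min >= geom >= mean >= max
})

test_that("adjusted_rand_index: identity and independence", {
  a <- rep(1:3, each = 20)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, rev(a)), 1)  # relabel-invariant
  set.seed(83)
  expect_lt(abs(adjusted_rand_index(a, sample(a))), 0.15)
})

test_that("downsample fraction 1.0 with a benchmark-reproducing callback", {
  f <- marker_fixture(n_clusters = 2, n_per = 40, seed = 84)
  bench <- stats::setNames(f$ann$cluster, f$ann$cell_id)
  echo_cb <- function(mat, cells, seed) bench[cells]
  rep_ <- downsample_robustness(f$mat, bench, echo_cb, fractions = 1,
                                n_reps = 3, seed = 1)
  expect_equal(rep_$nmi, rep(1, 3))
  expect_equal(rep_$n_cells, rep(80L, 3))
  expect_error(downsample_robustness(f$mat, bench, echo_cb,
                                     fractions = 1.2, n_reps = 1),
               "fractions")
})

test_that("random-label callback scores near zero", {
  f <- marker_fixture(n_clusters = 3, n_per = 100, seed = 85)
  bench <- stats::setNames(f$ann$cluster, f$ann$cell_id)
  rand_cb <- function(mat, cells, seed) {
    with_seed <- function(s, code) { set.seed(s); code }
    with_seed(seed, stats::setNames(sample(paste0("R", 1:3),
                                           length(cells),
                                           replace = TRUE), cells))
  }
  rep_ <- downsample_robustness(f$mat, bench, rand_cb, fractions = 0.5,
                                n_reps = 10, seed = 2)
  expect_lt(mean(rep_$nmi), 0.05)
})

test_that("sampling stream is seeded and reproducible", {
  f <- marker_fixture(n_clusters = 2, n_per = 50, seed = 86)
  bench <- stats::setNames(f$ann$cluster, f$ann$cell_id)
  cb <- make_kmeans_callback(k = 2, n_pcs = 5)
  r1 <- downsample_robustness(f$mat, bench, cb, fractions = 0.5,
                              n_reps = 3, seed = 7)
  r2 <- downsample_robustness(f$mat, bench, cb, fractions = 0.5,
                              n_reps = 3, seed = 7)
  expect_identical(r1, r2)
})

test_that("leave-one-patient-out produces one row per patient", {
  cl <- data.frame(name = c("A", "B"), lineage = "T/NK", n_cells = 150)
  cl$patient_probs <- replicate(2, c(P1 = 0.4, P2 = 0.3, P3 = 0.3),
                                simplify = FALSE)
  cfg <- sim_config(n_genes = 60, clusters = cl,
                    markers = data.frame(
                      cluster = rep(c("A", "B"), each = 8),
                      gene = sprintf("G%04d", 1:16), fold_change = 8),
                    baseline_mean = 2, seed = 87)
  sim <- simulate_cells(cfg)
  sim$mat <- normalize_counts(sim$mat)
  bench <- stats::setNames(sim$ann$cluster, sim$ann$cell_id)
  cb <- make_kmeans_callback(k = 2)
  rep_ <- leave_one_patient_out(sim$mat, sim$ann, bench, cb, seed = 1)
  expect_equal(nrow(rep_), 3L)
  expect_setequal(rep_$condition, c("P1", "P2", "P3"))
  expect_true(all(rep_$nmi >= 0.9))   # balanced shared clusters
  # single patient is refused
  ann1 <- sim$ann; ann1$patient <- "P1"
  expect_error(leave_one_patient_out(sim$mat, ann1, bench, cb), "patients")
})

test_that("summarize_robustness aggregates mean and sd", {
  rep_ <- data.frame(protocol = "downsample",
                     condition = rep(c("0.5", "0.25"), each = 4),
                     replicate = rep(1:4, 2), n_cells = 10,
                     nmi = c(1, 1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2))
  s <- summarize_robustness(rep_)
  expect_equal(s$mean_nmi[s$condition == "0.5"], 0.85)
  expect_equal(s$n, c(4, 4))
})
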