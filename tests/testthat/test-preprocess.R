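test_that("qc_filter keeps exactly the in-bounds cells, inclusively", {
  # 5 genes incl one MT gene; craft per-cell gene counts around the bounds
  thr <- qc_thresholds(min_genes = 2, max_genes = 4,
                       min_pct_mito = 1, max_pct_mito = 12)
  m <- toy_counts()
  st <- cell_qc_stats(m)
  keep_truth <- st$n_genes_detected >= 2 & st$n_genes_detected <= 4 &
    st$pct_mito >= 1 & st$pct_mito <= 12
  expect_true(any(keep_truth) && !all(keep_truth))
  out <- qc_filter(m, thr)
  expect_identical(colnames(out), colnames(m)[keep_truth])
  expect_identical(rownames(out), rownames(m))

  # boundary: a cell at exactly min_genes is kept, one below is dropped
  m2 <- Matrix::Matrix(rbind(A = c(1, 1), B = c(1, 0), `MT-X` = c(1, 1)),
                       sparse = TRUE)
  colnames(m2) <- c("at_bound", "below")
  out2 <- qc_filter(m2, qc_thresholds(3, 10, 1, 99))
  expect_identical(colnames(out2), "at_bound")

  # all cells in bounds: identity
  out3 <- qc_filter(m, qc_thresholds(1, 10, 0.5, 99))
  expect_equal(as.matrix(out3), as.matrix(m))

  expect_error(qc_filter(m[1:4, ], thr), "mitochondrial")
  expect_warning(qc_filter(m, qc_thresholds(100, 200, 1, 15)), "no cells")
  expect_error(qc_thresholds(min_genes = 10, max_genes = 5), "min_genes")
})

test_that("qc_filter is idempotent and monotone in the thresholds", {
  sim <- simulate_perturbation_experiment(small_sim_config(seed = 3))
  thr <- qc_thresholds(150, 400, 1, 15)
  once <- qc_filter(sim$counts, thr)
  twice <- qc_filter(once, thr)
  expect_identical(colnames(twice), colnames(once))
  wider <- qc_filter(sim$counts, qc_thresholds(100, 500, 0.5, 25))
  expect_true(all(colnames(once) %in% colnames(wider)))
  rep <- attr(once, "qc_report")
  expect_equal(rep$n_before, ncol(sim$counts))
  expect_equal(rep$n_after, ncol(once))
})

test_that("normalisation matches hand arithmetic and is scale invariant", {
  m <- Matrix::Matrix(matrix(c(1, 2, 7, 0, 5, 5, 2, 0, 0), nrow = 3,
                             dimnames = list(paste0("g", 1:3),
                                             paste0("c", 1:3))),
                      sparse = TRUE)
  n <- normalise_log(m, target_sum = 100)
  expect_equal(as.matrix(n),
               log1p(100 * sweep(as.matrix(m), 2, c(10, 10, 2), "/")),
               ignore_attr = TRUE)
  # zeros stay zero; a single-gene cell absorbs the full target sum
  expect_equal(n["g1", "c3"], log1p(100))
  expect_equal(n["g3", "c3"], 0)
  # doubling a cell's counts leaves its normalised vector unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(as.matrix(normalise_log(m2, 100))[, 1],
               as.matrix(n)[, 1])
  m3 <- m; m3[, 2] <- 0
  expect_error(normalise_log(m3), "zero total")
})

test_that("clustering separates planted populations and respects its contracts", {
  tp <- two_pop_counts(n_per = 60)
  norm <- normalise_log(tp$counts)
  cl <- cluster_cells(norm, resolution = 1, seed = 1, n_hvg = 30,
                      n_pcs = 5, k = 10)
  expect_identical(names(cl), colnames(norm))
  # >= 99% purity against planted truth
  purity <- sum(apply(table(cl, tp$truth), 1, max)) / length(cl)
  expect_gte(purity, 0.99)

  # determinism and permutation invariance (up to relabelling)
  cl2 <- cluster_cells(norm, resolution = 1, seed = 1, n_hvg = 30,
                       n_pcs = 5, k = 10)
  expect_identical(cl, cl2)
  perm <- sample(ncol(norm))
  clp <- cluster_cells(norm[, perm], resolution = 1, seed = 1,
                       n_hvg = 30, n_pcs = 5, k = 10)
  tab <- table(cl[colnames(norm)[perm]], clp)
  expect_equal(sum(apply(tab, 1, max)), length(cl))

  # resolution weakly increases the cluster count
  lo <- cluster_cells(norm, resolution = 0.05, seed = 1, n_hvg = 30,
                      n_pcs = 5, k = 10)
  hi <- cluster_cells(norm, resolution = 2, seed = 1, n_hvg = 30,
                      n_pcs = 5, k = 10)
  expect_lte(nlevels(lo), nlevels(hi))

  # a single homogeneous population at low resolution stays one cluster
  hom <- two_pop_counts(n_per = 60, shift_genes = 0)
  cl1 <- cluster_cells(normalise_log(hom$counts), resolution = 0.01,
                       seed = 1, n_hvg = 30, n_pcs = 5, k = 15)
  expect_equal(nlevels(cl1), 1L)

  expect_error(cluster_cells(norm[, 1, drop = FALSE]), "at least 2")
  expect_error(cluster_cells(norm, k = ncol(norm)), "neighbourhood")
})

test_that("cluster-then-annotate recovers planted populations above 90% purity", {
  for (s in c(2, 13)) {
    sim <- simulate_perturbation_experiment(
      small_sim_config(seed = s, n_cells = 700))
    norm <- normalise_log(sim$counts)
    cl <- cluster_cells(norm, seed = s)
    ann <- annotate_clusters(cl, norm)
    pans <- perturbEHT:::annotation_panel(ann$cluster_labels)
    cell_pan <- pans[as.character(cl)]
    truth <- sim$truth$cells$population[match(names(cl),
                                              sim$truth$cells$barcode)]
    expect_gte(mean(cell_pan == truth), 0.90)
  }
})

test_that("annotation labels clusters by their marker panels", {
  sim <- simulate_perturbation_experiment(small_sim_config(seed = 5))
  norm <- normalise_log(sim$counts)
  truth <- factor(sim$truth$cells$population)
  names(truth) <- sim$truth$cells$barcode
  ann <- annotate_clusters(truth, norm)
  expect_equal(unname(ann$cluster_labels[c("arterial", "venous", "EHT")]),
               c("arterial", "venous", "EHT"))
  expect_equal(colnames(ann$evidence), unlist(default_marker_panels()),
               ignore_attr = TRUE)

  # planted EHT program (RUNX1/CD44 high, pan-endothelial lowered) wins EHT
  expect_gt(ann$scores["EHT", "EHT"], ann$scores["EHT", "arterial"])

  # exact tie goes to the first panel in priority order
  flat <- Matrix::Matrix(matrix(1, 6, 8,
                                dimnames = list(unlist(default_marker_panels()),
                                                paste0("c", 1:8))),
                         sparse = TRUE)
  cl <- factor(rep(1:2, each = 4)); names(cl) <- colnames(flat)
  ann_tie <- annotate_clusters(cl, flat)
  expect_true(all(startsWith(ann_tie$cluster_labels, "arterial")))

  expect_error(annotate_clusters(truth, norm[!rownames(norm) %in% "GJA4", ]),
               "GJA4")
  expect_error(annotate_clusters(truth, norm, panels = list()), "non-empty")
})
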