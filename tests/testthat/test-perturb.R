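# A small deterministic "experiment" for contract-level checks: two
# libraries forming one line, identical expression, hand-set guides.
line_fixture <- function(mean_b = 5) {
  genes <- c("T1", "T2", "BG")
  cells <- sprintf("c%02d", 1:12)
  set.seed(99)
  m <- matrix(rpois(36, 5), 3, dimnames = list(genes, cells))
  m["BG", ] <- rpois(12, mean_b)
  counts <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  metadata <- data.frame(
    barcode = cells,
    library = rep(c("L_AGM", "L_AGM_DOX"), each = 6),
    line = "AGM", dox = rep(c(FALSE, TRUE), each = 6),
    stringsAsFactors = FALSE)
  assignment <- data.frame(
    barcode = cells, n_guides = 2L,
    guides = "T1_g1;T2_g1", targets = "T1;T2",
    keep = TRUE, reason = "kept", stringsAsFactors = FALSE)
  list(counts = counts, metadata = metadata, assignment = assignment)
}

test_that("activation log2 ratios are zero for identical means and flag missing cells", {
  fx <- line_fixture()
  norm <- normalise_log(fx$counts, target_sum = 100)
  # same distribution +-DOX: ratio near 0 (exactly 0 when means match)
  m <- as.matrix(fx$counts)
  m[, 7:12] <- m[, 1:6]
  eq <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  act <- activation_matrix(normalise_log(eq, 100), fx$metadata,
                           fx$assignment, targets = c("T1", "T2"))
  expect_equal(unname(act$log2_ratio[, "AGM"]), c(0, 0), tolerance = 1e-12)

  # a target with zero eligible cells is missing, not zero
  asn <- fx$assignment
  asn$targets <- "T1"
  act2 <- activation_matrix(norm, fx$metadata, asn,
                            targets = c("T1", "T2"))
  expect_true(all(is.na(act2$means["T2", ])))
  expect_true(all(act2$missing["T2", ]))
  expect_error(activation_matrix(norm, fx$metadata, fx$assignment,
                                 targets = "T9"), "absent")
})

test_that("composition testing matches the exact oracle and rejects degenerate input", {
  meta <- data.frame(
    cluster = rep(c("A", "B"), c(10, 10)),
    library = c(rep("L1", 10), rep("L2", 10)))
  res <- compare_cluster_composition(meta)
  # 2x2 table (10,0 / 0,10): exact-test fallback, hypergeometric tail
  expect_equal(res$table$p[res$table$cluster == "A"],
               enum_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(res$table$p[res$table$cluster == "A"], 2 / choose(20, 10),
               tolerance = 1e-9)
  expect_true(all(abs(colSums(res$proportions) - 1) < 1e-9))

  expect_error(compare_cluster_composition(
    data.frame(cluster = c("A", "B"), library = "L1")), "two libraries")
  expect_error(compare_cluster_composition(
    data.frame(cluster = "A", library = c("L1", "L2"))), "two clusters")
  expect_error(compare_cluster_composition(meta, focal_pair = c("L1", "L9")),
               "not present")

  # planted arterial expansion flags the arterial cluster only
  sim <- simulate_perturbation_experiment(sim_config(seed = 61))
  truth <- sim$truth$cells
  truth$cluster <- truth$population
  comp <- compare_cluster_composition(
    truth, focal_pair = c("iSAM_AGM_DOX", "iSAM_NT_DOX"))
  expect_identical(comp$table$cluster[comp$table$flagged], "arterial")
})

test_that("guide enrichment matches the brute-force hypergeometric oracle", {
  # hand 2x2: carriers 3 in / 7 out, non-carriers 9 in / 1 out
  asn <- data.frame(
    barcode = sprintf("c%02d", 1:20), n_guides = 2L,
    guides = "x", targets = c(rep("T1", 10), rep("", 10)),
    keep = TRUE, reason = "kept", stringsAsFactors = FALSE)
  in_cluster <- sprintf("c%02d", c(1:3, 11:19))
  res <- guide_enrichment(asn, in_cluster)
  expect_equal(res$p, enum_fisher_p(3, 7, 9, 1), tolerance = 1e-12)
  expect_equal(res$in_cluster_carrier, 3)
  expect_equal(res$out_cluster_noncarrier, 1)
  # Haldane-corrected odds ratio when a cell is zero
  asn2 <- asn; asn2$targets <- c(rep("T1", 10), rep("", 10))
  res2 <- guide_enrichment(asn2, sprintf("c%02d", 1:10))
  expect_equal(res2$odds_ratio,
               (10.5 * 10.5) / (0.5 * 0.5))
  expect_error(guide_enrichment(asn, "c99"), "no kept cells")

  # identical carrier fraction in and out of the cluster: near-null
  asn3 <- asn
  asn3$targets <- rep(c("T1", ""), 10)
  res3 <- guide_enrichment(asn3, sprintf("c%02d", 1:10))
  expect_equal(res3$p, 1, tolerance = 1e-9)
  expect_false(res3$flagged)
})

test_that("differential expression recovers the planted effector and honours contracts", {
  # 6-cell toy: p equals the exhaustive permutation oracle
  m <- Matrix::Matrix(matrix(c(8, 1, 9, 2, 10, 3, 1, 4, 2, 5, 3, 6), 2,
                             dimnames = list(c("g1", "g2"),
                                             sprintf("c%d", 1:6))),
                      sparse = TRUE)
  norm <- normalise_log(m, 10)
  de <- differential_expression(norm, c("c1", "c2", "c3"),
                                c("c4", "c5", "c6"))
  for (g in c("g1", "g2")) {
    expect_equal(de$p[de$gene == g],
                 perm_rank_sum_p(as.matrix(norm)[g, 1:3],
                                 as.matrix(norm)[g, 4:6]),
                 tolerance = 1e-12)
  }
  expect_error(differential_expression(norm, c("c1", "c2", "c3"),
                                       c("c3", "c4", "c5")), "overlap")
  expect_error(differential_expression(norm, c("c1", "c2"),
                                       c("c4", "c5", "c6")), "at least 3")

  # null contrast: adjusted p flags nothing
  tp <- two_pop_counts(n_per = 40, n_genes = 30, shift_genes = 0, seed = 3)
  nn <- normalise_log(tp$counts)
  de0 <- differential_expression(nn, colnames(nn)[1:40],
                                 colnames(nn)[41:80])
  expect_equal(sum(de0$p_adj < 0.05), 0)
})

test_that("BH adjustment equals the direct definition", {
  set.seed(5)
  p <- c(runif(20), runif(5)^4)
  expect_equal(stats::p.adjust(p, "BH"), direct_bh(p), tolerance = 1e-12)
})

test_that("over-representation ranks planted sets first and calibrates on random sets", {
  universe <- sprintf("G%03d", 1:200)
  planted <- universe[1:15]
  sets <- list(planted = planted,
               half = universe[11:40],
               random = universe[101:130])
  res <- gene_set_overrepresentation(planted, sets, universe)
  expect_equal(res$set[1], "planted")
  expect_equal(res$p[res$set == "planted"],
               enum_hyper_upper_p(15, 15, 200, 15), tolerance = 1e-12)
  # p-values match the enumeration oracle for partial overlap too
  expect_equal(res$p[res$set == "half"],
               enum_hyper_upper_p(5, 30, 200, 15), tolerance = 1e-12)

  expect_warning(
    gene_set_overrepresentation(planted,
                                c(sets, list(alien = c("ZZ1", "ZZ2"))),
                                universe),
    "skipped")
  expect_error(gene_set_overrepresentation(c(planted, "NOT_HERE"), sets,
                                           universe), "universe")

  # null calibration: random draws give roughly uniform p
  set.seed(7)
  ps <- replicate(200, {
    drawn <- sample(universe, 15)
    gene_set_overrepresentation(drawn, sets["random"], universe)$p
  })
  expect_gt(mean(ps > 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.15)
})
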