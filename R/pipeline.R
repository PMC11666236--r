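#' Run the full perturbation analysis on a simulated experiment
#'
#' Chains the module surfaces end to end on a
#' [simulate_perturbation_experiment()] result: optional QC, normalisation,
#' clustering, marker-panel annotation, guide detection and
#' library-specific filtering, target activation, cluster-composition
#' testing (on panel-level cluster labels), guide enrichment within the
#' arterial cells of the induced activation library, and differential
#' expression of arterial cells between the induced activation and
#' control libraries.
#'
#' @param sim A `perturb_sim` object.
#' @param min_umi Guide detection threshold used by the pipeline (the
#'   simulated capture chemistry separates true from ambient counts at 3).
#' @param qc Optional [qc_thresholds()] applied before normalisation.
#' @param resolution,seed Clustering parameters (seed defaults to the
#'   simulation seed).
#' @param alpha Significance level shared by the tests.
#' @return List with `norm`, `clusters`, `annotation`, `assignment`,
#'   `activation`, `composition`, `enrichment`, `de`, `metadata` (kept
#'   cells with panel-level cluster labels).
#' @export
run_perturbation_pipeline <- function(sim, min_umi = 3, qc = NULL,
                                      resolution = 1,
                                      seed = sim$config$seed,
                                      alpha = 0.05) {
  counts <- sim$counts
  if (!is.null(qc)) counts <- qc_filter(counts, qc)
  norm <- normalise_log(counts)
  clusters <- cluster_cells(norm, resolution = resolution, seed = seed)
  ann <- annotate_clusters(clusters, norm)
  panel_of_cell <- annotation_panel(ann$cluster_labels)[as.character(clusters)]
  names(panel_of_cell) <- names(clusters)

  assignment <- detect_guides(sim$guide_counts, sim$guide_library,
                              min_umi = min_umi,
                              all_barcodes = colnames(sim$counts))
  line_of <- stats::setNames(sim$metadata$line, sim$metadata$barcode)
  assignment <- filter_cells_by_guides(assignment, line_of)

  activation <- activation_matrix(norm, sim$metadata, assignment,
                                  targets = sim$config$targets$gene)

  kept <- assignment$barcode[assignment$keep]
  meta <- sim$metadata[sim$metadata$barcode %in% kept &
                         sim$metadata$barcode %in% colnames(counts), ,
                       drop = FALSE]
  meta$cluster <- unname(panel_of_cell[meta$barcode])
  labs <- sim$config$library_labels
  composition <- compare_cluster_composition(
    meta, alpha = alpha, focal_pair = c(labs[4], labs[2]))

  agm_dox <- meta$barcode[meta$library == labs[4]]
  arterial <- meta$barcode[meta$cluster == "arterial"]
  enrichment <- guide_enrichment(
    assignment[assignment$barcode %in% agm_dox, , drop = FALSE],
    in_cluster = intersect(arterial, agm_dox), alpha = alpha)

  de <- differential_expression(
    norm,
    cells_a = intersect(arterial, agm_dox),
    cells_b = intersect(arterial, meta$barcode[meta$library == labs[2]]))

  list(norm = norm, clusters = clusters, annotation = ann,
       assignment = assignment, activation = activation,
       composition = composition, enrichment = enrichment, de = de,
       metadata = meta)
}
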