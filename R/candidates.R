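#' Marker statistics for one group against the rest
#'
#' Per-gene two-sided Wilcoxon rank-sum test on normalised expression of
#' the group versus all other cells, with a log2 fold-change of group
#' means and Benjamini-Hochberg adjustment. Rows are ordered by adjusted
#' p, then by decreasing absolute effect.
#'
#' @param norm Normalised gene-by-cell matrix.
#' @param labels Per-cell population labels (aligned with columns or named
#'   by barcode).
#' @param group Label of the focal group (default `"aHEC"`).
#' @param min_cells Minimum cells required in each side.
#' @param pseudocount Stabiliser for the fold-change of means.
#' @return `data.frame`: `gene`, `lfc`, `u`, `p`, `p_adj`.
#' @export
find_markers <- function(norm, labels, group = "aHEC", min_cells = 3,
                         pseudocount = 1e-4) {
  if (!is.null(names(labels))) labels <- unname(labels[colnames(norm)])
  if (length(labels) != ncol(norm))
    stop("labels must cover every cell")
  idx_a <- which(labels == group)
  idx_b <- which(labels != group)
  if (length(idx_a) < min_cells || length(idx_b) < min_cells)
    stop("need at least ", min_cells, " cells in the group and the rest")
  st <- rank_sum_scan(norm, idx_a, idx_b)
  lfc <- log2_fc_means(norm, idx_a, idx_b, pseudocount)
  out <- data.frame(gene = rownames(norm), lfc = unname(lfc),
                    u = st[, "u"], p = st[, "p"],
                    p_adj = p.adjust(st[, "p"], method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p_adj, -abs(out$lfc)), , drop = FALSE]
}

#' Fraction of cells in which a gene is detected
#'
#' Detection means a raw count above zero.
#'
#' @param counts Gene-by-cell count matrix.
#' @param cells Barcodes (or logical/integer index) of the cell subset.
#' @param gene Gene symbol; absence is an error, not zero.
#' @return Fraction in `[0, 1]`.
#' @export
fraction_detected <- function(counts, cells, gene) {
  if (!gene %in% rownames(counts))
    stop("gene not present in the matrix: ", gene)
  sub <- counts[gene, cells, drop = FALSE]
  if (ncol(sub) == 0) stop("empty cell subset")
  sum(sub > 0) / ncol(sub)
}

#' Select candidate transcription factors across the dataset pair
#'
#' Reproduces the cross-dataset target selection: significant markers of
#' the in vivo haemogenic endothelium (aHEC versus the other in vivo
#' populations), restricted to transcription factors, detected in more
#' than `frac_hi` of aHEC cells and in less than `frac_lo` of the in
#' vitro-derived endothelium (both inequalities strict). Detection
#' fractions are computed on raw counts within each dataset separately;
#' normalisation affects only the marker ranking.
#'
#' @param panel A reference panel: list with `in_vivo` and `in_vitro`,
#'   each holding `counts` and `labels` (`barcode`, `population`), e.g.
#'   from [simulate_reference_panel()].
#' @param tf_list Character vector of transcription-factor symbols
#'   (defaults to `panel$tf_list`).
#' @param frac_hi,frac_lo Detection-fraction gates (strict).
#' @param alpha BH-adjusted marker significance cutoff.
#' @param markers Optional precomputed [find_markers()] table.
#' @return `data.frame` of class `candidate_table`: `gene`, `lfc`,
#'   `marker_p`, `marker_p_adj`, `is_TF`, `frac_aHEC`, `frac_IVD_Endo`,
#'   `selected`, ordered as the marker table.
#' @export
select_candidates <- function(panel, tf_list = NULL,
                              frac_hi = 0.50, frac_lo = 0.25,
                              alpha = 0.05, markers = NULL) {
  if (frac_hi <= 0 || frac_hi >= 1 || frac_lo <= 0 || frac_lo >= 1)
    stop("fraction thresholds must lie in (0, 1)")
  tf_list <- tf_list %||% panel$tf_list
  if (is.null(tf_list) || !length(tf_list))
    stop("tf_list must be non-empty")
  vivo <- panel$in_vivo
  vitro <- panel$in_vitro
  if (is.null(markers)) {
    norm <- normalise_log(vivo$counts)
    labels <- stats::setNames(vivo$labels$population, vivo$labels$barcode)
    markers <- find_markers(norm, labels, group = "aHEC")
  }
  ahec <- vivo$labels$barcode[vivo$labels$population == "aHEC"]
  endo <- vitro$labels$barcode[vitro$labels$population == "IVD_Endo"]
  frac_ahec <- Matrix::rowMeans(vivo$counts[, ahec, drop = FALSE] > 0)
  frac_endo_all <- Matrix::rowMeans(vitro$counts[, endo, drop = FALSE] > 0)
  genes <- markers$gene
  frac_endo <- frac_endo_all[genes]
  out <- data.frame(
    gene = genes,
    lfc = markers$lfc,
    marker_p = markers$p,
    marker_p_adj = markers$p_adj,
    is_TF = genes %in% tf_list,
    frac_aHEC = unname(frac_ahec[genes]),
    frac_IVD_Endo = unname(frac_endo),
    row.names = NULL, stringsAsFactors = FALSE)
  out$selected <- !is.na(out$frac_IVD_Endo) &
    out$marker_p_adj < alpha & out$is_TF &
    out$frac_aHEC > frac_hi & out$frac_IVD_Endo < frac_lo
  class(out) <- c("candidate_table", class(out))
  out
}
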