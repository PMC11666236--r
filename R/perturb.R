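#' Target activation matrix across libraries
#'
#' Mean normalised expression of each target per library, restricted in
#' the activation (AGM) libraries to cells carrying at least one guide for
#' that target (controllable via `carriers_only`), with the +DOX entry of
#' each line expressed as the log2 ratio to its matched -DOX entry using a
#' small pseudocount. Targets with zero eligible cells in a library are
#' flagged missing (`NA`), never zero.
#'
#' @param norm Normalised gene-by-cell matrix.
#' @param metadata `data.frame` with `barcode`, `library`, `line`
#'   (`NT`/`AGM`), `dox` (logical).
#' @param assignment Decided guide assignment (kept cells are used).
#' @param targets Target gene symbols; all must be in the matrix.
#' @param carriers_only Restrict AGM means to carrier cells (default).
#' @param pseudocount Added to both means before the ratio (default
#'   `1/target_sum` of the normalisation).
#' @param lfc_threshold Absolute log2 ratio above which a target is called
#'   activated in the induced activation library.
#' @return List of class `activation_profile`: `means` and `n_cells`
#'   (target x library), `log2_ratio` (target x line), `activated`
#'   (logical per target, induced AGM library), `missing`.
#' @export
activation_matrix <- function(norm, metadata, assignment, targets,
                              carriers_only = TRUE, pseudocount = 1e-4,
                              lfc_threshold = 0.5) {
  absent <- setdiff(targets, rownames(norm))
  if (length(absent))
    stop("targets absent from the matrix: ", paste(absent, collapse = ", "))
  kept <- assignment$barcode[!is.na(assignment$keep) & assignment$keep]
  meta <- metadata[metadata$barcode %in% kept &
                     metadata$barcode %in% colnames(norm), , drop = FALSE]
  libs <- unique(metadata$library)
  means <- matrix(NA_real_, length(targets), length(libs),
                  dimnames = list(targets, libs))
  ncell <- matrix(0L, length(targets), length(libs),
                  dimnames = list(targets, libs))
  lin <- expm1(as.matrix(norm[targets, , drop = FALSE]))
  for (lib in libs) {
    lib_cells <- meta$barcode[meta$library == lib]
    lib_line <- metadata$line[match(lib, metadata$library)]
    for (tg in targets) {
      cells <- lib_cells
      if (carriers_only && lib_line == "AGM") {
        carr <- target_carriers(assignment, tg)
        cells <- intersect(lib_cells, carr)
      }
      ncell[tg, lib] <- length(cells)
      if (length(cells))
        means[tg, lib] <- mean(lin[tg, cells])
    }
  }
  lines <- unique(metadata$line)
  lr <- matrix(NA_real_, length(targets), length(lines),
               dimnames = list(targets, lines))
  for (ln in lines) {
    lib_dox <- unique(metadata$library[metadata$line == ln & metadata$dox])
    lib_ctl <- unique(metadata$library[metadata$line == ln & !metadata$dox])
    if (length(lib_dox) != 1 || length(lib_ctl) != 1) next
    lr[, ln] <- log2((means[, lib_dox] + pseudocount) /
                       (means[, lib_ctl] + pseudocount))
  }
  agm_col <- if ("AGM" %in% lines) "AGM" else lines[1]
  out <- list(means = means, n_cells = ncell, log2_ratio = lr,
              activated = !is.na(lr[, agm_col]) &
                lr[, agm_col] > lfc_threshold,
              missing = is.na(means),
              lfc_threshold = lfc_threshold)
  class(out) <- "activation_profile"
  out
}

# Exact (Fisher) two-sided p for a contingency table; the single entry
# point for every exact test in the package.
exact_p_2x2 <- function(tab) fisher.test(tab)$p.value

# 2xL association test: chi-square, or exact when any expected count is
# at or below 5 (inclusive boundary, so sparse tables always go exact).
test_2xL <- function(tab) {
  suppressWarnings({
    cs <- chisq.test(tab, correct = FALSE)
    if (any(cs$expected <= 5)) exact_p_2x2(tab) else cs$p.value
  })
}

#' Test cluster-composition shifts across libraries
#'
#' For each cluster, tests the association between membership in that
#' cluster (versus the rest) and library of origin: chi-square on the
#' 2 x L table, replaced by the exact test when any expected count is at
#' or below 5; BH adjustment across clusters. A cluster is flagged when its
#' adjusted p is below `alpha` and, if a focal library pair is given, its
#' proportion is expanded at least `fold_threshold`-fold in the first
#' member of the pair relative to the second (population fractions are
#' compositional, so without the direction gate every cluster shifted by
#' renormalisation would be flagged alongside the expanded one).
#'
#' @param metadata `data.frame` with one row per cell.
#' @param cluster_col,library_col Column names.
#' @param alpha BH-adjusted significance level.
#' @param focal_pair Optional `c(numerator_library, denominator_library)`
#'   for the expansion fold and direction gate.
#' @param fold_threshold Minimum expansion fold for flagging.
#' @return List of class `composition_result`: `table` (per-cluster p,
#'   adjusted p, fold change, flag), `counts`, `proportions` (columns sum
#'   to 1).
#' @export
compare_cluster_composition <- function(metadata, cluster_col = "cluster",
                                        library_col = "library",
                                        alpha = 0.05, focal_pair = NULL,
                                        fold_threshold = 1.25) {
  tab <- table(metadata[[cluster_col]], metadata[[library_col]])
  if (ncol(tab) < 2) stop("at least two libraries are required")
  if (nrow(tab) < 2) stop("at least two clusters are required")
  props <- sweep(tab, 2, colSums(tab), "/")
  p <- vapply(rownames(tab), function(k) {
    m <- rbind(in_cluster = tab[k, ], rest = colSums(tab) - tab[k, ])
    test_2xL(m)
  }, numeric(1))
  p_adj <- p.adjust(p, method = "BH")
  fold <- rep(NA_real_, nrow(tab))
  if (!is.null(focal_pair)) {
    if (!all(focal_pair %in% colnames(tab)))
      stop("focal_pair libraries not present: ",
           paste(setdiff(focal_pair, colnames(tab)), collapse = ", "))
    fold <- props[, focal_pair[1]] / props[, focal_pair[2]]
  }
  flagged <- p_adj < alpha &
    (if (is.null(focal_pair)) TRUE else !is.na(fold) & fold >= fold_threshold)
  out <- list(table = data.frame(cluster = rownames(tab),
                                 p = unname(p), p_adj = unname(p_adj),
                                 fold_change = unname(fold),
                                 flagged = unname(flagged),
                                 row.names = NULL,
                                 stringsAsFactors = FALSE),
              counts = tab, proportions = props)
  class(out) <- "composition_result"
  out
}

#' Guide enrichment within a cluster
#'
#' Per target (guides pooled; or per guide), a Fisher exact test on the
#' 2 x 2 table of carrying the target versus membership in the named
#' cluster, over the kept cells supplied. Odds ratios are the sample
#' cross-product with Haldane correction (+0.5 on every cell) when any
#' cell is zero; BH adjustment across targets. Flagged entries require
#' adjusted p below `alpha` and an odds ratio above 1 (enrichment).
#'
#' @param assignment Decided guide assignment restricted to the cells of
#'   interest (e.g. the induced activation library).
#' @param in_cluster Barcodes of the cluster's cells, or a logical vector
#'   named by barcode.
#' @param grouping `"by_target"` (default) or `"by_guide"`.
#' @param alpha BH-adjusted significance level.
#' @return `data.frame` of class `enrichment_result`: `unit`, the 2 x 2
#'   counts, `odds_ratio`, `p`, `p_adj`, `flagged`.
#' @export
guide_enrichment <- function(assignment, in_cluster,
                             grouping = c("by_target", "by_guide"),
                             alpha = 0.05) {
  grouping <- match.arg(grouping)
  kept <- assignment[!is.na(assignment$keep) & assignment$keep, ,
                     drop = FALSE]
  if (is.logical(in_cluster))
    in_cluster <- names(in_cluster)[in_cluster]
  member <- kept$barcode %in% in_cluster
  if (!any(member)) stop("the cluster contains no kept cells")
  col <- if (grouping == "by_target") "targets" else "guides"
  sets <- lapply(kept[[col]], split_ids)
  units <- sort(unique(unlist(sets)))
  rows <- lapply(units, function(u) {
    carrier <- vapply(sets, function(s) u %in% s, logical(1))
    a <- sum(carrier & member); b <- sum(carrier & !member)
    c2 <- sum(!carrier & member); d <- sum(!carrier & !member)
    or <- if (min(a, b, c2, d) == 0) {
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c2 + 0.5))
    } else a * d / (b * c2)
    p <- exact_p_2x2(matrix(c(a, c2, b, d), 2))
    data.frame(unit = u, in_cluster_carrier = a, out_cluster_carrier = b,
               in_cluster_noncarrier = c2, out_cluster_noncarrier = d,
               odds_ratio = or, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$flagged <- out$p_adj < alpha & out$odds_ratio > 1
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Differential expression between two cell sets
#'
#' Per-gene two-sided Wilcoxon rank-sum test (A versus B) on normalised
#' expression with BH adjustment and a log2 fold-change of means; rows
#' ordered by adjusted p, then decreasing absolute effect.
#'
#' @param norm Normalised gene-by-cell matrix.
#' @param cells_a,cells_b Disjoint barcode sets, each of size >= 3.
#' @param pseudocount Fold-change stabiliser.
#' @return `data.frame` of class `de_table`: `gene`, `lfc`, `p`, `p_adj`,
#'   `direction`.
#' @export
differential_expression <- function(norm, cells_a, cells_b,
                                    pseudocount = 1e-4) {
  if (length(intersect(cells_a, cells_b)))
    stop("cell sets A and B overlap")
  if (length(cells_a) < 3 || length(cells_b) < 3)
    stop("each cell set needs at least 3 cells")
  idx_a <- match(cells_a, colnames(norm))
  idx_b <- match(cells_b, colnames(norm))
  if (anyNA(idx_a) || anyNA(idx_b))
    stop("cells missing from the matrix")
  st <- rank_sum_scan(norm, idx_a, idx_b)
  lfc <- log2_fc_means(norm, idx_a, idx_b, pseudocount)
  out <- data.frame(gene = rownames(norm), lfc = unname(lfc),
                    p = st[, "p"],
                    p_adj = p.adjust(st[, "p"], method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$direction <- ifelse(out$lfc > 0, "up", "down")
  out <- out[order(out$p_adj, -abs(out$lfc)), , drop = FALSE]
  class(out) <- c("de_table", class(out))
  out
}

#' Gene-set over-representation (hypergeometric)
#'
#' Tests each supplied gene set for over-representation of an input gene
#' list within a gene universe; BH adjustment across sets. Sets with no
#' member in the universe are skipped with a warning.
#'
#' @param genes Character vector of genes of interest (e.g. upregulated),
#'   or a [differential_expression()] table from which upregulated genes
#'   at `alpha`/`lfc_min` are taken.
#' @param gene_sets Named list of character vectors (see [read_gmt()]).
#' @param universe Gene universe; must contain all tested genes.
#' @param alpha,lfc_min Thresholds used when `genes` is a DE table.
#' @return `data.frame`: `set`, `n_set`, `n_overlap`, `p`, `p_adj`,
#'   ordered by p.
#' @export
gene_set_overrepresentation <- function(genes, gene_sets, universe,
                                        alpha = 0.05, lfc_min = 0) {
  if (is.data.frame(genes))
    genes <- genes$gene[genes$p_adj < alpha & genes$lfc > lfc_min]
  genes <- unique(genes)
  if (!all(genes %in% universe))
    stop("the universe must contain every tested gene")
  keepable <- vapply(gene_sets, function(s)
    length(intersect(s, universe)) > 0, logical(1))
  if (any(!keepable))
    warning("gene sets with no member in the universe skipped: ",
            paste(names(gene_sets)[!keepable], collapse = ", "))
  gene_sets <- gene_sets[keepable]
  if (!length(gene_sets)) stop("no testable gene sets")
  N <- length(unique(universe))
  k <- length(genes)
  rows <- lapply(names(gene_sets), function(nm) {
    m <- length(intersect(gene_sets[[nm]], universe))
    ov <- length(intersect(gene_sets[[nm]], genes))
    data.frame(set = nm, n_set = m, n_overlap = ov,
               p = phyper(ov - 1, m, N - m, k, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
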