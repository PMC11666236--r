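#' QC thresholds
#'
#' Cell-level quality gates on the number of detected genes and the
#' percentage of counts on mitochondrial genes. Defaults match the
#' standard gates for droplet scRNA-seq of these libraries: 1000-7500
#' genes and 1-15% mitochondrial, both bounds inclusive.
#'
#' @param min_genes,max_genes Inclusive bounds on genes detected per cell.
#' @param min_pct_mito,max_pct_mito Inclusive bounds on the mitochondrial
#'   percentage (0-100 scale).
#' @export
qc_thresholds <- function(min_genes = 1000, max_genes = 7500,
                          min_pct_mito = 1, max_pct_mito = 15) {
  if (min_genes >= max_genes) stop("min_genes must be < max_genes")
  if (min_pct_mito >= max_pct_mito)
    stop("min_pct_mito must be < max_pct_mito")
  list(min_genes = min_genes, max_genes = max_genes,
       min_pct_mito = min_pct_mito, max_pct_mito = max_pct_mito)
}

#' Per-cell QC statistics
#'
#' @param counts Gene-by-cell count matrix.
#' @param mito_pattern Regular expression identifying mitochondrial gene
#'   symbols (GRCh38 convention `^MT-`).
#' @return `data.frame` with `barcode`, `n_genes_detected`, `pct_mito`.
#' @export
cell_qc_stats <- function(counts, mito_pattern = "^MT-") {
  mito <- grepl(mito_pattern, rownames(counts))
  if (!any(mito))
    stop("no mitochondrial genes match pattern '", mito_pattern, "'")
  tot <- Matrix::colSums(counts)
  data.frame(
    barcode = colnames(counts),
    n_genes_detected = Matrix::colSums(counts > 0),
    pct_mito = ifelse(tot > 0,
                      100 * Matrix::colSums(counts[mito, , drop = FALSE]) / tot,
                      0),
    stringsAsFactors = FALSE)
}

#' Filter cells on QC gates
#'
#' Retains exactly the cells whose detected-gene count and mitochondrial
#' percentage fall inside the (inclusive) threshold bounds. The gene set
#' is unchanged. A before/after report is attached as attribute
#' `qc_report`.
#'
#' @param counts Gene-by-cell count matrix.
#' @param thresholds A [qc_thresholds()] list.
#' @param mito_pattern Mitochondrial symbol pattern, see [cell_qc_stats()].
#' @return The filtered matrix.
#' @export
qc_filter <- function(counts, thresholds = qc_thresholds(),
                      mito_pattern = "^MT-") {
  st <- cell_qc_stats(counts, mito_pattern)
  in_genes <- st$n_genes_detected >= thresholds$min_genes &
    st$n_genes_detected <= thresholds$max_genes
  in_mito <- st$pct_mito >= thresholds$min_pct_mito &
    st$pct_mito <= thresholds$max_pct_mito
  keep <- in_genes & in_mito
  if (!any(keep)) warning("no cells pass the QC gates")
  out <- counts[, keep, drop = FALSE]
  attr(out, "qc_report") <- list(
    n_before = ncol(counts), n_after = sum(keep),
    dropped_genes_gate = sum(!in_genes),
    dropped_mito_gate = sum(!in_mito),
    thresholds = thresholds)
  out
}

#' Normalise counts to a common per-cell total and log-transform
#'
#' Each cell is scaled to `target_sum` total counts, then `log1p` is
#' applied. Zero entries stay zero and sparsity is preserved.
#'
#' @param counts Gene-by-cell count matrix (post-QC).
#' @param target_sum Common per-cell total (default 10,000).
#' @return Sparse normalised matrix.
#' @export
normalise_log <- function(counts, target_sum = 1e4) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cells with zero total counts: ",
                          paste(utils::head(colnames(counts)[tot == 0], 5),
                                collapse = ", "))
  scaled <- counts %*% Matrix::Diagonal(x = target_sum / tot)
  out <- log1p(scaled)
  dimnames(out) <- dimnames(counts)
  attr(out, "target_sum") <- target_sum
  methods::as(out, "CsparseMatrix")
}

# Highly variable genes by trend-corrected variance: residual of
# log-variance against a lowess trend on log-mean, so structured genes
# rank above high-mean genes that are merely noisy.
select_hvg <- function(norm, n_hvg) {
  rv <- row_vars(norm)
  rm_ <- Matrix::rowMeans(norm)
  keep <- which(rv > 0 & rm_ > 0)
  if (length(keep) < 2) return(order(rv, decreasing = TRUE)[1])
  lv <- log(rv[keep]); lm_ <- log(rm_[keep])
  fit <- stats::lowess(lm_, lv, f = 0.3)
  resid <- lv - stats::approx(fit$x, fit$y, xout = lm_, rule = 2,
                              ties = "ordered")$y
  keep[order(resid, decreasing = TRUE)[seq_len(min(n_hvg, length(keep)))]]
}

# k-nearest-neighbour index on a PCA embedding, computed block-wise so the
# full distance matrix is never materialised.
knn_index <- function(emb, k, block = 512L) {
  n <- nrow(emb)
  sq <- rowSums(emb^2)
  idx <- matrix(0L, nrow = n, ncol = k)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(emb[rows, , drop = FALSE], emb)
    for (j in seq_along(rows)) {
      o <- order(d2[j, ])
      o <- o[o != rows[j]][seq_len(k)]
      idx[rows[j], ] <- o
    }
  }
  idx
}

#' Cluster cells by graph community detection
#'
#' PCA on scaled highly variable genes, a k-nearest-neighbour graph, and
#' Louvain community detection at the given resolution. Deterministic for
#' a fixed seed.
#'
#' @param norm Normalised gene-by-cell matrix from [normalise_log()].
#' @param resolution Louvain resolution; larger values yield weakly more
#'   clusters.
#' @param seed Integer seed.
#' @param n_hvg Number of highly variable genes used (ranked by
#'   trend-corrected variance).
#' @param n_pcs Number of principal components.
#' @param k Neighbourhood size; must be smaller than the number of cells.
#' @return Factor of cluster labels named by cell barcode.
#' @export
cluster_cells <- function(norm, resolution = 1, seed = 0L,
                          n_hvg = 200L, n_pcs = 10L, k = 15L) {
  n <- ncol(norm)
  if (n < 2) stop("clustering needs at least 2 cells")
  if (k >= n) stop("neighbourhood size k=", k,
                   " must be below the number of cells (", n, ")")
  # canonical cell order makes the partition invariant to column
  # permutation of the input (up to label names)
  ord <- order(colnames(norm))
  norm <- norm[, ord, drop = FALSE]
  set.seed(seed)
  hvg <- select_hvg(norm, n_hvg)
  x <- t(as.matrix(norm[hvg, , drop = FALSE]))
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  n_pcs <- min(n_pcs, ncol(x), n - 1L)
  emb <- prcomp(x, rank. = n_pcs, center = FALSE)$x
  nn <- knn_index(emb, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  out <- factor(igraph::membership(cl))
  names(out) <- colnames(norm)
  out[order(ord)]
}

#' Default marker panels for cluster annotation
#'
#' Panel order is the tie-break priority: arterial (GJA4, DLL4), venous
#' (NRP2, APLNR), then haemogenic/EHT (RUNX1, CD44).
#'
#' @export
default_marker_panels <- function() {
  list(arterial = c("GJA4", "DLL4"),
       venous = c("NRP2", "APLNR"),
       EHT = c("RUNX1", "CD44"))
}

#' Annotate clusters by marker panels
#'
#' Each cluster is labelled by the panel with the highest mean z-scored
#' marker expression; exact ties go to the earlier panel in the priority
#' order. When one panel wins several clusters its label is suffixed
#' (`EHT_1`, `EHT_2`, ...). Clusters whose best panel score does not
#' exceed `min_score` are labelled `endothelial_other`.
#'
#' @param clusters Factor from [cluster_cells()], named by barcode.
#' @param norm Normalised matrix over the same cells.
#' @param panels Named list of marker panels in priority order.
#' @param min_score Minimum winning mean z-score (default `-Inf`: always
#'   assign the best panel).
#' @return List of class `cluster_annotation`: `cluster_labels` (named
#'   character, cluster id to label), `cell_labels` (per cell), `scores`
#'   (cluster x panel mean z-scores), `evidence` (cluster x marker mean
#'   normalised expression).
#' @export
annotate_clusters <- function(clusters, norm,
                              panels = default_marker_panels(),
                              min_score = -Inf) {
  if (length(panels) == 0 || any(!lengths(panels)))
    stop("marker panels must be non-empty")
  markers <- unique(unlist(panels))
  missing <- setdiff(markers, rownames(norm))
  if (length(missing))
    stop("markers absent from the matrix: ",
         paste(missing, collapse = ", "))
  x <- as.matrix(norm[markers, , drop = FALSE])
  mu <- rowMeans(x)
  sdv <- apply(x, 1, sd)
  sdv[sdv == 0] <- 1
  z <- (x - mu) / sdv
  cl_ids <- levels(clusters)
  scores <- matrix(NA_real_, length(cl_ids), length(panels),
                   dimnames = list(cl_ids, names(panels)))
  evidence <- matrix(NA_real_, length(cl_ids), length(markers),
                     dimnames = list(cl_ids, markers))
  for (cid in cl_ids) {
    cells <- names(clusters)[clusters == cid]
    evidence[cid, ] <- rowMeans(x[, cells, drop = FALSE])
    zc <- rowMeans(z[, cells, drop = FALSE])
    scores[cid, ] <- vapply(panels, function(p) mean(zc[p]), numeric(1))
  }
  best <- apply(scores, 1, function(s) which(s == max(s))[1])
  labels <- names(panels)[best]
  labels[scores[cbind(seq_along(best), best)] <= min_score] <-
    "endothelial_other"
  for (lab in unique(labels)) {
    ii <- which(labels == lab)
    if (length(ii) > 1)
      labels[ii] <- paste0(lab, "_", seq_along(ii))
  }
  names(labels) <- cl_ids
  out <- list(cluster_labels = labels,
              cell_labels = unname(labels[as.character(clusters)]),
              scores = scores, evidence = evidence)
  class(out) <- "cluster_annotation"
  out
}

# Panel name behind a (possibly suffixed) annotation label.
annotation_panel <- function(labels, panels = default_marker_panels()) {
  vapply(labels, function(l) {
    hit <- names(panels)[vapply(names(panels), function(p)
      l == p || startsWith(l, paste0(p, "_")), logical(1))]
    if (length(hit)) hit[1] else "endothelial_other"
  }, character(1))
}
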