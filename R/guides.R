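#' Detect guides per cell from capture counts
#'
#' A guide is called detected in a cell when its capture count reaches
#' `min_umi`. Detected targets are the target genes of the detected
#' targeting guides. The keep/drop decision is left undecided; see
#' [filter_cells_by_guides()].
#'
#' Cells present in the expression matrix but absent from the capture
#' matrix can be supplied via `all_barcodes`; they are treated as
#' zero-guide cells.
#'
#' @param capture Guide-by-cell capture count matrix (rows = guide ids).
#' @param library Guide library `data.frame` (guide_id, target, class).
#' @param min_umi Detection threshold (>= 1).
#' @param all_barcodes Optional full barcode universe to align to.
#' @return `data.frame` of class `guide_assignment`: `barcode`,
#'   `n_guides`, `guides` (`;`-separated), `targets` (`;`-separated
#'   targets of targeting guides), `keep` (NA), `reason` ("undecided").
#' @export
detect_guides <- function(capture, library, min_umi = 1,
                          all_barcodes = NULL) {
  if (min_umi < 1) stop("min_umi must be >= 1")
  library <- validate_guide_library(library)
  unknown <- setdiff(rownames(capture), library$guide_id)
  if (length(unknown))
    stop("guides in capture matrix missing from the library: ",
         paste(unknown, collapse = ", "))
  if (any(capture < 0)) stop("capture counts must be non-negative")
  barcodes <- colnames(capture)
  if (!is.null(all_barcodes)) {
    extra <- setdiff(colnames(capture), all_barcodes)
    if (length(extra))
      stop("capture barcodes absent from the expression matrix: ",
           paste(utils::head(extra, 5), collapse = ", "))
    barcodes <- all_barcodes
  }
  hits <- which(as.matrix(capture) >= min_umi, arr.ind = TRUE)
  by_cell <- split(rownames(capture)[hits[, 1]],
                   factor(colnames(capture)[hits[, 2]], levels = barcodes))
  tmap <- stats::setNames(library$target, library$guide_id)
  targeting <- stats::setNames(library$class == "targeting",
                               library$guide_id)
  out <- data.frame(
    barcode = barcodes,
    n_guides = unname(lengths(by_cell)),
    guides = vapply(by_cell, function(g) paste(sort(g), collapse = ";"),
                    character(1), USE.NAMES = FALSE),
    targets = vapply(by_cell, function(g) {
      tg <- unique(tmap[g[targeting[g]]])
      paste(sort(tg), collapse = ";")
    }, character(1), USE.NAMES = FALSE),
    keep = NA,
    reason = "undecided",
    stringsAsFactors = FALSE)
  class(out) <- c("guide_assignment", class(out))
  out
}

#' Apply the library-specific cell filters
#'
#' Control (NT) libraries carry a single non-targeting guide, so a cell is
#' kept iff exactly one guide is detected; activation (AGM) libraries were
#' infected at high MOI, so a cell is kept iff more than one guide is
#' detected. Drop reasons: `zero_guides` (none detected), `too_few` (AGM
#' cell with a single guide), `wrong_multiplicity` (NT cell with more than
#' one).
#'
#' @param assignment A [detect_guides()] result.
#' @param library_type Either a single value or a per-cell vector (aligned
#'   with `assignment$barcode` or named by barcode) in `{"NT", "AGM"}`.
#' @return The assignment with `keep` and `reason` decided.
#' @export
filter_cells_by_guides <- function(assignment, library_type) {
  n <- nrow(assignment)
  if (length(library_type) == 1) {
    library_type <- rep(library_type, n)
  } else if (!is.null(names(library_type))) {
    library_type <- unname(library_type[assignment$barcode])
  }
  if (length(library_type) != n || anyNA(library_type))
    stop("library_type must cover every cell in the assignment")
  if (!all(library_type %in% c("NT", "AGM")))
    stop("library_type values must be 'NT' or 'AGM'")
  ng <- assignment$n_guides
  keep <- ifelse(library_type == "NT", ng == 1, ng > 1)
  reason <- rep("kept", n)
  reason[ng == 0] <- "zero_guides"
  reason[!keep & ng >= 1 & library_type == "AGM"] <- "too_few"
  reason[!keep & ng >= 1 & library_type == "NT"] <- "wrong_multiplicity"
  assignment$keep <- keep
  assignment$reason <- reason
  assignment
}

#' Per-target carrier summary over kept cells
#'
#' @param assignment A decided [filter_cells_by_guides()] result.
#' @param library Guide library `data.frame`.
#' @return List with `target_summary` (target, n_cells carrying >= 1 guide
#'   for it) and `guide_summary` (guide, target, n_cells).
#' @export
guides_per_target_summary <- function(assignment, library) {
  library <- validate_guide_library(library)
  if (anyNA(assignment$keep))
    stop("keep/drop must be decided first (filter_cells_by_guides)")
  kept <- assignment[assignment$keep, , drop = FALSE]
  guide_lists <- lapply(kept$guides, split_ids)
  target_lists <- lapply(kept$targets, split_ids)
  tg <- unique(library$target[library$class == "targeting"])
  target_summary <- data.frame(
    target = tg,
    n_cells = vapply(tg, function(t)
      sum(vapply(target_lists, function(ts) t %in% ts, logical(1))),
      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  gids <- library$guide_id
  guide_summary <- data.frame(
    guide = gids,
    target = library$target,
    n_cells = vapply(gids, function(g)
      sum(vapply(guide_lists, function(gs) g %in% gs, logical(1))),
      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(target_summary = target_summary, guide_summary = guide_summary)
}

#' Kept cells carrying at least one guide for a target
#'
#' @param assignment A decided guide assignment.
#' @param target Target gene symbol.
#' @return Character vector of barcodes.
#' @export
target_carriers <- function(assignment, target) {
  kept <- assignment[!is.na(assignment$keep) & assignment$keep, ,
                     drop = FALSE]
  has <- vapply(kept$targets, function(t) target %in% split_ids(t),
                logical(1))
  kept$barcode[has]
}
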