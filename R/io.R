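#' Read a 10x-style MatrixMarket triplet directory
#'
#' Reads `matrix.mtx` together with its `features.tsv` and `barcodes.tsv`
#' side files (plain or gzipped) and returns a sparse gene-by-cell count
#' matrix with feature identifiers as row names and cell barcodes as column
#' names.
#'
#' @param dir Directory containing the three files.
#' @param matrix_file,features_file,barcodes_file File names within `dir`;
#'   a `.gz` sibling is used when the plain file is absent.
#' @return A `dgCMatrix` of non-negative integer counts.
#' @export
read_10x_counts <- function(dir, matrix_file = "matrix.mtx",
                            features_file = "features.tsv",
                            barcodes_file = "barcodes.tsv") {
  pick <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
    pgz <- paste0(p, ".gz")
    if (file.exists(pgz)) return(pgz)
    stop("file not found: ", p, " (or .gz)")
  }
  mat <- methods::as(Matrix::readMM(pick(matrix_file)), "CsparseMatrix")
  feats <- utils::read.table(pick(features_file), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE)
  bars <- utils::read.table(pick(barcodes_file), sep = "\t",
                            header = FALSE, stringsAsFactors = FALSE)
  if (nrow(feats) != nrow(mat))
    stop("features file has ", nrow(feats), " rows but matrix has ",
         nrow(mat))
  if (nrow(bars) != ncol(mat))
    stop("barcodes file has ", nrow(bars), " rows but matrix has ",
         ncol(mat), " columns")
  rownames(mat) <- make.unique(feats[[1]])
  colnames(mat) <- bars[[1]]
  validate_count_matrix(mat)
  mat
}

#' Write a count matrix as a 10x-style MatrixMarket triplet directory
#'
#' @param mat Gene-by-cell matrix with row and column names.
#' @param dir Output directory (created if needed).
#' @export
write_10x_counts <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(mat, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  utils::write.table(data.frame(rownames(mat), rownames(mat)),
                     file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(colnames(mat)),
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

validate_count_matrix <- function(mat) {
  if (any(mat@x < 0)) stop("count matrix has negative entries")
  if (anyDuplicated(rownames(mat))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(mat))) stop("duplicate cell barcodes")
  invisible(mat)
}

#' Read a guide library table
#'
#' Tab-separated file with columns `guide_id`, `target`, `class`
#' (`targeting` or `non_targeting`). Non-targeting guides carry an empty
#' target.
#'
#' @param path Path to the TSV file.
#' @return Validated `data.frame` with those three columns.
#' @export
read_guide_library <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  validate_guide_library(df)
}

#' @rdname read_guide_library
#' @param library Guide library `data.frame` to validate.
#' @export
validate_guide_library <- function(library) {
  need <- c("guide_id", "target", "class")
  if (!all(need %in% names(library)))
    stop("guide library must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(library$guide_id))
    stop("duplicate guide_id in guide library")
  if (!all(library$class %in% c("targeting", "non_targeting")))
    stop("guide class must be 'targeting' or 'non_targeting'")
  bad <- library$class == "targeting" &
    (is.na(library$target) | !nzchar(library$target))
  if (any(bad))
    stop("targeting guides without a target gene: ",
         paste(library$guide_id[bad], collapse = ", "))
  library
}

#' Read a transcription-factor list (one gene symbol per line)
#'
#' @param path Path to a plain-text file.
#' @return Character vector of symbols.
#' @export
read_tf_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  unique(x[nzchar(x)])
}

#' Read gene sets in GMT format
#'
#' Each line: set name, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-c(1, 2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Read a Seahorse trace CSV
#'
#' Expected columns: `well`, `condition`, `phase` (basal/oligo/rot),
#' `read_index`, `OCR`, `ECAR`.
#'
#' @param path Path to the CSV file.
#' @return `data.frame` trace.
#' @export
read_seahorse_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("well", "phase", "read_index", "OCR", "ECAR")
  if (!all(need %in% names(df)))
    stop("Seahorse trace must have columns: ", paste(need, collapse = ", "))
  if (!"condition" %in% names(df)) df$condition <- "all"
  bad <- setdiff(unique(df$phase), c("basal", "oligo", "rot"))
  if (length(bad))
    stop("unknown phase labels: ", paste(bad, collapse = ", "))
  if (any(df$OCR < 0) || any(df$ECAR < 0))
    stop("OCR/ECAR must be non-negative")
  df
}
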