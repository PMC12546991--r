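#' Read a sparse count matrix in Matrix Market format
#'
#' Reads the 10x-style triplet of files: a Matrix Market coordinate `.mtx`
#' file plus one-identifier-per-line TSV files for genes and cells
#' (barcodes). On disk genes are rows by convention; if the stored matrix is
#' transposed relative to the id files the orientation is auto-detected from
#' the dimensions. A square matrix is taken as genes x cells.
#'
#' @param mtx_path Path to the `.mtx` file.
#' @param genes_path Path to the gene id file (first column used).
#' @param cells_path Path to the cell id file (first column used).
#' @param meta_path Optional CSV with per-cell metadata (`cell_id`,
#'   `replicate`, ...).
#' @return A [gene_expression_matrix()].
#' @export
read_count_matrix <- function(mtx_path, genes_path, cells_path,
                              meta_path = NULL) {
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("format error: ", conditionMessage(e)))
  gene_ids <- .read_id_column(genes_path)
  cell_ids <- .read_id_column(cells_path)
  ng <- length(gene_ids); nc <- length(cell_ids)
  if (nrow(m) == ng && ncol(m) == nc) {
    # genes x cells as stored
  } else if (nrow(m) == nc && ncol(m) == ng) {
    m <- Matrix::t(m)
  } else {
    stop(sprintf(
      "format error: matrix is %d x %d but id files list %d genes and %d cells",
      nrow(m), ncol(m), ng, nc))
  }
  meta <- if (!is.null(meta_path)) {
    utils::read.csv(meta_path, stringsAsFactors = FALSE)
  } else NULL
  gene_expression_matrix(m, gene_ids = gene_ids, cell_ids = cell_ids,
                         cell_meta = meta)
}

.read_id_column <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  as.character(tab[[1]])
}

#' Write a count matrix as Matrix Market plus id files
#'
#' Inverse of [read_count_matrix()]; genes are written as rows. Also writes
#' the cell metadata table.
#'
#' @param gem A `GeneExpressionMatrix`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_count_matrix <- function(gem, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(mtx = file.path(dir, "matrix.mtx"),
             genes = file.path(dir, "genes.tsv"),
             cells = file.path(dir, "barcodes.tsv"),
             meta = file.path(dir, "cell_meta.csv"))
  Matrix::writeMM(gem$counts, paths[["mtx"]])
  writeLines(gem$gene_ids, paths[["genes"]])
  writeLines(gem$cell_ids, paths[["cells"]])
  write_results(gem$cell_meta, paths[["meta"]])
  invisible(paths)
}

#' Write a result table to CSV
#'
#' Serializes marker tables, assignment results, embeddings and other
#' tabular stage outputs with a stable column order and full floating-point
#' precision (15 significant digits), so that a write/read round trip
#' preserves values to better than 1e-12.
#'
#' @param obj A `data.frame` (or matrix, converted with row names as a
#'   column named `id`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(obj, path) {
  if (is.matrix(obj)) {
    obj <- data.frame(id = if (is.null(rownames(obj)))
      as.character(seq_len(nrow(obj))) else rownames(obj),
      as.data.frame(obj), stringsAsFactors = FALSE, check.names = FALSE)
  }
  stopifnot(is.data.frame(obj))
  out <- obj
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      out[[j]] <- formatC(out[[j]], digits = 15, format = "g")
    } else if (is.factor(out[[j]])) {
      out[[j]] <- as.character(out[[j]])
    }
  }
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("I/O error writing ", path, ": ",
                        conditionMessage(ok))
  invisible(path)
}

#' Read a table written by [write_results()]
#' @param path CSV path.
#' @return A `data.frame`.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
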