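#' Construct a gene-by-cell UMI count matrix
#'
#' The central container of the pipeline: raw unique-molecular-identifier
#' (UMI) counts with genes as rows and cells as columns, together with
#' per-cell metadata. All downstream stages (filtering, normalization,
#' integration, differential expression) consume and return this structure
#' or objects derived from it.
#'
#' @param counts A non-negative integer matrix or `Matrix::sparseMatrix`,
#'   genes x cells.
#' @param gene_ids Character vector of unique gene identifiers; defaults to
#'   `rownames(counts)`.
#' @param cell_ids Character vector of unique cell identifiers; defaults to
#'   `colnames(counts)`.
#' @param cell_meta A `data.frame` keyed by `cell_id` with at least a
#'   `replicate` column. If `NULL`, a single replicate `"r1"` is assumed.
#'
#' @return An object of class `GeneExpressionMatrix`: a list with elements
#'   `counts` (a `dgCMatrix`, genes x cells, dimnames set), `gene_ids`,
#'   `cell_ids` and `cell_meta`.
#' @export
gene_expression_matrix <- function(counts, gene_ids = rownames(counts),
                                   cell_ids = colnames(counts),
                                   cell_meta = NULL) {
  counts <- methods::as(methods::as(methods::as(
    Matrix::Matrix(counts, sparse = TRUE), "dMatrix"), "generalMatrix"),
    "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(ncol(counts)))
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts) || length(cell_ids) != ncol(counts))
    stop("validation error: id list lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids))
    stop("validation error: duplicate gene ids")
  if (anyDuplicated(cell_ids))
    stop("validation error: duplicate cell ids")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) stop("validation error: negative counts")
    if (any(x != round(x))) stop("validation error: non-integer counts")
  }
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = cell_ids, replicate = "r1",
                            stringsAsFactors = FALSE)
  }
  cell_meta <- as.data.frame(cell_meta, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "replicate") %in% names(cell_meta)))
    stop("validation error: cell_meta needs columns cell_id and replicate")
  cell_meta$cell_id <- as.character(cell_meta$cell_id)
  cell_meta$replicate <- as.character(cell_meta$replicate)
  if (anyDuplicated(cell_meta$cell_id) ||
      !setequal(cell_meta$cell_id, cell_ids))
    stop("validation error: cell_meta must list every cell_id exactly once")
  cell_meta <- cell_meta[match(cell_ids, cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "GeneExpressionMatrix")
}

#' @export
print.GeneExpressionMatrix <- function(x, ...) {
  cat(sprintf("GeneExpressionMatrix: %d genes x %d cells (%d replicates)\n",
              length(x$gene_ids), length(x$cell_ids),
              length(unique(x$cell_meta$replicate))))
  invisible(x)
}

#' Number of genes / cells in a GeneExpressionMatrix
#' @param gem A `GeneExpressionMatrix`.
#' @return Integer count.
#' @export
n_genes <- function(gem) length(gem$gene_ids)

#' @rdname n_genes
#' @export
n_cells <- function(gem) length(gem$cell_ids)

#' Subset a GeneExpressionMatrix by cells or genes
#'
#' @param gem A `GeneExpressionMatrix`.
#' @param cells,genes Character ids, logical mask, or integer indices.
#' @return A new `GeneExpressionMatrix` restricted to the selection.
#' @export
subset_cells <- function(gem, cells) {
  idx <- .resolve_index(cells, gem$cell_ids, "cell")
  gene_expression_matrix(gem$counts[, idx, drop = FALSE],
                         gene_ids = gem$gene_ids,
                         cell_ids = gem$cell_ids[idx],
                         cell_meta = gem$cell_meta[idx, , drop = FALSE])
}

#' @rdname subset_cells
#' @export
subset_genes <- function(gem, genes) {
  idx <- .resolve_index(genes, gem$gene_ids, "gene")
  gene_expression_matrix(gem$counts[idx, , drop = FALSE],
                         gene_ids = gem$gene_ids[idx],
                         cell_ids = gem$cell_ids,
                         cell_meta = gem$cell_meta)
}

.resolve_index <- function(sel, ids, what) {
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop(sprintf("unknown %s ids: %s", what,
                                 paste(sel[is.na(idx)], collapse = ", ")))
    idx
  } else if (is.logical(sel)) {
    if (length(sel) != length(ids)) stop("logical mask length mismatch")
    which(sel)
  } else {
    sel <- as.integer(sel)
    if (any(sel < 1L) || any(sel > length(ids))) stop("index out of range")
    sel
  }
}

#' Per-cell replicate labels
#' @param gem A `GeneExpressionMatrix`.
#' @return Character vector aligned with `gem$cell_ids`.
#' @export
replicate_labels <- function(gem) gem$cell_meta$replicate
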