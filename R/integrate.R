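#' PCA embedding of normalized expression
#'
#' Restricts to the supplied feature genes, centers each gene, and returns
#' the top-`d` principal component scores. A deterministic sign convention
#' (the loading with the largest magnitude is positive) makes results
#' reproducible across runs and platforms.
#'
#' @param nm A `NormalizedMatrix`.
#' @param genes Feature genes: an `HvgSet`, character ids, or `NULL` for all.
#' @param d Number of components (<= min(#genes, #cells)).
#' @return Cells x d numeric matrix with attributes `space = "pca"`,
#'   `var_explained`, `rotation` and `center`.
#' @export
pca_embed <- function(nm, genes = NULL, d = 30) {
  ids <- .gene_ids_of(genes, rownames(nm$values))
  vals <- nm$values[ids, , drop = FALSE]
  if (d > min(nrow(vals), ncol(vals)))
    stop("validation error: d exceeds min(#genes, #cells)")
  pc <- stats::prcomp(t(vals), center = TRUE, scale. = FALSE, rank. = d)
  flip <- .sign_convention(pc$rotation)
  scores <- sweep(pc$x, 2, flip, "*")
  rownames(scores) <- colnames(nm$values)
  structure(scores, space = "pca",
            var_explained = pc$sdev^2,
            rotation = sweep(pc$rotation, 2, flip, "*"),
            center = pc$center)
}

.gene_ids_of <- function(genes, universe) {
  if (is.null(genes)) return(universe)
  ids <- if (inherits(genes, "HvgSet")) genes$gene_id
  else if (inherits(genes, "GeneSet")) genes$members
  else as.character(genes)
  missing <- setdiff(ids, universe)
  if (length(missing))
    stop("genes not present in matrix: ",
         paste(utils::head(missing, 5), collapse = ", "))
  ids
}

# +1/-1 per column so the largest-magnitude loading is positive
.sign_convention <- function(rotation) {
  apply(rotation, 2, function(v) {
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  })
}

#' Mutual-nearest-neighbor batch correction
#'
#' Fast MNN-style integration in a joint principal-component space: cells
#' are cosine-normalized, jointly embedded by PCA to `d` dimensions, and
#' batches are merged sequentially in input order. For each incoming batch,
#' mutual k-nearest-neighbor pairs against the current reference set define
#' per-pair correction vectors (reference minus incoming); each incoming
#' cell is shifted by a Gaussian-kernel-weighted average of pair vectors
#' (bandwidth = `bandwidth_mult` x the median MNN pair distance), then the
#' corrected cells join the reference set. With a single batch the joint
#' PCA embedding is returned unchanged.
#'
#' @param batches List of `NormalizedMatrix` objects (or genes x cells
#'   matrices) on an identical gene space, typically restricted to HVGs.
#' @param d Number of principal components (default 30).
#' @param k Neighbors for the mutual-NN search (default 20).
#' @param bandwidth_mult Multiple of the median pair distance used as the
#'   Gaussian smoothing bandwidth.
#' @return Cells x d corrected coordinates for all cells in input order,
#'   with attributes `space = "mnn-corrected"` and `batch`.
#' @export
mnn_correct <- function(batches, d = 30, k = 20, bandwidth_mult = 1.0) {
  stopifnot(length(batches) >= 1)
  mats <- lapply(batches, function(b)
    if (inherits(b, "NormalizedMatrix")) b$values else as.matrix(b))
  ref_genes <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), ref_genes))
      stop("validation error: batches must share an identical gene space")
  }
  sizes <- vapply(mats, ncol, integer(1))
  batch_names <- if (!is.null(names(batches)) && all(nzchar(names(batches))))
    names(batches) else paste0("batch", seq_along(batches))
  combined <- do.call(cbind, lapply(mats, .cosine_norm))
  d_use <- min(d, nrow(combined), ncol(combined))
  pc <- stats::prcomp(t(combined), center = TRUE, scale. = FALSE,
                      rank. = d_use)
  flip <- .sign_convention(pc$rotation)
  coords <- sweep(pc$x, 2, flip, "*")
  idx_list <- split(seq_len(sum(sizes)), rep(seq_along(mats), sizes))
  out <- coords
  if (length(mats) > 1) {
    ref_idx <- idx_list[[1]]
    for (b in seq_along(mats)[-1]) {
      inc_idx <- idx_list[[b]]
      corrected <- .mnn_merge(out[ref_idx, , drop = FALSE],
                              out[inc_idx, , drop = FALSE],
                              k = k, bandwidth_mult = bandwidth_mult)
      out[inc_idx, ] <- corrected
      ref_idx <- c(ref_idx, inc_idx)
    }
  }
  cell_ids <- unlist(lapply(mats, colnames))
  if (!is.null(cell_ids)) rownames(out) <- cell_ids
  structure(out, space = "mnn-corrected",
            batch = rep(batch_names, sizes))
}

#' MNN correction of pre-computed embedding coordinates
#'
#' The merge step of [mnn_correct()] applied directly to low-dimensional
#' coordinates (e.g. an existing PC embedding): batches are merged
#' sequentially in input order via mutual k-nearest-neighbor pair vectors
#' smoothed with a Gaussian kernel. Useful when the embedding is shared or
#' when correcting a known coordinate-space shift.
#'
#' @param coord_batches List of cells x d coordinate matrices.
#' @param k Mutual nearest neighbors (default 20).
#' @param bandwidth_mult Gaussian bandwidth as a multiple of the median
#'   MNN pair distance.
#' @return Stacked corrected coordinates (input order) with attribute
#'   `batch`.
#' @export
mnn_correct_coords <- function(coord_batches, k = 20, bandwidth_mult = 1.0) {
  stopifnot(length(coord_batches) >= 1)
  mats <- lapply(coord_batches, as.matrix)
  sizes <- vapply(mats, nrow, integer(1))
  batch_names <- if (!is.null(names(coord_batches)) &&
                     all(nzchar(names(coord_batches))))
    names(coord_batches) else paste0("batch", seq_along(coord_batches))
  out <- do.call(rbind, mats)
  idx_list <- split(seq_len(sum(sizes)), rep(seq_along(mats), sizes))
  if (length(mats) > 1) {
    ref_idx <- idx_list[[1]]
    for (b in seq_along(mats)[-1]) {
      inc_idx <- idx_list[[b]]
      out[inc_idx, ] <- .mnn_merge(out[ref_idx, , drop = FALSE],
                                   out[inc_idx, , drop = FALSE],
                                   k = k, bandwidth_mult = bandwidth_mult)
      ref_idx <- c(ref_idx, inc_idx)
    }
  }
  structure(out, space = "mnn-corrected", batch = rep(batch_names, sizes))
}

# unit-L2 columns; all-zero columns left untouched
.cosine_norm <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  sweep(m, 2, nrm, "/")
}

.mnn_merge <- function(ref, inc, k, bandwidth_mult) {
  k_use <- min(k, nrow(ref), nrow(inc))
  nn_ri <- FNN::get.knnx(inc, ref, k_use)$nn.index    # neighbors of ref in inc
  nn_ir <- FNN::get.knnx(ref, inc, k_use)$nn.index    # neighbors of inc in ref
  pairs_r <- integer(0); pairs_i <- integer(0)
  for (r in seq_len(nrow(ref))) {
    cand <- nn_ri[r, ]
    mutual <- cand[vapply(cand, function(j) any(nn_ir[j, ] == r),
                          logical(1))]
    if (length(mutual)) {
      pairs_r <- c(pairs_r, rep(r, length(mutual)))
      pairs_i <- c(pairs_i, mutual)
    }
  }
  if (length(pairs_r) == 0)
    stop("no mutual nearest neighbors found between batches; ",
         "consider increasing k")
  vecs <- ref[pairs_r, , drop = FALSE] - inc[pairs_i, , drop = FALSE]
  pair_dist <- sqrt(rowSums(vecs^2))
  sigma <- bandwidth_mult * stats::median(pair_dist)
  # anchor at pair midpoints: for identical batches mirrored pairs carry
  # opposite vectors with equal weight, so corrections cancel exactly
  anchor <- (ref[pairs_r, , drop = FALSE] + inc[pairs_i, , drop = FALSE]) / 2
  if (sigma < 1e-12) {
    corr <- matrix(colMeans(vecs), nrow(inc), ncol(inc), byrow = TRUE)
  } else {
    d2 <- .cross_dist2(inc, anchor)
    w <- exp(-d2 / (2 * sigma^2))
    wsum <- rowSums(w)
    zero <- wsum < 1e-300
    if (any(zero)) { w[zero, ] <- 1; wsum[zero] <- ncol(w) }
    corr <- (w %*% vecs) / wsum
  }
  inc + corr
}

# squared Euclidean distances between rows of a and rows of b
.cross_dist2 <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Batch-mixing entropy of an embedding
#'
#' Mean Shannon entropy (base 2, normalized by the entropy of the global
#' batch proportions is not applied) of batch composition over each cell's
#' k-nearest neighborhood; higher values mean better mixing. Used to
#' quantify the effect of [mnn_correct()].
#'
#' @param coords Cells x d coordinates.
#' @param batch Per-cell batch labels.
#' @param k Neighborhood size (default 20).
#' @return Mean per-cell entropy in bits.
#' @export
batch_mixing_entropy <- function(coords, batch, k = 20) {
  stopifnot(nrow(coords) == length(batch))
  k_use <- min(k, nrow(coords) - 1)
  nn <- FNN::get.knn(coords, k_use)$nn.index
  batch <- as.character(batch)
  ent <- apply(nn, 1, function(idx) {
    p <- table(batch[idx]) / length(idx)
    -sum(p * log2(p))
  })
  mean(ent)
}
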