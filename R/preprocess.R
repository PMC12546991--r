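#' Remove low-complexity cells
#'
#' Keeps exactly the cells in which at least `min_genes` genes are detected
#' (count > 0). This is the standard first pruning step for droplet or
#' plate-based UMI data; typical cutoffs for the datasets this pipeline was
#' designed around range from 750 to 1200 detected genes.
#'
#' @param gem A `GeneExpressionMatrix`.
#' @param min_genes Minimum number of detected genes per cell (>= 0).
#' @return The filtered `GeneExpressionMatrix` (gene set unchanged).
#' @export
filter_cells <- function(gem, min_genes) {
  stopifnot(min_genes >= 0)
  detected <- Matrix::colSums(gem$counts > 0)
  keep <- detected >= min_genes
  if (!any(keep))
    stop("empty-result error: all cells removed by min_genes = ", min_genes)
  subset_cells(gem, keep)
}

#' Remove near-silent genes
#'
#' Keeps exactly the genes observed at count >= 2 in at least 2 of the
#' remaining cells, dropping genes whose expression is at most 1 in
#' (nearly) every cell. Apply after [filter_cells()].
#'
#' @param gem A `GeneExpressionMatrix`.
#' @return The filtered `GeneExpressionMatrix` (cell set unchanged).
#' @export
filter_genes <- function(gem) {
  keep <- Matrix::rowSums(gem$counts >= 2) >= 2
  if (!any(keep)) {
    warning("gene filter removed every gene")
    return(subset_genes(gem, keep))
  }
  subset_genes(gem, keep)
}

#' Per-cell size factors
#'
#' Estimates the per-cell scaling constant used to remove depth and
#' composition differences before log transformation. `method = "library"`
#' uses total counts; `method = "pooled"` (default) uses deconvolution of
#' pooled-cell ratios (the scran approach), which is robust to
#' composition effects. Factors are rescaled to mean 1.
#'
#' @param gem A `GeneExpressionMatrix` with no all-zero cells.
#' @param method `"pooled"` or `"library"`.
#' @param pool_sizes Pool sizes for the deconvolution (clamped to the number
#'   of available cells).
#' @return Named positive numeric vector, one factor per cell, mean 1.
#' @export
compute_size_factors <- function(gem, method = c("pooled", "library"),
                                 pool_sizes = c(21, 41, 61)) {
  method <- match.arg(method)
  totals <- Matrix::colSums(gem$counts)
  if (any(totals == 0))
    stop("validation error: all-zero cells present; run filter_cells first")
  sf <- if (method == "library") {
    totals
  } else {
    sizes <- pool_sizes[pool_sizes <= n_cells(gem)]
    res <- if (length(sizes) == 0) NULL else tryCatch({
      sce <- SingleCellExperiment::SingleCellExperiment(
        list(counts = gem$counts))
      f <- scran::calculateSumFactors(sce, sizes = sizes, min.mean = 0.1)
      if (any(!is.finite(f)) || any(f <= 0)) NULL else f
    }, error = function(e) NULL)
    if (is.null(res)) {
      warning("pooled size-factor system unusable; falling back to ",
              "library-size factors")
      totals
    } else res
  }
  sf <- sf / mean(sf)
  stats::setNames(sf, gem$cell_ids)
}

#' Log-normalize counts
#'
#' Divides each cell by its size factor and applies `log2(1 + x)`. Zero
#' counts map to zero for any size factor, and the transform is monotone in
#' counts within a cell.
#'
#' @param gem A `GeneExpressionMatrix`.
#' @param sf Positive size factors, one per cell (any order if named).
#' @return A `NormalizedMatrix`: list with `values` (dense genes x cells
#'   matrix), `size_factors`, `log_base = 2`.
#' @export
normalize_log <- function(gem, sf) {
  if (length(sf) != n_cells(gem))
    stop("validation error: size-factor length does not match cell count")
  if (!is.null(names(sf))) {
    idx <- match(gem$cell_ids, names(sf))
    if (anyNA(idx)) stop("validation error: size-factor names do not match")
    sf <- sf[idx]
  }
  if (any(sf <= 0)) stop("validation error: size factors must be positive")
  vals <- log2(1 + sweep(as.matrix(gem$counts), 2, sf, "/"))
  dimnames(vals) <- list(gem$gene_ids, gem$cell_ids)
  structure(list(values = vals, size_factors = stats::setNames(sf,
                                                               gem$cell_ids),
                 log_base = 2, cell_meta = gem$cell_meta),
            class = "NormalizedMatrix")
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d genes x %d cells (log base %d)\n",
              nrow(x$values), ncol(x$values), x$log_base))
  invisible(x)
}

#' Select highly variable genes
#'
#' Per replicate, fits the technical trend `CV^2 ~ a + b / mu` on the
#' per-gene mean and squared coefficient of variation of normalized counts
#' by robust regression, and scores each gene by its excess CV^2 (observed
#' minus trend). Scores are combined across replicates (mean by default)
#' and the top `fraction` of eligible genes is returned. Genes on any
#' exclusion list (ribosomal, mitochondrial, stress, proliferation,
#' cell-cycle) are removed before ranking so they can never enter the
#' feature space.
#'
#' @param nm A `NormalizedMatrix`.
#' @param replicate_labels Per-cell replicate labels; `NULL` treats all
#'   cells as one replicate.
#' @param exclude Character vector (or list of vectors) of gene ids to
#'   exclude before ranking.
#' @param fraction Fraction of eligible genes to retain (default 0.05).
#' @param combine How per-replicate scores/sets are merged: `"mean"`
#'   averages the statistic before ranking; `"union"`/`"intersection"`
#'   combine per-replicate top sets.
#' @return An `HvgSet`: data.frame with `gene_id` and `statistic`, ordered
#'   by decreasing excess CV^2; attribute `fraction`.
#' @export
select_hvgs <- function(nm, replicate_labels = NULL, exclude = character(0),
                        fraction = 0.05,
                        combine = c("mean", "union", "intersection")) {
  combine <- match.arg(combine)
  stopifnot(fraction > 0, fraction <= 1)
  exclude <- unique(unlist(exclude, use.names = FALSE))
  if (is.null(replicate_labels)) replicate_labels <- rep("r1",
                                                         ncol(nm$values))
  if (min(table(replicate_labels)) < 2)
    stop("validation error: need >= 2 cells per replicate")
  norm_counts <- nm$log_base^nm$values - 1
  gene_ids <- rownames(norm_counts)
  eligible <- setdiff(gene_ids, exclude)
  stat_by_rep <- sapply(unique(replicate_labels), function(r) {
    sub <- norm_counts[, replicate_labels == r, drop = FALSE]
    .excess_cv2(sub)
  })
  rownames(stat_by_rep) <- gene_ids
  stat_by_rep <- stat_by_rep[eligible, , drop = FALSE]
  n_take <- ceiling(fraction * length(eligible))
  if (n_take > length(eligible)) {
    warning("fewer eligible genes than requested; returning all")
    n_take <- length(eligible)
  }
  if (combine == "mean") {
    score <- rowMeans(stat_by_rep)
    ord <- order(-score, eligible)
    sel <- ord[seq_len(n_take)]
    out <- data.frame(gene_id = eligible[sel], statistic = score[sel],
                      stringsAsFactors = FALSE)
  } else {
    tops <- apply(stat_by_rep, 2, function(s) {
      eligible[order(-s, eligible)[seq_len(n_take)]]
    }, simplify = FALSE)
    set <- Reduce(if (combine == "union") union else intersect, tops)
    score <- rowMeans(stat_by_rep)[match(set, eligible)]
    ord <- order(-score, set)
    out <- data.frame(gene_id = set[ord], statistic = score[ord],
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "fraction") <- fraction
  class(out) <- c("HvgSet", "data.frame")
  out
}

# Excess CV^2 over a robust a + b/mu trend; genes with zero mean get -Inf
# so they always rank last.
.excess_cv2 <- function(mat) {
  mu <- rowMeans(mat)
  v <- apply(mat, 1, stats::var)
  cv2 <- ifelse(mu > 0, v / mu^2, NA_real_)
  use <- is.finite(cv2) & mu > 0
  if (sum(use) < 3) return(ifelse(use, cv2, -Inf))
  fit <- tryCatch(
    MASS::rlm(cv2[use] ~ I(1 / mu[use]), maxit = 100),
    error = function(e) stats::lm(cv2[use] ~ I(1 / mu[use])))
  trend <- rep(NA_real_, length(mu))
  trend[use] <- stats::coef(fit)[1] + stats::coef(fit)[2] / mu[use]
  out <- cv2 - trend
  out[!use] <- -Inf
  out
}

#' Score cells for G2/M cell-cycle phase
#'
#' Pair-voting classifier: for each marker pair (gene_hi, gene_lo) the vote
#' is 1 when expression(gene_hi) > expression(gene_lo), 0.5 on a tie, 0
#' otherwise; the G2/M score of a cell is the mean vote over usable pairs.
#' Cells with score above `threshold` (default 0.2) are called G2/M,
#' otherwise G1/S.
#'
#' @param nm A `NormalizedMatrix`.
#' @param marker_pairs data.frame with columns `hi` and `lo` (gene ids).
#' @param threshold G2/M score cut (default 0.2).
#' @return A `CellCycleCall` data.frame: `cell_id`, `g2m_score`, `phase`.
#' @export
score_cell_cycle <- function(nm, marker_pairs, threshold = 0.2) {
  stopifnot(all(c("hi", "lo") %in% names(marker_pairs)))
  genes <- rownames(nm$values)
  usable <- marker_pairs$hi %in% genes & marker_pairs$lo %in% genes
  if (!any(usable)) {
    missing <- setdiff(unique(c(marker_pairs$hi, marker_pairs$lo)), genes)
    stop("no usable marker pairs; missing genes: ",
         paste(missing, collapse = ", "))
  }
  mp <- marker_pairs[usable, , drop = FALSE]
  hi <- nm$values[mp$hi, , drop = FALSE]
  lo <- nm$values[mp$lo, , drop = FALSE]
  votes <- (hi > lo) + 0.5 * (hi == lo)
  score <- colMeans(votes)
  ids <- colnames(nm$values)
  if (is.null(ids)) ids <- sprintf("cell%d", seq_len(ncol(nm$values)))
  data.frame(cell_id = ids, g2m_score = as.numeric(score),
             phase = ifelse(score > threshold, "G2/M", "G1/S"),
             stringsAsFactors = FALSE)
}

#' Build cycle-scoring marker pairs from a known cycle program
#'
#' Pairs each cycle gene (`hi`) with a non-program gene (`lo`) whose median
#' expression sits three quarters of the induction shift above the cycle
#' gene's resting level. Cells outside the cycle phase then reliably fail
#' the `hi > lo` comparison (scores near 0) while cycling cells win about
#' half of them, which is what makes the pair-vote score discriminative at
#' the low 0.2 call threshold.
#'
#' @param nm A `NormalizedMatrix`.
#' @param cycle_genes Gene ids of the cycle program.
#' @param log2fc Expected log2 up-shift of cycle genes in cycling cells.
#' @param exclude Additional gene ids never used as partners (e.g. cell-type
#'   markers).
#' @return data.frame with columns `hi` and `lo` for [score_cell_cycle()].
#' @export
cycle_marker_pairs <- function(nm, cycle_genes, log2fc = 1.5,
                               exclude = character(0)) {
  meds <- apply(nm$values, 1, stats::median)
  hi <- intersect(cycle_genes, names(meds))
  if (!length(hi)) stop("no cycle genes present in the matrix")
  pool <- setdiff(names(meds), c(cycle_genes, exclude))
  lo <- character(length(hi))
  for (i in seq_along(hi)) {
    target <- meds[hi[i]] + 0.75 * log2fc
    j <- pool[which.min(abs(meds[pool] - target))]
    lo[i] <- j
    pool <- setdiff(pool, j)
  }
  data.frame(hi = hi, lo = lo, stringsAsFactors = FALSE)
}

#' Regress a binary covariate out of normalized expression
#'
#' Per gene, ordinary least squares of expression on the binary covariate
#' (e.g. the G2/M phase call); returns residuals plus the gene's grand mean
#' so values stay on the original scale. Residuals are exactly orthogonal
#' to the covariate.
#'
#' @param nm A `NormalizedMatrix`.
#' @param covariate Binary per-cell vector (logical, 0/1, or two-level
#'   factor/character), both levels present.
#' @return A `NormalizedMatrix` with the covariate effect removed.
#' @export
regress_out_covariate <- function(nm, covariate) {
  if (length(covariate) != ncol(nm$values))
    stop("validation error: covariate length mismatch")
  z <- as.numeric(as.factor(covariate)) - 1
  if (length(unique(z)) < 2)
    stop("validation error: covariate is constant")
  if (length(unique(z)) > 2)
    stop("validation error: covariate must be binary")
  X <- cbind(1, z)
  # hat projection applied to all genes at once
  coefs <- solve(crossprod(X), crossprod(X, t(nm$values)))
  fitted <- X %*% coefs
  resid <- nm$values - t(fitted)
  out <- resid + rowMeans(nm$values)
  dimnames(out) <- dimnames(nm$values)
  res <- nm
  res$values <- out
  res
}
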