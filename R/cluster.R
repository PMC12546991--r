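#' Build a shared-nearest-neighbor graph
#'
#' Finds each cell's k nearest neighbors by Euclidean distance in the first
#' `d` embedding coordinates and connects two cells whenever they are
#' neighbors of each other or share at least one neighbor. Neighbor sets
#' are self-inclusive (a cell belongs to its own set), and the edge weight
#' is the Jaccard overlap of the two sets, |shared| / |union|, which is
#' strictly positive for every edge.
#'
#' @param e Cells x D embedding matrix (row names = cell ids).
#' @param k Neighbors per cell (default 2, >= 1 and < number of cells).
#' @param d Number of leading coordinates to use (default 30, clamped to
#'   the embedding dimension).
#' @return A `NeighborGraph`: list with `graph` (weighted undirected
#'   igraph), `kind = "snn"`, `k`, `d`.
#' @export
build_snn_graph <- function(e, k = 2, d = 30) {
  e <- as.matrix(e)
  n <- nrow(e)
  if (k < 1) stop("validation error: k must be >= 1")
  if (k >= n) stop("validation error: k must be smaller than the number of cells")
  d_use <- min(d, ncol(e))
  coords <- e[, seq_len(d_use), drop = FALSE]
  nn <- FNN::get.knn(coords, k)$nn.index
  # self-inclusive neighbor sets as a sparse indicator matrix
  A <- Matrix::sparseMatrix(
    i = c(seq_len(n), rep(seq_len(n), k)),
    j = c(seq_len(n), as.vector(nn)),
    x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  shared <- methods::as(shared, "TsparseMatrix")
  keep <- shared@i < shared@j & shared@x > 0
  i <- shared@i[keep] + 1L; j <- shared@j[keep] + 1L; s <- shared@x[keep]
  wt <- s / (2 * (k + 1) - s)
  W <- Matrix::sparseMatrix(i = i, j = j, x = wt, dims = c(n, n),
                            symmetric = TRUE)
  ids <- rownames(e)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dimnames(W) <- list(ids, ids)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  structure(list(graph = g, kind = "snn", k = k, d = d_use),
            class = "NeighborGraph")
}

#' Louvain clustering of a cell graph
#'
#' Greedy modularity optimization with a resolution parameter; smaller
#' resolutions give fewer, larger clusters. Deterministic under a fixed
#' seed. Cluster labels are relabeled 0, 1, 2, ... by decreasing cluster
#' size.
#'
#' @param g A `NeighborGraph` (or an igraph).
#' @param resolution Positive resolution parameter.
#' @param seed Integer seed controlling the (randomized) optimization.
#' @return A `ClusterLabels`: list with `labels` (named integer vector,
#'   contiguous from 0), `resolution`, `exclusions` (filled by
#'   [apply_cluster_exclusion()]).
#' @export
louvain_cluster <- function(g, resolution = 1, seed = 1) {
  graph <- if (inherits(g, "NeighborGraph")) g$graph else g
  if (!igraph::is_igraph(graph)) stop("validation error: not a graph")
  if (igraph::vcount(graph) == 0)
    stop("validation error: empty graph")
  if (resolution <= 0) stop("validation error: resolution must be > 0")
  comm <- withr::with_seed(as.integer(seed),
    igraph::cluster_louvain(graph, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  labels <- relabel[as.character(memb)]
  names(labels) <- igraph::V(graph)$name
  structure(list(labels = labels, resolution = resolution,
                 exclusions = NULL),
            class = "ClusterLabels")
}

#' @export
print.ClusterLabels <- function(x, ...) {
  cat(sprintf("ClusterLabels: %d cells, %d clusters (resolution %.3g)\n",
              length(x$labels), length(unique(x$labels)), x$resolution))
  if (!is.null(x$exclusions)) {
    flagged <- x$exclusions[x$exclusions$flag != "none", , drop = FALSE]
    if (nrow(flagged))
      cat("flagged:", paste(sprintf("%s (%s)", flagged$cluster,
                                    flagged$flag), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flag clusters for exclusion
#'
#' Applies the three exclusion rules used before downstream analysis:
#' a cluster is flagged `pluripotency` when its mean expression of the
#' pluripotency gene set is an outlier relative to the other clusters
#' (above their mean + 2 SD; the SD falls back to the cell-level spread
#' when fewer than two other clusters exist), `replicate-imbalance` when
#' one replicate contributes more than `imbalance_threshold` of its cells,
#' and `too-small` when it has fewer than `min_cells` cells. Flags are
#' reported; removal is a separate, explicit step by the caller.
#'
#' @param labels A `ClusterLabels`.
#' @param nm The `NormalizedMatrix` the clusters were derived from.
#' @param replicate_labels Per-cell replicate labels (aligned with cells).
#' @param pluripotency_genes Non-empty character vector of gene ids.
#' @param min_cells Minimum cluster size (default 10).
#' @param imbalance_threshold Maximum tolerated replicate share
#'   (default 0.9).
#' @return The `ClusterLabels` with `exclusions`: a data.frame of
#'   `cluster`, `n_cells`, `flag` (one of `pluripotency`,
#'   `replicate-imbalance`, `too-small`, `none`).
#' @export
apply_cluster_exclusion <- function(labels, nm, replicate_labels,
                                    pluripotency_genes, min_cells = 10,
                                    imbalance_threshold = 0.9) {
  stopifnot(inherits(labels, "ClusterLabels"))
  if (length(pluripotency_genes) == 0)
    stop("validation error: pluripotency gene set is empty")
  lab <- labels$labels
  cells <- colnames(nm$values)
  lab <- lab[cells]
  genes_present <- intersect(pluripotency_genes, rownames(nm$values))
  pluri_score <- if (length(genes_present))
    colMeans(nm$values[genes_present, , drop = FALSE]) else
      rep(0, length(cells))
  clusters <- sort(unique(lab))
  cl_mean <- vapply(clusters, function(cl) mean(pluri_score[lab == cl]),
                    numeric(1))
  flags <- vapply(clusters, function(cl) {
    ci <- which(clusters == cl)
    others <- cl_mean[-ci]
    spread <- if (length(others) >= 2) stats::sd(others) else
      stats::sd(pluri_score[lab != cl])
    if (is.finite(spread) && length(others) >= 1 &&
        cl_mean[ci] > mean(others) + 2 * spread) return("pluripotency")
    shares <- table(replicate_labels[lab == cl])
    if (max(shares) / sum(shares) > imbalance_threshold &&
        length(unique(replicate_labels)) > 1) return("replicate-imbalance")
    if (sum(lab == cl) < min_cells) return("too-small")
    "none"
  }, character(1))
  labels$exclusions <- data.frame(
    cluster = as.integer(clusters),
    n_cells = as.integer(table(lab)[as.character(clusters)]),
    flag = flags, stringsAsFactors = FALSE)
  labels
}

#' Cells belonging to non-flagged clusters
#' @param labels A `ClusterLabels` with exclusions applied.
#' @return Character vector of cell ids in retained clusters.
#' @export
retained_cells <- function(labels) {
  stopifnot(!is.null(labels$exclusions))
  keep <- labels$exclusions$cluster[labels$exclusions$flag == "none"]
  names(labels$labels)[labels$labels %in% keep]
}
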