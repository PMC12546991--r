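#' Diffusion components of a cell embedding
#'
#' Builds a Gaussian transition kernel on a k-nearest-neighbor graph with
#' per-cell adaptive bandwidth (the distance to the ceil(k/2)-th neighbor):
#' `K_ij = exp(-||x_i - x_j||^2 / (sigma_i sigma_j))`, support symmetrized,
#' then row-normalized into a diffusion operator. Returns eigenvectors
#' 2..(n_comps+1) of the operator (the trivial constant eigenvector is
#' dropped), each scaled by its eigenvalue; eigenvalues are attached as an
#' attribute. Eigenvector signs follow the largest-magnitude-entry-positive
#' convention.
#'
#' @param e Cells x D embedding matrix.
#' @param n_comps Number of diffusion components (< number of cells).
#' @param k Neighbors of the kernel graph (default 20).
#' @return Cells x n_comps matrix with attributes `space = "diffusion"` and
#'   `eigenvalues`.
#' @export
diffusion_components <- function(e, n_comps, k = 20) {
  e <- as.matrix(e)
  n <- nrow(e)
  if (n_comps >= n)
    stop("validation error: n_comps must be smaller than the number of cells")
  k_use <- min(k, n - 1)
  nn <- FNN::get.knn(e, k_use)
  h <- ceiling(k_use / 2)
  sigma <- nn$nn.dist[, h]
  pos <- sigma[sigma > 0]
  sigma[sigma == 0] <- if (length(pos)) min(pos) else 1
  ii <- rep(seq_len(n), k_use)
  jj <- as.vector(nn$nn.index)
  d2 <- as.vector(nn$nn.dist)^2
  kv <- exp(-d2 / (sigma[ii] * sigma[jj]))
  K <- .symmetrize_kernel(ii, jj, kv, n)
  Matrix::diag(K) <- 1
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(K > 0, mode = "undirected"))
  if (comp$no > 1)
    warning("kernel graph has ", comp$no,
            " connected components; diffusion computed on the full kernel")
  dg <- Matrix::rowSums(K)
  dinv <- 1 / sqrt(dg)
  Dinv <- Matrix::Diagonal(x = dinv)
  M <- Dinv %*% K %*% Dinv     # symmetric normalized operator
  nev <- n_comps + 1
  dec <- if (nev < n / 3 && n > 100) {
    tryCatch(RSpectra::eigs_sym(as.matrix(M), nev, which = "LA"),
             error = function(e2) NULL)
  } else NULL
  if (is.null(dec)) {
    full <- eigen(as.matrix(M), symmetric = TRUE)
    dec <- list(values = full$values[seq_len(nev)],
                vectors = full$vectors[, seq_len(nev), drop = FALSE])
  }
  ord <- order(dec$values, decreasing = TRUE)
  vals <- dec$values[ord]
  vecs <- dec$vectors[, ord, drop = FALSE]
  psi <- vecs * dinv           # eigenvectors of the row-normalized operator
  # drop the trivial first eigenvector (eigenvalue 1, constant psi)
  lambdas <- vals[-1]
  psi <- psi[, -1, drop = FALSE]
  flip <- .sign_convention(psi)
  psi <- sweep(psi, 2, flip, "*")
  coords <- sweep(psi, 2, lambdas, "*")
  rownames(coords) <- rownames(e)
  structure(coords, space = "diffusion", eigenvalues = lambdas)
}

.symmetrize_kernel <- function(ii, jj, kv, n) {
  # union support with a single value per (i, j); kernel formula is already
  # symmetric, so duplicates carry the same value and we keep the first
  key <- paste(pmin(ii, jj), pmax(ii, jj))
  first <- !duplicated(key)
  i1 <- pmin(ii, jj)[first]; j1 <- pmax(ii, jj)[first]; v1 <- kv[first]
  off <- i1 != j1
  Matrix::sparseMatrix(i = c(i1[off], j1[off]), j = c(j1[off], i1[off]),
                       x = c(v1[off], v1[off]), dims = c(n, n))
}

#' Diffusion pseudotime from a root cell
#'
#' Distance from the root in eigenvalue-rescaled diffusion space:
#' `dpt(i) = || (lambda/(1-lambda)) * (psi_i - psi_root) ||` over the
#' retained components. The root has pseudotime exactly 0. Components with
#' eigenvalue numerically equal to 1 (e.g. extra trivial components of a
#' disconnected graph) are dropped with a warning.
#'
#' @param dc Diffusion embedding from [diffusion_components()].
#' @param root Cell id (must be a row name of `dc`).
#' @return A `PseudotimeResult` data.frame: `cell_id`, `pseudotime`;
#'   attributes `root` and `n_comps`.
#' @export
diffusion_pseudotime <- function(dc, root) {
  lambdas <- attr(dc, "eigenvalues")
  if (is.null(lambdas)) stop("dc must come from diffusion_components()")
  if (!root %in% rownames(dc)) stop("root cell '", root, "' not found")
  keep <- lambdas < 1 - 1e-12
  if (!all(keep))
    warning("dropping ", sum(!keep), " component(s) with eigenvalue 1")
  # stored coords are psi * lambda; dpt weight is lambda/(1-lambda)
  W <- dc[, keep, drop = FALSE]
  W <- sweep(W, 2, 1 - lambdas[keep], "/")
  delta <- sweep(W, 2, W[root, ], "-")
  pt <- sqrt(rowSums(delta^2))
  res <- data.frame(cell_id = rownames(dc), pseudotime = as.numeric(pt),
                    stringsAsFactors = FALSE)
  attr(res, "root") <- root
  attr(res, "n_comps") <- sum(keep)
  class(res) <- c("PseudotimeResult", "data.frame")
  res
}

#' Cluster-level graph connectivity (PAGA-style)
#'
#' For each cluster pair, the observed number of inter-cluster edges is
#' divided by the count expected under random edge placement given cluster
#' sizes: `conn(c1, c2) = e_obs / E_total * choose(n, 2) / (n_c1 * n_c2)`.
#' The matrix is then scaled by its maximum and clipped to [0, 1], giving a
#' relative abstraction of how strongly clusters touch in the cell graph.
#'
#' @param g A `NeighborGraph` (or igraph) over the cells.
#' @param labels A `ClusterLabels` covering every node.
#' @return Symmetric clusters x clusters matrix with zero diagonal; empty
#'   (0 x 0) when fewer than two clusters exist.
#' @export
paga_connectivity <- function(g, labels) {
  graph <- if (inherits(g, "NeighborGraph")) g$graph else g
  lab <- labels$labels
  vnames <- igraph::V(graph)$name
  if (is.null(vnames)) vnames <- as.character(seq_len(igraph::vcount(graph)))
  if (!all(vnames %in% names(lab)))
    stop("validation error: every node must be labeled")
  lab <- lab[vnames]
  clusters <- sort(unique(lab))
  ncl <- length(clusters)
  if (ncl < 2)
    return(matrix(numeric(0), 0, 0))
  el <- igraph::as_edgelist(graph, names = TRUE)
  c1 <- lab[el[, 1]]; c2 <- lab[el[, 2]]
  inter <- c1 != c2
  E_total <- nrow(el)
  n_total <- length(lab)
  sizes <- table(lab)[as.character(clusters)]
  conn <- matrix(0, ncl, ncl, dimnames = list(clusters, clusters))
  if (any(inter) && E_total > 0) {
    pairs <- data.frame(a = pmin(c1[inter], c2[inter]),
                        b = pmax(c1[inter], c2[inter]))
    counts <- stats::aggregate(list(n = rep(1, nrow(pairs))), pairs, sum)
    for (r in seq_len(nrow(counts))) {
      a <- as.character(counts$a[r]); b <- as.character(counts$b[r])
      val <- counts$n[r] / E_total * choose(n_total, 2) /
        (as.numeric(sizes[a]) * as.numeric(sizes[b]))
      conn[a, b] <- val; conn[b, a] <- val
    }
    mx <- max(conn)
    if (mx > 0) conn <- pmin(conn / mx, 1)
  }
  diag(conn) <- 0
  conn
}

#' Medoid cell of a cluster in an embedding
#'
#' Helper for root selection: the cell of a cluster minimizing the total
#' Euclidean distance to its cluster companions.
#'
#' @param e Cells x d embedding with row names.
#' @param labels A `ClusterLabels`.
#' @param cluster Cluster id.
#' @return A cell id.
#' @export
cluster_medoid <- function(e, labels, cluster) {
  cells <- names(labels$labels)[labels$labels == cluster]
  if (!length(cells)) stop("cluster ", cluster, " has no cells")
  sub <- e[cells, , drop = FALSE]
  dd <- as.matrix(stats::dist(sub))
  cells[which.min(rowSums(dd))]
}
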