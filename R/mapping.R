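#' A named gene set
#' @param name Set name.
#' @param members Character gene ids (deduplicated).
#' @return A `GeneSet` list.
#' @export
gene_set <- function(name, members) {
  structure(list(name = name, members = unique(as.character(members))),
            class = "GeneSet")
}

#' Two-step MNN mapping of query data onto a labeled reference
#'
#' Reproduces the reference-mapping recipe: the feature space is the top
#' `hvg_fraction_ref` highly variable genes of the *reference*; query
#' replicates are first merged with each other by MNN correction, then the
#' reference is mapped onto the combined query, all within one joint
#' `d`-dimensional PC space using `k` mutual nearest neighbors.
#'
#' @param query_batches List of `NormalizedMatrix` objects (the query
#'   replicates), full gene space.
#' @param reference A `ReferenceAtlas` (list with `gem` counts or `nm`
#'   normalized values, and per-cell `labels`).
#' @param hvg_fraction_ref HVG fraction computed on the reference
#'   (default 0.10).
#' @param d Principal components (default 30).
#' @param k Mutual nearest neighbors (default 100).
#' @return Joint corrected embedding (cells x d) for all query and
#'   reference cells with attributes `origin` (`"query"` / `"reference"`),
#'   `batch`, and `reference_labels`.
#' @export
map_to_reference <- function(query_batches, reference,
                             hvg_fraction_ref = 0.10, d = 30, k = 100) {
  ref_nm <- .reference_norm(reference)
  hvg <- select_hvgs(ref_nm, fraction = hvg_fraction_ref)
  shared <- hvg$gene_id
  for (q in query_batches) shared <- intersect(shared, rownames(q$values))
  if (length(shared) < 10)
    stop("fewer than 10 shared highly variable genes between query and ",
         "reference")
  batches <- c(lapply(query_batches, function(q) q$values[shared, ,
                                                          drop = FALSE]),
               list(reference = ref_nm$values[shared, , drop = FALSE]))
  names(batches) <- c(paste0("query", seq_along(query_batches)),
                      "reference")
  emb <- mnn_correct(batches, d = d, k = k)
  origin <- ifelse(attr(emb, "batch") == "reference", "reference", "query")
  structure(emb, origin = origin,
            reference_labels = reference$labels)
}

.reference_norm <- function(reference) {
  if (!is.null(reference$nm)) return(reference$nm)
  gem <- reference$gem
  sf <- compute_size_factors(gem, method = "library")
  normalize_log(gem, sf)
}

#' Confidence- and distance-gated KNN cell-type transfer
#'
#' Each query cell receives the modal cell-type label of its `k` nearest
#' reference cells (Euclidean distance in the joint corrected embedding),
#' with `confidence = modal votes / k`. A cell stays `UNASSIGNED` when its
#' mean neighbor distance exceeds the distance gate, when confidence falls
#' below the confidence gate, or when it belongs to a query cluster with
#' fewer than `min_cluster` cells. Vote ties are broken by the smaller mean
#' distance to the tied type's voting neighbors, then lexicographically.
#'
#' @param joint Joint embedding from [map_to_reference()] (or any cells x d
#'   matrix with an `origin` attribute), or a query-cells matrix if
#'   `reference_coords` is given.
#' @param reference_labels Named type labels of the reference cells (taken
#'   from `joint`'s attributes if absent).
#' @param query_clusters Optional `ClusterLabels` (or named vector) of the
#'   query's clusters; if missing the small-cluster gate is skipped with a
#'   warning.
#' @param k Neighbors (default 100, clamped to the reference size).
#' @param confidence_threshold Minimum vote fraction (default 0.5).
#' @param distance_threshold Absolute gate on the mean neighbor distance
#'   (the published analysis used 0.35 on its embedding scale), or
#'   `"quantile:q"` for the q-th percentile of reference-internal mean
#'   k-NN distances (default `"quantile:99"`), which adapts the gate to
#'   the embedding scale.
#' @param min_cluster Minimum query-cluster size (default 10).
#' @param nn_summary `"mean"` gates on the mean distance to the k
#'   neighbors (default); `"first"` gates on the 1-NN distance.
#' @return An `AssignmentResult` data.frame: `cell_id`, `assigned_type`,
#'   `confidence`, `mean_nn_distance`, `gate_reason` (one of `none`,
#'   `distance`, `confidence`, `small-cluster`); attribute
#'   `distance_threshold` holds the gate actually used.
#' @export
knn_assign_types <- function(joint, reference_labels = NULL,
                             query_clusters = NULL, k = 100,
                             confidence_threshold = 0.5,
                             distance_threshold = "quantile:99",
                             min_cluster = 10,
                             nn_summary = c("mean", "first")) {
  nn_summary <- match.arg(nn_summary)
  if (is.null(reference_labels))
    reference_labels <- attr(joint, "reference_labels")
  if (is.null(reference_labels)) stop("reference labels required")
  origin <- attr(joint, "origin")
  if (is.null(origin))
    origin <- ifelse(rownames(joint) %in% names(reference_labels),
                     "reference", "query")
  ref <- joint[origin == "reference", , drop = FALSE]
  qry <- joint[origin == "query", , drop = FALSE]
  if (k > nrow(ref))
    stop("validation error: k exceeds the number of reference cells")
  labels <- as.character(reference_labels[rownames(ref)])
  nn <- FNN::get.knnx(ref, qry, k)
  mean_dist <- if (nn_summary == "mean") rowMeans(nn$nn.dist) else
    nn$nn.dist[, 1]
  gate <- .resolve_distance_gate(distance_threshold, ref, k, nn_summary)
  n_q <- nrow(qry)
  assigned <- character(n_q); conf <- numeric(n_q)
  for (i in seq_len(n_q)) {
    idx <- nn$nn.index[i, ]
    votes <- table(labels[idx])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      md <- vapply(top, function(ty)
        mean(nn$nn.dist[i, labels[idx] == ty]), numeric(1))
      top <- top[order(md, top)]
    }
    assigned[i] <- top[1]
    conf[i] <- max(votes) / k
  }
  reason <- rep("none", n_q)
  reason[mean_dist > gate] <- "distance"
  reason[reason == "none" & conf < confidence_threshold] <- "confidence"
  if (is.null(query_clusters)) {
    warning("query cluster labels missing; small-cluster gate skipped")
  } else {
    cl <- if (inherits(query_clusters, "ClusterLabels"))
      query_clusters$labels else query_clusters
    cl <- cl[rownames(qry)]
    small <- names(table(cl))[table(cl) < min_cluster]
    reason[as.character(cl) %in% small] <- "small-cluster"
  }
  assigned[reason != "none"] <- "UNASSIGNED"
  res <- data.frame(cell_id = rownames(qry), assigned_type = assigned,
                    confidence = conf, mean_nn_distance = mean_dist,
                    gate_reason = reason, stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "distance_threshold") <- gate
  class(res) <- c("AssignmentResult", "data.frame")
  res
}

.resolve_distance_gate <- function(distance_threshold, ref, k, nn_summary) {
  if (is.numeric(distance_threshold)) return(distance_threshold)
  m <- regmatches(distance_threshold,
                  regexec("^quantile:([0-9.]+)$", distance_threshold))[[1]]
  if (length(m) != 2)
    stop("distance_threshold must be numeric or 'quantile:q'")
  q <- as.numeric(m[2]) / 100
  k_int <- min(k, nrow(ref) - 1)
  internal <- FNN::get.knn(ref, k_int)$nn.dist
  ref_means <- if (nn_summary == "mean") rowMeans(internal) else
    internal[, 1]
  stats::quantile(ref_means, q, names = FALSE)
}

#' Top-ranked marker set of a differential expression test
#'
#' Filters to adjusted p-value strictly below `p_cut`, ranks the remaining
#' genes by log2 fold change (signed, descending, ties broken by gene id)
#' and keeps the first `top_n` (478 by default, matching the marker-set
#' size used for Jaccard comparisons).
#'
#' @param mt A `MarkerTable`.
#' @param p_cut Adjusted p cut (strict, default 0.05).
#' @param top_n Set size cap (default 478).
#' @param name Name for the resulting set.
#' @return A [gene_set()].
#' @export
top_marker_set <- function(mt, p_cut = 0.05, top_n = 478,
                           name = "markers") {
  keep <- !is.na(mt$p_adj) & mt$p_adj < p_cut
  sub <- mt[keep, , drop = FALSE]
  ord <- order(-sub$log2fc, sub$gene_id)
  gene_set(name, utils::head(sub$gene_id[ord], top_n))
}

#' Jaccard similarity of two gene sets
#'
#' `|intersection| / |union|`; two empty sets give 0 with a warning.
#'
#' @param a,b `GeneSet`s or character vectors.
#' @return A number in [0, 1].
#' @export
jaccard_similarity <- function(a, b) {
  am <- if (inherits(a, "GeneSet")) a$members else unique(as.character(a))
  bm <- if (inherits(b, "GeneSet")) b$members else unique(as.character(b))
  u <- union(am, bm)
  if (length(u) == 0) {
    warning("both gene sets are empty; Jaccard defined as 0")
    return(0)
  }
  length(intersect(am, bm)) / length(u)
}

#' Pseudobulk expression profile
#'
#' Sums raw counts per gene over a non-empty cell subset, making a
#' single-cell cluster comparable with a bulk RNA-seq sample.
#'
#' @param gem A `GeneExpressionMatrix`.
#' @param cells Cell ids (or indices/mask) of the subset.
#' @return Named integer vector, one total per gene.
#' @export
pseudobulk_profile <- function(gem, cells) {
  idx <- .resolve_index(cells, gem$cell_ids, "cell")
  if (length(idx) == 0) stop("validation error: empty cell subset")
  v <- Matrix::rowSums(gem$counts[, idx, drop = FALSE])
  stats::setNames(as.integer(round(v)), gem$gene_ids)
}

#' Combined PCA of bulk and pseudobulk samples on marker genes
#'
#' Joins per-gene total vectors from bulk samples and single-cell
#' pseudobulks, restricts to a marker gene set, log2(1+x)-transforms,
#' standardizes each gene to mean 0 / SD 1 across samples (zero-variance
#' genes dropped with a warning), and returns principal-component
#' coordinates of the samples with a deterministic sign convention.
#'
#' @param samples Named list of per-gene total vectors (each named by
#'   gene id), or a genes x samples matrix.
#' @param marker_genes A `GeneSet` or character vector of marker genes.
#' @return Samples x PCs coordinate matrix with attribute `var_explained`.
#' @export
combined_pca <- function(samples, marker_genes) {
  if (is.list(samples) && !is.matrix(samples)) {
    genes <- Reduce(intersect, lapply(samples, names))
    mat <- vapply(samples, function(s) as.numeric(s[genes]),
                  numeric(length(genes)))
    rownames(mat) <- genes
  } else {
    mat <- as.matrix(samples)
  }
  if (ncol(mat) < 3) stop("validation error: need >= 3 samples")
  markers <- if (inherits(marker_genes, "GeneSet")) marker_genes$members
  else as.character(marker_genes)
  use <- intersect(markers, rownames(mat))
  mat <- log2(1 + mat[use, , drop = FALSE])
  sds <- apply(mat, 1, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance marker gene(s) dropped")
    mat <- mat[sds > 0, , drop = FALSE]
  }
  if (nrow(mat) < 2)
    stop("fewer than 2 usable marker genes after filtering")
  z <- t(scale(t(mat)))               # per-gene standardization
  pc <- stats::prcomp(t(z), center = FALSE, scale. = FALSE)
  flip <- .sign_convention(pc$rotation)
  coords <- sweep(pc$x, 2, flip, "*")
  rownames(coords) <- colnames(mat)
  structure(coords, var_explained = pc$sdev^2)
}
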