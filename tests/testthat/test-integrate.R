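test_that("PCA embedding matches the eigendecomposition of the covariance", {
  withr::with_seed(31, {
    vals <- matrix(rnorm(20 * 50, 5), 20, 50)   # 20 genes x 50 cells
  })
  rownames(vals) <- sprintf("g%02d", 1:20)
  colnames(vals) <- sprintf("c%02d", 1:50)
  nm <- structure(list(values = vals, log_base = 2),
                  class = "NormalizedMatrix")
  emb <- pca_embed(nm, d = 10)
  ev <- attr(emb, "var_explained")
  oracle <- eigen(stats::cov(t(vals)), symmetric = TRUE)$values
  expect_equal(ev[1:10], oracle[1:10], tolerance = 1e-8)
  rot <- attr(emb, "rotation")
  expect_equal(crossprod(rot), diag(10), tolerance = 1e-9,
               ignore_attr = TRUE)
  # data on a line: PC1 explains everything
  t_line <- seq(0, 1, length.out = 30)
  line <- outer(c(1, 2, -1, 0.5), t_line)
  rownames(line) <- paste0("g", 1:4); colnames(line) <- paste0("c", 1:30)
  nml <- structure(list(values = line, log_base = 2),
                   class = "NormalizedMatrix")
  el <- pca_embed(nml, d = 2)
  vl <- attr(el, "var_explained")
  expect_equal(vl[1] / sum(vl), 1, tolerance = 1e-9)
  expect_error(pca_embed(nm, d = 25), "validation error")
})

test_that("identical batches incur numerically zero MNN correction", {
  withr::with_seed(32, {
    vals <- matrix(rnorm(60 * 80, 4, 2), 60, 80)
  })
  rownames(vals) <- sprintf("g%02d", 1:60)
  colnames(vals) <- sprintf("c%02d", 1:80)
  emb <- mnn_correct(list(vals, vals), d = 20, k = 20)
  n <- 80
  corr <- emb[(n + 1):(2 * n), ] - emb[1:n, ]
  expect_lt(mean(sqrt(rowSums(corr^2))), 1e-6 * stats::sd(emb))
  # single batch: embedding passes through untouched by any merge
  single <- mnn_correct(list(vals), d = 20)
  expect_equal(dim(single), c(80L, 20L))
  expect_identical(attr(single, "batch"), rep("batch1", 80))
})

test_that("a constant embedding-space offset is almost fully removed", {
  n <- 400
  b1 <- offset_clouds(n, seed = 33)
  b2 <- sweep(offset_clouds(n, seed = 133), 2,
              c(rep(2, 5), rep(0, 25)), "+")
  pre <- sqrt(sum((colMeans(b1) - colMeans(b2))^2))
  emb <- mnn_correct_coords(list(b1, b2), k = 20)
  post <- sqrt(sum((colMeans(emb[1:n, ]) -
                      colMeans(emb[(n + 1):(2 * n), ]))^2))
  expect_lte(post / pre, 0.05)
  batch <- attr(emb, "batch")
  ent_pre <- batch_mixing_entropy(rbind(b1, b2), batch)
  ent_post <- batch_mixing_entropy(emb, batch)
  expect_gt(ent_post, ent_pre)
})

test_that("SNN graph equals the brute-force shared-neighbor computation", {
  # three equally spaced collinear points, k = 1: ends share the middle
  e3 <- matrix(c(0, 1, 2), ncol = 1)
  rownames(e3) <- c("a", "b", "c")
  g3 <- build_snn_graph(e3, k = 1, d = 1)
  expect_true(igraph::are_adjacent(g3$graph, "a", "c"))
  # random instance vs exhaustive oracle
  withr::with_seed(34, coords <- matrix(rnorm(30 * 4), 30, 4))
  rownames(coords) <- sprintf("p%02d", 1:30)
  k <- 3
  g <- build_snn_graph(coords, k = k, d = 4)
  dd <- as.matrix(dist(coords))
  # self-inclusive neighbor sets by exhaustive distance sorting
  sets <- lapply(seq_len(30), function(i) {
    ord <- setdiff(order(dd[i, ]), i)[seq_len(k)]
    c(i, ord)
  })
  W <- igraph::as_adjacency_matrix(g$graph, attr = "weight", sparse = FALSE)
  for (i in 1:29) for (j in (i + 1):30) {
    shared <- length(intersect(sets[[i]], sets[[j]]))
    expected <- if (shared > 0)
      shared / length(union(sets[[i]], sets[[j]])) else 0
    expect_equal(W[i, j], expected, tolerance = 1e-12)
  }
  # two distant clouds never connect
  far <- rbind(matrix(rnorm(40, 0, 0.1), 20, 2),
               matrix(rnorm(40, 50, 0.1), 20, 2))
  rownames(far) <- sprintf("f%02d", 1:40)
  gf <- build_snn_graph(far, k = 3, d = 2)
  Wf <- igraph::as_adjacency_matrix(gf$graph, sparse = FALSE)
  expect_equal(sum(Wf[1:20, 21:40]), 0)
  expect_error(build_snn_graph(e3, k = 3, d = 1), "validation error")
})

test_that("Louvain recovers planted structure and is deterministic", {
  cl1 <- igraph::make_full_graph(10)
  cl2 <- igraph::make_full_graph(10)
  g <- igraph::disjoint_union(cl1, cl2)
  igraph::V(g)$name <- paste0("v", 1:20)
  igraph::E(g)$weight <- 1
  lab <- louvain_cluster(g, resolution = 1, seed = 1)
  expect_equal(sort(unique(lab$labels)), c(0L, 1L))
  expect_length(unique(lab$labels[1:10]), 1L)
  expect_length(unique(lab$labels[11:20]), 1L)
  expect_identical(louvain_cluster(g, resolution = 1, seed = 1)$labels,
                   lab$labels)
  # planted partition
  withr::with_seed(35, {
    sbm <- igraph::sample_sbm(100, matrix(c(0.3, 0.01, 0.01, 0.3), 2),
                              c(50, 50))
  })
  igraph::V(sbm)$name <- paste0("n", 1:100)
  igraph::E(sbm)$weight <- 1
  labs <- louvain_cluster(sbm, resolution = 1, seed = 2)
  ari <- mclust::adjustedRandIndex(labs$labels, rep(1:2, each = 50))
  expect_gte(ari, 0.9)
  expect_error(louvain_cluster(igraph::make_empty_graph(0), 1, 1),
               "empty graph")
})

test_that("cluster exclusion flags pluripotency, imbalance and size", {
  withr::with_seed(36, {
    vals <- matrix(rnorm(30 * 90, 2, 0.3), 30, 90)
    vals[1:5, 61:90] <- vals[1:5, 61:90] + 4  # cluster 2 high on pluri genes
  })
  rownames(vals) <- sprintf("g%02d", 1:30)
  colnames(vals) <- sprintf("c%02d", 1:90)
  nm <- structure(list(values = vals, log_base = 2),
                  class = "NormalizedMatrix")
  labels <- structure(list(labels = stats::setNames(
    rep(0:2, each = 30L), colnames(vals)), resolution = 1),
    class = "ClusterLabels")
  reps <- c(rep(c("r1", "r2"), 15),        # cluster 0 balanced
            rep("r1", 30),                 # cluster 1 all one replicate
            rep(c("r1", "r2"), 15))        # cluster 2 balanced
  out <- apply_cluster_exclusion(labels, nm, reps,
                                 pluripotency_genes = sprintf("g%02d", 1:5))
  fl <- out$exclusions
  expect_equal(fl$flag[fl$cluster == 2], "pluripotency")
  expect_equal(fl$flag[fl$cluster == 1], "replicate-imbalance")
  expect_equal(fl$flag[fl$cluster == 0], "none")
  # tiny cluster flagged when otherwise unremarkable
  lab2 <- structure(list(labels = stats::setNames(
    c(rep(0L, 84), rep(1L, 6)), colnames(vals)), resolution = 1),
    class = "ClusterLabels")
  out2 <- apply_cluster_exclusion(lab2, nm, rep(c("r1", "r2"), 45),
                                  pluripotency_genes = "g30",
                                  min_cells = 10)
  expect_equal(out2$exclusions$flag[out2$exclusions$cluster == 1],
               "too-small")
  expect_error(apply_cluster_exclusion(labels, nm, reps, character(0)),
               "pluripotency gene set is empty")
})

test_that("contaminant population is flagged by the pluripotency rule", {
  pops <- list(population_spec("ecA", 120, 2, 1:40, 2.5, 0.2),
               population_spec("ecB", 120, 2, 41:80, 2.5, 0.2))
  contam <- population_spec("plur", 25, 2, 81:105, 3.5, 0.2)
  q <- generate_query_batches(pops, n_genes = 1500, n_replicates = 2,
                              batch_sd = 0.3, contaminant = contam,
                              seed = 37)
  gem <- filter_genes(filter_cells(q$gem, 50))
  nm <- normalize_log(gem, compute_size_factors(gem, "library"))
  hvg <- select_hvgs(nm, replicate_labels(gem), fraction = 0.08)
  reps <- split(seq_len(n_cells(gem)), replicate_labels(gem))
  emb <- mnn_correct(lapply(reps, function(ix)
    nm$values[hvg$gene_id, ix, drop = FALSE]), d = 20, k = 20)
  emb <- emb[gem$cell_ids, , drop = FALSE]
  labels <- louvain_cluster(build_snn_graph(emb, k = 10, d = 20),
                            resolution = 0.4, seed = 3)
  pluri_genes <- q$truth$genes$gene_id[
    q$truth$genes$is_marker_of == "plur"]
  out <- apply_cluster_exclusion(labels, nm, replicate_labels(gem),
                                 intersect(pluri_genes, gem$gene_ids))
  truth <- q$truth$cells$true_type[match(names(labels$labels),
                                         q$truth$cells$cell_id)]
  plur_cluster <- as.integer(names(which.max(
    table(labels$labels[truth == "plur"]))))
  flagged <- out$exclusions$cluster[out$exclusions$flag == "pluripotency"]
  expect_identical(flagged, plur_cluster)
})
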