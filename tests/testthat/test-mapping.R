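test_that("KNN assignment equals the exhaustive all-pairs oracle", {
  withr::with_seed(61, {
    ref <- rbind(matrix(rnorm(150 * 4, 0), 150, 4),
                 matrix(rnorm(150 * 4, 3), 150, 4))
    qry <- matrix(rnorm(120 * 4, 1.5), 120, 4)
  })
  labels <- stats::setNames(rep(c("alpha", "beta"), each = 150),
                            sprintf("ref%03d", 1:300))
  rownames(ref) <- names(labels)
  rownames(qry) <- sprintf("q%03d", 1:120)
  joint <- rbind(qry, ref)
  attr(joint, "origin") <- rep(c("query", "reference"), c(120, 300))
  res <- suppressWarnings(
    knn_assign_types(joint, labels, query_clusters = NULL, k = 25,
                     confidence_threshold = 0, distance_threshold = Inf))
  oracle <- brute_knn_assign(ref, qry, unname(labels), 25)
  lvl <- sort(unique(unname(labels)))
  expect_identical(res$assigned_type, lvl[oracle[, "type"]])
  expect_equal(res$confidence, unname(oracle[, "conf"]), tolerance = 1e-12)
  expect_equal(res$mean_nn_distance, unname(oracle[, "mean_dist"]),
               tolerance = 1e-12)
})

test_that("confidence and distance gates abstain as specified", {
  # 10 reference neighbors at distance ~1: 4 of one type, 3 + 3 of others
  ref <- matrix(0, 40, 2)
  ref[1:10, ] <- cbind(seq(0.9, 1.08, length.out = 10), 0)
  ref[11:40, ] <- 100 + matrix(seq_len(60), 30, 2)     # far away
  labels <- stats::setNames(c(rep("A", 4), rep("B", 3), rep("C", 3),
                              rep("D", 30)), sprintf("r%02d", 1:40))
  rownames(ref) <- names(labels)
  qry <- matrix(c(0, 0), 1, 2, dimnames = list("q1", NULL))
  joint <- rbind(qry, ref)
  attr(joint, "origin") <- c("query", rep("reference", 40))
  expect_warning(
    res <- knn_assign_types(joint, labels, query_clusters = NULL, k = 10,
                            confidence_threshold = 0.5,
                            distance_threshold = 50),
    "small-cluster gate skipped")
  expect_equal(res$confidence, 0.4)
  expect_identical(res$assigned_type, "UNASSIGNED")
  expect_identical(res$gate_reason, "confidence")
  # same neighbors, permissive confidence, strict distance
  res2 <- suppressWarnings(
    knn_assign_types(joint, labels, NULL, k = 10,
                     confidence_threshold = 0.1, distance_threshold = 0.5))
  expect_identical(res2$gate_reason, "distance")
  # unanimous neighbors within gates
  res3 <- suppressWarnings(
    knn_assign_types(joint, labels, NULL, k = 4,
                     confidence_threshold = 0.5, distance_threshold = 50))
  expect_identical(res3$assigned_type, "A")
  expect_equal(res3$confidence, 1.0)
  # small-cluster gate overrides assignment
  res4 <- knn_assign_types(joint, labels,
                           query_clusters = c(q1 = 7L), k = 4,
                           confidence_threshold = 0.5,
                           distance_threshold = 50, min_cluster = 10)
  expect_identical(res4$gate_reason, "small-cluster")
  expect_identical(res4$assigned_type, "UNASSIGNED")
})

test_that("gating is monotone in both thresholds", {
  sc <- run_std_transfer(seed = 700, n_genes = 1200, n_query = 80,
                         n_ref = 250)
  joint <- sc$joint
  truth_cl <- sc$truth
  n_assigned <- function(conf, dist) {
    a <- knn_assign_types(joint, query_clusters = truth_cl, k = 50,
                          confidence_threshold = conf,
                          distance_threshold = dist)
    sum(a$assigned_type != "UNASSIGNED")
  }
  gate <- attr(sc$assignment, "distance_threshold")
  by_conf <- vapply(c(0, 0.25, 0.5, 0.75, 1), n_assigned, numeric(1),
                    dist = gate)
  expect_true(all(diff(by_conf) <= 0))
  by_dist <- vapply(c(2, 1, 0.5, 0.25) * gate, n_assigned, numeric(1),
                    conf = 0.5)
  expect_true(all(diff(by_dist) <= 0))
})

test_that("two-step reference mapping brings same-type cells together", {
  # query with replicate batch shifts; reference carries its own
  # (platform-scale) expression shift on shared gene baselines
  n_genes <- 2000L
  mkpop <- function(name, n, idx) population_spec(name, n, 2, idx, 2.5, 0.2)
  qpops <- list(mkpop("typeA", 150, 1:40), mkpop("typeB", 150, 41:80))
  rpops <- list(mkpop("typeA", 400, 1:40), mkpop("typeB", 400, 41:80))
  bl <- withr::with_seed(71, stats::rlnorm(n_genes, -0.5, 1))
  q <- generate_query_batches(qpops, n_genes = n_genes, n_replicates = 2,
                              batch_sd = 0.3, seed = 72, baselines = bl)
  r <- generate_query_batches(rpops, n_genes = n_genes, n_replicates = 1,
                              batch_sd = 0.4, seed = 73, baselines = bl)
  atlas <- structure(list(
    gem = r$gem,
    labels = stats::setNames(r$truth$cells$true_type,
                             r$truth$cells$cell_id),
    provenance = "synthetic"), class = "ReferenceAtlas")
  nmq <- normalize_log(q$gem, compute_size_factors(q$gem, "library"))
  reps <- split(seq_len(n_cells(q$gem)), replicate_labels(q$gem))
  batches <- lapply(reps, function(ix) {
    nm <- nmq
    nm$values <- nm$values[, ix, drop = FALSE]
    nm
  })
  truth <- stats::setNames(q$truth$cells$true_type, q$truth$cells$cell_id)
  joint <- map_to_reference(batches, atlas, hvg_fraction_ref = 0.10,
                            d = 30, k = 100)
  expect_equal(nrow(joint),
               sum(vapply(batches, function(b) ncol(b$values),
                          integer(1))) + n_cells(atlas$gem))
  origin <- attr(joint, "origin")
  # pre-correction = same feature space and PCA, one combined pseudo-batch
  ref_nm <- normalize_log(atlas$gem,
                          compute_size_factors(atlas$gem, "library"))
  hvg <- select_hvgs(ref_nm, fraction = 0.10)
  shared <- intersect(hvg$gene_id, rownames(batches[[1]]$values))
  all_vals <- cbind(batches[[1]]$values[shared, ],
                    batches[[2]]$values[shared, ],
                    ref_nm$values[shared, ])
  pre <- mnn_correct(list(all_vals), d = 30)
  type_of <- c(truth[colnames(batches[[1]]$values)],
               truth[colnames(batches[[2]]$values)], atlas$labels)
  gap <- function(emb) {
    mean(vapply(c("typeA", "typeB"), function(ty) {
      a <- colMeans(emb[origin == "query" & type_of == ty, , drop = FALSE])
      b <- colMeans(emb[origin == "reference" & type_of == ty,
                        , drop = FALSE])
      sqrt(sum((a - b)^2))
    }, numeric(1)))
  }
  expect_lte(gap(joint), 0.25 * gap(pre))
})

test_that("mapping a dataset onto itself is a near-identity", {
  sc <- std_transfer_scenario(seed = 72, n_genes = 1000, n_query = 100,
                              n_ref = 100)
  nmq <- sc$batches[[1]]
  atlas <- structure(list(nm = nmq,
                          labels = sc$truth[colnames(nmq$values)],
                          provenance = "synthetic"),
                     class = "ReferenceAtlas")
  joint <- map_to_reference(list(nmq), atlas, hvg_fraction_ref = 0.25,
                            d = 15, k = 30)
  nq <- ncol(nmq$values)
  corr <- joint[(nq + 1):(2 * nq), ] - joint[1:nq, ]
  expect_lt(mean(sqrt(rowSums(corr^2))), 1e-6 * stats::sd(joint))
})

test_that("top marker sets follow the filter-sort-slice contract", {
  mt <- structure(data.frame(
    gene_id = sprintf("g%02d", 1:8),
    log2fc = c(3, 2.5, 2.5, 1, -2, 4, 0.5, 2),
    p_raw = rep(0.001, 8),
    p_adj = c(0.01, 0.01, 0.01, 0.05, 0.01, 0.2, 0.001, 0.04),
    stringsAsFactors = FALSE), class = c("MarkerTable", "data.frame"))
  set <- top_marker_set(mt, p_cut = 0.05, top_n = 3)
  # g04 excluded (p_adj == 0.05 strict), g06 excluded (p_adj 0.2)
  expect_identical(set$members, c("g01", "g02", "g03"))
  set_all <- top_marker_set(mt, p_cut = 0.05, top_n = 478)
  expect_length(set_all$members, 6)
  # randomized oracle
  withr::with_seed(73, {
    mt2 <- structure(data.frame(
      gene_id = sprintf("r%03d", 1:200),
      log2fc = rnorm(200), p_raw = runif(200), p_adj = runif(200),
      stringsAsFactors = FALSE), class = c("MarkerTable", "data.frame"))
  })
  s2 <- top_marker_set(mt2, p_cut = 0.3, top_n = 25)
  keep <- mt2[mt2$p_adj < 0.3, ]
  oracle <- head(keep$gene_id[order(-keep$log2fc, keep$gene_id)], 25)
  expect_identical(s2$members, oracle)
})

test_that("jaccard similarity satisfies its identities", {
  expect_equal(jaccard_similarity(c("A", "B", "C"), c("B", "C", "D")), 0.5)
  expect_equal(jaccard_similarity(c("x", "y"), c("x", "y")), 1)
  expect_equal(jaccard_similarity(c("x"), c("y")), 0)
  expect_equal(jaccard_similarity(gene_set("a", c("p", "q")),
                                  gene_set("b", c("q", "p"))), 1)
  expect_warning(j0 <- jaccard_similarity(character(0), character(0)),
                 "empty")
  expect_equal(j0, 0)
  # symmetry on random sets
  withr::with_seed(74, {
    for (i in 1:20) {
      a <- sample(letters, sample(0:10, 1))
      b <- sample(letters, sample(1:10, 1))
      expect_equal(jaccard_similarity(a, b), jaccard_similarity(b, a))
      expect_gte(jaccard_similarity(a, b), 0)
      expect_lte(jaccard_similarity(a, b), 1)
    }
  })
})

test_that("pseudobulk profiles are exact integer sums", {
  cnt <- rbind(c(1, 3, 0), c(2, 4, 5))
  gem <- mk_gem(cnt)
  expect_equal(unname(pseudobulk_profile(gem, "c001")), c(1, 2))
  expect_equal(unname(pseudobulk_profile(gem, c("c001", "c002"))), c(4, 6))
  expect_error(pseudobulk_profile(gem, character(0)), "empty")
  cnt2 <- rand_counts(50, 80, seed = 75)
  g2 <- mk_gem(cnt2)
  sub <- withr::with_seed(76, sample(g2$cell_ids, 30))
  expect_equal(unname(pseudobulk_profile(g2, sub)),
               unname(rowSums(cnt2[, match(sub, g2$cell_ids)])))
})

test_that("combined PCA standardizes genes and separates planted groups", {
  pops <- list(population_spec("A", 60, 2, 1:30, 2.5, 0.2),
               population_spec("B", 60, 2, 31:60, 2.5, 0.2))
  samples <- list()
  for (s in 1:4) {
    r <- generate_reference_atlas(pops, 300, seed = 80 + s)
    for (p in c("A", "B")) {
      cells <- r$truth$cells$cell_id[r$truth$cells$true_type == p]
      samples[[paste0(p, "_s", s)]] <-
        pseudobulk_profile(r$atlas$gem, cells)
    }
  }
  markers <- gene_set("A_markers", sprintf("gene%05d", 1:30))
  coords <- combined_pca(samples, markers)
  expect_equal(nrow(coords), 8)
  grpA <- grepl("^A", rownames(coords))
  # PC1 separates the two sample groups completely
  expect_true(max(coords[grpA, 1]) < min(coords[!grpA, 1]) ||
                min(coords[grpA, 1]) > max(coords[!grpA, 1]))
  # duplicated samples land on identical coordinates
  dup <- samples[c(1, 1, 2, 3)]
  names(dup) <- c("d1", "d2", "o1", "o2")
  cd <- combined_pca(dup, markers)
  expect_equal(cd["d1", ], cd["d2", ], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_error(combined_pca(samples[1:2], markers), "3 samples")
})

test_that("standardization inside combined PCA is exact", {
  withr::with_seed(77, {
    mat <- matrix(rpois(40 * 5, 20), 40, 5)
  })
  rownames(mat) <- sprintf("m%02d", 1:40)
  colnames(mat) <- sprintf("s%d", 1:5)
  lg <- log2(1 + mat)
  z <- t(scale(t(lg)))
  keep <- apply(lg, 1, sd) > 0
  expect_true(all(abs(rowMeans(z[keep, ])) < 1e-9))
  expect_true(all(abs(apply(z[keep, ], 1, sd) - 1) < 1e-9))
  coords <- combined_pca(mat, rownames(mat))
  expect_equal(dim(coords), c(5L, 5L))
})
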