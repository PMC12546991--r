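# Shared fixture builders and independent oracles. Oracles are deliberately
# naive (dense loops, exhaustive search) so they stay independent of the
# package's implementation paths.

mk_gem <- function(mat, replicates = NULL) {
  mat <- as.matrix(mat)
  rownames(mat) <- sprintf("g%03d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("c%03d", seq_len(ncol(mat)))
  meta <- if (!is.null(replicates))
    data.frame(cell_id = colnames(mat), replicate = replicates,
               stringsAsFactors = FALSE) else NULL
  gene_expression_matrix(mat, cell_meta = meta)
}

rand_counts <- function(ng, nc, seed, lambda = 3) {
  withr::with_seed(seed, matrix(stats::rpois(ng * nc, lambda), ng, nc))
}

# exhaustive k-nearest-neighbor assignment oracle (all pairwise distances)
brute_knn_assign <- function(ref, qry, labels, k) {
  t(vapply(seq_len(nrow(qry)), function(i) {
    d <- sqrt(colSums((t(ref) - qry[i, ])^2))
    ord <- order(d)[seq_len(k)]
    votes <- table(labels[ord])
    top <- names(votes)[votes == max(votes)]
    if (length(top) > 1) {
      md <- vapply(top, function(ty) mean(d[ord][labels[ord] == ty]),
                   numeric(1))
      top <- top[order(md, top)]
    }
    c(conf = max(votes) / k, mean_dist = mean(d[ord]),
      type = match(top[1], sort(unique(labels))))
  }, c(conf = 0, mean_dist = 0, type = 0)))
}

# brute-force Benjamini-Hochberg step-up
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# tight two-population clouds in a 30-d "PC-like" space; batch offset tests
offset_clouds <- function(n, seed, sd = 0.03, d = 30) {
  withr::with_seed(seed, {
    grp <- rep(1:2, length.out = n)
    centers <- matrix(0, n, d)
    centers[, 1] <- ifelse(grp == 1, -4, 4)
    centers + matrix(stats::rnorm(n * d, 0, sd), n, d)
  })
}

# standard label-transfer scenario: 3 query populations, typeC absent from
# the reference, replicate batch shifts of sd 0.3, shared gene baselines
std_transfer_scenario <- function(seed, n_genes = 2000L, n_query = 150L,
                                  n_ref = 400L) {
  mkpop <- function(name, n, idx)
    population_spec(name, n, 2, idx, 2.5, 0.2)
  qpops <- list(mkpop("typeA", n_query, 1:40),
                mkpop("typeB", n_query, 41:80),
                mkpop("typeC", n_query, 81:120))
  rpops <- list(mkpop("typeA", n_ref, 1:40), mkpop("typeB", n_ref, 41:80))
  bl <- withr::with_seed(seed, stats::rlnorm(n_genes, -0.5, 1))
  q <- generate_query_batches(qpops, n_genes = n_genes, n_replicates = 2,
                              batch_sd = 0.3, seed = seed + 1,
                              baselines = bl)
  r <- generate_reference_atlas(rpops, n_genes, seed = seed + 2,
                                baselines = bl)
  nmq <- normalize_log(q$gem, compute_size_factors(q$gem, "library"))
  reps <- split(seq_len(n_cells(q$gem)), replicate_labels(q$gem))
  batches <- lapply(reps, function(ix) {
    nm <- nmq
    nm$values <- nm$values[, ix, drop = FALSE]
    nm
  })
  truth <- stats::setNames(q$truth$cells$true_type, q$truth$cells$cell_id)
  list(batches = batches, atlas = r$atlas, truth = truth, query = q)
}

run_std_transfer <- function(seed, ...) {
  sc <- std_transfer_scenario(seed, ...)
  joint <- map_to_reference(sc$batches, sc$atlas, hvg_fraction_ref = 0.10,
                            d = 30, k = 100)
  asg <- knn_assign_types(joint, query_clusters = sc$truth, k = 100,
                          confidence_threshold = 0.5,
                          distance_threshold = "quantile:99",
                          min_cluster = 10)
  tt <- sc$truth[asg$cell_id]
  assigned <- asg$assigned_type != "UNASSIGNED"
  known <- tt != "typeC"
  list(assignment = asg, joint = joint, truth = tt,
       accuracy = mean(asg$assigned_type[assigned & known] ==
                         tt[assigned & known]),
       unassigned_absent = mean(!assigned[tt == "typeC"]))
}

spearman <- function(a, b) stats::cor(a, b, method = "spearman")

# a reduced-size configuration exercising every pipeline stage quickly
small_pipeline_config <- function(seed = 7L) {
  pipeline_config(list(
    global = list(seed = seed),
    simulate = list(
      n_genes = 900L, cycle_gene_count = 25L,
      populations = list(
        list(name = "progenitor", n_cells = 110L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 35L, dispersion = 0.2),
        list(name = "endothelial", n_cells = 110L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 35L, dispersion = 0.2)),
      contaminant = list(name = "pluripotent", n_cells = 15L,
                         baseline_mean = 2, marker_log2fc = 3.5,
                         n_markers = 20L, dispersion = 0.2),
      reference = list(
        list(name = "progenitor", n_cells = 150L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 35L, dispersion = 0.2),
        list(name = "endothelial", n_cells = 150L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 35L, dispersion = 0.2))),
    preprocess = list(min_genes = 50L, hvg_fraction = 0.08),
    integrate = list(d = 20L),
    transfer = list(k = 60L)))
}
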