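# Stage orchestration: simulate -> preprocess -> integrate -> cluster ->
# trajectory -> de -> transfer. Each stage logs one structured line and
# writes its artifacts under the configured output directory; the manifest
# lists every artifact with a path relative to that directory.

.pipeline_stages <- c("simulate", "preprocess", "integrate", "cluster",
                      "trajectory", "de", "transfer")

#' Run the full synthetic-to-transfer pipeline
#'
#' Executes the stages in declared order on a validated configuration (see
#' [pipeline_config()]): synthetic data generation, preprocessing
#' (filtering, normalization, HVGs, cell-cycle regression), MNN
#' integration, SNN/Louvain clustering with exclusion flags, diffusion
#' pseudotime, per-cluster NB differential expression, and reference
#' mapping with KNN type transfer plus marker-set Jaccard similarity.
#' Every stochastic step draws from a seed derived from `global$seed`, so
#' a fixed seed yields byte-identical artifacts across runs.
#'
#' @param config Configuration list from [pipeline_config()].
#' @param outdir Output directory; overrides `config$global$outdir`.
#' @param stages Contiguous prefix of the stage list to run (default all).
#' @return Manifest data.frame (`stage`, `artifact`, `path`), invisibly
#'   also written to `manifest.csv`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL,
                         stages = .pipeline_stages) {
  stages <- match.arg(stages, .pipeline_stages, several.ok = TRUE)
  if (!identical(stages,
                 .pipeline_stages[seq_along(stages)]))
    stop("validation error: stages must be a contiguous prefix of: ",
         paste(.pipeline_stages, collapse = ", "))
  for (blk in c("global", stages)) {
    if (is.null(config[[blk]]))
      stop("validation error: configuration is missing required block '",
           blk, "'")
  }
  if (is.null(outdir)) outdir <- config$global$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$global$seed
  state <- new.env(parent = emptyenv())
  manifest <- data.frame(stage = character(0), artifact = character(0),
                         path = character(0), stringsAsFactors = FALSE)
  add <- function(stage, artifact, path) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artifact = artifact,
      path = sub(paste0("^", outdir, "/?"), "", path),
      stringsAsFactors = FALSE))
  }
  for (st in stages) {
    res <- tryCatch(
      switch(st,
             simulate = .stage_simulate(config, seed, outdir, state, add),
             preprocess = .stage_preprocess(config, outdir, state, add),
             integrate = .stage_integrate(config, outdir, state, add),
             cluster = .stage_cluster(config, seed, outdir, state, add),
             trajectory = .stage_trajectory(config, outdir, state, add),
             de = .stage_de(config, outdir, state, add),
             transfer = .stage_transfer(config, outdir, state, add)),
      error = function(e)
        stop("pipeline stage '", st, "' failed: ", conditionMessage(e),
             call. = FALSE))
  }
  write_results(manifest, file.path(outdir, "manifest.csv"))
  invisible(manifest)
}

.log_stage <- function(stage, params, shapes) {
  message(sprintf("[%s] %s | %s", stage,
                  paste(names(params), unlist(params), sep = "=",
                        collapse = " "),
                  shapes))
}

# Translate the config's population descriptions (name, n_cells,
# baseline_mean, marker_log2fc, n_markers, dispersion) into PopulationSpec
# objects with disjoint marker blocks shared across query and reference by
# population name.
.pop_specs_from_config <- function(sim) {
  descs <- c(sim$populations,
             if (!is.null(sim$contaminant)) list(sim$contaminant),
             sim$reference)
  blocks <- list(); nxt <- 1L
  for (d in descs) {
    if (is.null(blocks[[d$name]])) {
      blocks[[d$name]] <- seq.int(nxt, nxt + d$n_markers - 1L)
      nxt <- nxt + d$n_markers
    }
  }
  if (nxt - 1L > sim$n_genes)
    stop("validation error: marker blocks exceed n_genes")
  mk <- function(d) population_spec(d$name, d$n_cells, d$baseline_mean,
                                    blocks[[d$name]], d$marker_log2fc,
                                    d$dispersion)
  list(populations = lapply(sim$populations, mk),
       contaminant = if (!is.null(sim$contaminant)) mk(sim$contaminant),
       reference = lapply(sim$reference, mk))
}

.stage_simulate <- function(config, seed, outdir, state, add) {
  sim <- config$simulate
  specs <- .pop_specs_from_config(sim)
  baselines <- withr::with_seed(seed, .gene_baselines(sim$n_genes))
  query <- generate_query_batches(
    specs$populations, n_genes = sim$n_genes,
    n_replicates = sim$n_replicates, batch_sd = sim$batch_sd,
    cycle_fraction = sim$cycle_fraction,
    cycle_gene_count = sim$cycle_gene_count,
    cycle_log2fc = sim$cycle_log2fc, contaminant = specs$contaminant,
    seed = seed + 1L, lib_size_sd = sim$lib_size_sd,
    baselines = baselines)
  ref <- generate_reference_atlas(
    specs$reference, n_genes = sim$n_genes, seed = seed + 2L,
    lib_size_sd = sim$lib_size_sd, baselines = baselines)
  state$query <- query; state$ref <- ref
  qdir <- file.path(outdir, "query_counts")
  write_count_matrix(query$gem, qdir)
  rdir <- file.path(outdir, "reference_counts")
  write_count_matrix(ref$atlas$gem, rdir)
  write_results(query$truth$cells, file.path(outdir, "truth_cells.csv"))
  write_results(query$truth$genes, file.path(outdir, "truth_genes.csv"))
  write_results(data.frame(cell_id = names(ref$atlas$labels),
                           type = unname(ref$atlas$labels),
                           stringsAsFactors = FALSE),
                file.path(outdir, "reference_labels.csv"))
  add("simulate", "query_counts", file.path(qdir, "matrix.mtx"))
  add("simulate", "reference_counts", file.path(rdir, "matrix.mtx"))
  add("simulate", "truth_cells", file.path(outdir, "truth_cells.csv"))
  add("simulate", "truth_genes", file.path(outdir, "truth_genes.csv"))
  add("simulate", "reference_labels",
      file.path(outdir, "reference_labels.csv"))
  .log_stage("simulate",
             list(seed = seed, n_genes = sim$n_genes,
                  replicates = sim$n_replicates, batch_sd = sim$batch_sd),
             sprintf("query=%dx%d reference=%dx%d",
                     n_genes(query$gem), n_cells(query$gem),
                     n_genes(ref$atlas$gem), n_cells(ref$atlas$gem)))
}

.stage_preprocess <- function(config, outdir, state, add) {
  pp <- config$preprocess
  gem <- filter_genes(filter_cells(state$query$gem, pp$min_genes))
  sf <- compute_size_factors(gem, method = pp$size_factor_method)
  nm <- normalize_log(gem, sf)
  truth <- state$query$truth
  cycle_genes <- intersect(truth$cycle_genes, gem$gene_ids)
  hvg <- select_hvgs(nm, replicate_labels(gem), exclude = cycle_genes,
                     fraction = pp$hvg_fraction)
  cc <- NULL
  if (length(cycle_genes) >= 2) {
    markers <- truth$genes$gene_id[truth$genes$is_marker_of != ""]
    pairs <- cycle_marker_pairs(nm, cycle_genes,
                                log2fc = config$simulate$cycle_log2fc,
                                exclude = markers)
    cc <- score_cell_cycle(nm, pairs, threshold = pp$g2m_threshold)
    if (length(unique(cc$phase)) == 2)
      nm <- regress_out_covariate(nm, cc$phase == "G2/M")
  }
  state$gem <- gem; state$nm <- nm; state$hvg <- hvg; state$cc <- cc
  write_results(data.frame(cell_id = names(sf), size_factor = unname(sf),
                           stringsAsFactors = FALSE),
                file.path(outdir, "size_factors.csv"))
  write_results(as.data.frame(hvg), file.path(outdir, "hvgs.csv"))
  if (!is.null(cc))
    write_results(cc, file.path(outdir, "cell_cycle.csv"))
  add("preprocess", "size_factors", file.path(outdir, "size_factors.csv"))
  add("preprocess", "hvgs", file.path(outdir, "hvgs.csv"))
  if (!is.null(cc))
    add("preprocess", "cell_cycle", file.path(outdir, "cell_cycle.csv"))
  .log_stage("preprocess",
             list(min_genes = pp$min_genes, hvg_fraction = pp$hvg_fraction,
                  sf_method = pp$size_factor_method),
             sprintf("kept=%dx%d hvgs=%d", n_genes(gem), n_cells(gem),
                     nrow(hvg)))
}

.stage_integrate <- function(config, outdir, state, add) {
  ig <- config$integrate
  reps <- split(seq_len(n_cells(state$gem)), replicate_labels(state$gem))
  vals <- state$nm$values[state$hvg$gene_id, , drop = FALSE]
  batches <- lapply(reps, function(ix) vals[, ix, drop = FALSE])
  d_use <- min(ig$d, nrow(vals) - 1, ncol(vals) - 1)
  emb <- mnn_correct(batches, d = d_use, k = ig$k_mnn)
  # restore original cell order (split() groups by replicate)
  emb_ordered <- emb[state$gem$cell_ids, , drop = FALSE]
  attr(emb_ordered, "space") <- attr(emb, "space")
  state$embedding <- emb_ordered
  write_results(emb_ordered, file.path(outdir, "embedding.csv"))
  add("integrate", "embedding", file.path(outdir, "embedding.csv"))
  .log_stage("integrate", list(d = d_use, k = ig$k_mnn),
             sprintf("cells=%d dims=%d", nrow(emb_ordered),
                     ncol(emb_ordered)))
}

.stage_cluster <- function(config, seed, outdir, state, add) {
  cl <- config$cluster
  g <- build_snn_graph(state$embedding, k = cl$k_snn, d = cl$d)
  lseed <- if (is.null(cl$seed)) seed + 4L else cl$seed
  labels <- louvain_cluster(g, resolution = cl$resolution, seed = lseed)
  truth_genes <- state$query$truth$genes
  contam <- setdiff(unique(unlist(strsplit(
    truth_genes$is_marker_of, ";"))),
    c("", vapply(.pop_specs_from_config(config$simulate)$populations,
                 `[[`, character(1), "name")))
  pluri <- truth_genes$gene_id[
    vapply(strsplit(truth_genes$is_marker_of, ";"),
           function(x) any(x %in% contam), logical(1))]
  pluri <- intersect(pluri, rownames(state$nm$values))
  if (length(pluri)) {
    labels <- apply_cluster_exclusion(
      labels, state$nm, replicate_labels(state$gem), pluri,
      min_cells = cl$min_cells,
      imbalance_threshold = cl$imbalance_threshold)
  } else {
    labels$exclusions <- data.frame(
      cluster = sort(unique(labels$labels)),
      n_cells = as.integer(table(labels$labels)),
      flag = "none", stringsAsFactors = FALSE)
  }
  state$graph <- g; state$clusters <- labels
  out <- data.frame(cell_id = names(labels$labels),
                    cluster = unname(labels$labels),
                    stringsAsFactors = FALSE)
  out$flag <- labels$exclusions$flag[match(out$cluster,
                                           labels$exclusions$cluster)]
  write_results(out, file.path(outdir, "clusters.csv"))
  add("cluster", "clusters", file.path(outdir, "clusters.csv"))
  .log_stage("cluster",
             list(k = cl$k_snn, resolution = cl$resolution, seed = lseed),
             sprintf("clusters=%d flagged=%d",
                     nrow(labels$exclusions),
                     sum(labels$exclusions$flag != "none")))
}

.stage_trajectory <- function(config, outdir, state, add) {
  tr <- config$trajectory
  dc <- diffusion_components(state$embedding, n_comps = tr$n_comps,
                             k = tr$k)
  root <- if (identical(tr$root, "auto")) {
    keep <- retained_cells(state$clusters)
    kept_lab <- state$clusters$labels[keep]
    biggest <- names(sort(table(kept_lab), decreasing = TRUE))[1]
    cluster_medoid(dc, structure(list(labels = kept_lab),
                                 class = "ClusterLabels"),
                   as.integer(biggest))
  } else tr$root
  pt <- diffusion_pseudotime(dc, root)
  conn <- paga_connectivity(state$graph, state$clusters)
  state$pseudotime <- pt
  write_results(dc, file.path(outdir, "diffusion.csv"))
  write_results(pt, file.path(outdir, "pseudotime.csv"))
  write_results(as.matrix(conn), file.path(outdir, "connectivity.csv"))
  add("trajectory", "diffusion", file.path(outdir, "diffusion.csv"))
  add("trajectory", "pseudotime", file.path(outdir, "pseudotime.csv"))
  add("trajectory", "connectivity", file.path(outdir, "connectivity.csv"))
  .log_stage("trajectory",
             list(n_comps = tr$n_comps, k = tr$k, root = root),
             sprintf("cells=%d", nrow(dc)))
}

.stage_de <- function(config, outdir, state, add) {
  de <- config$de
  keep <- retained_cells(state$clusters)
  gem <- subset_cells(state$gem, keep)
  lab <- state$clusters$labels[keep]
  sizes <- table(lab)
  usable <- names(sizes)[sizes >= 3]
  design <- build_design(cluster = lab,
                         replicate = replicate_labels(gem),
                         depth = Matrix::colSums(gem$counts))
  disp <- estimate_dispersion(gem, design, shrink_weight = de$shrink_weight)
  fit <- fit_nb_glm(gem, design, disp)
  tables <- lapply(usable, function(cl) {
    tb <- test_contrast(fit, contrast_vs_rest(design, cl))
    tb$cluster <- cl
    tb
  })
  names(tables) <- usable
  state$marker_tables <- tables
  combined <- do.call(rbind, tables)
  write_results(combined, file.path(outdir, "markers.csv"))
  add("de", "markers", file.path(outdir, "markers.csv"))
  .log_stage("de", list(clusters = length(usable),
                        genes = n_genes(gem)),
             sprintf("significant=%d",
                     sum(combined$p_adj < de$p_cut, na.rm = TRUE)))
}

.stage_transfer <- function(config, outdir, state, add) {
  tf <- config$transfer
  reps <- split(seq_len(n_cells(state$gem)), replicate_labels(state$gem))
  query_batches <- lapply(reps, function(ix) {
    nm <- state$nm
    nm$values <- nm$values[, ix, drop = FALSE]
    nm
  })
  k_map <- min(tf$k, min(vapply(query_batches,
                                function(q) ncol(q$values), integer(1))))
  joint <- map_to_reference(query_batches, state$ref$atlas,
                            hvg_fraction_ref = tf$hvg_fraction_ref,
                            d = config$integrate$d, k = k_map)
  assign <- knn_assign_types(
    joint, query_clusters = state$clusters,
    k = min(tf$k, n_cells(state$ref$atlas$gem)),
    confidence_threshold = tf$confidence_threshold,
    distance_threshold = tf$distance_threshold,
    min_cluster = tf$min_cluster)
  write_results(assign, file.path(outdir, "assignments.csv"))
  add("transfer", "assignments", file.path(outdir, "assignments.csv"))
  # marker-set Jaccard: per-cluster top markers vs reference truth programs
  ref_truth <- state$ref$truth$genes
  ref_sets <- lapply(split(ref_truth$gene_id[ref_truth$is_marker_of != ""],
                           ref_truth$is_marker_of[
                             ref_truth$is_marker_of != ""]),
                     function(g) gene_set("ref", g))
  if (length(state$marker_tables) && length(ref_sets)) {
    jac <- sapply(ref_sets, function(rs)
      vapply(state$marker_tables, function(tb)
        jaccard_similarity(top_marker_set(tb, top_n = tf$top_n), rs),
        numeric(1)))
    jac <- matrix(jac, nrow = length(state$marker_tables),
                  dimnames = list(names(state$marker_tables),
                                  names(ref_sets)))
    write_results(as.matrix(jac), file.path(outdir, "jaccard.csv"))
    add("transfer", "jaccard", file.path(outdir, "jaccard.csv"))
  }
  .log_stage("transfer",
             list(k = k_map, confidence = tf$confidence_threshold,
                  distance = tf$distance_threshold),
             sprintf("assigned=%d/%d",
                     sum(assign$assigned_type != "UNASSIGNED"),
                     nrow(assign)))
}
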