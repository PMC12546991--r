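#' Default pipeline configuration
#'
#' Returns the full nested list of stage parameter blocks with their
#' defaults. Thresholds mirror the analysis conventions this package
#' implements: top 5% highly variable genes, G2/M score cut 0.2, MNN with
#' d = 30 / k = 20, SNN Louvain clustering, transfer with k = 100 and
#' confidence gate 0.5. Simulation sizes are chosen so a full run completes
#' in well under a minute on one core.
#'
#' @return Nested named list of parameter blocks.
#' @export
default_config <- function() {
  list(
    global = list(seed = 1L, outdir = "ecmapper_run"),
    simulate = list(
      n_genes = 2500L,
      n_replicates = 2L,
      batch_sd = 0.3,
      cycle_fraction = 0.2,
      cycle_gene_count = 40L,
      cycle_log2fc = 1.5,
      lib_size_sd = 0.25,
      populations = list(
        list(name = "progenitor", n_cells = 220L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 40L, dispersion = 0.2),
        list(name = "endothelial", n_cells = 220L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 40L, dispersion = 0.2)
      ),
      contaminant = list(name = "pluripotent", n_cells = 20L,
                         baseline_mean = 2, marker_log2fc = 3.5,
                         n_markers = 25L, dispersion = 0.2),
      reference = list(
        list(name = "progenitor", n_cells = 300L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 40L, dispersion = 0.2),
        list(name = "endothelial", n_cells = 300L, baseline_mean = 2,
             marker_log2fc = 2.5, n_markers = 40L, dispersion = 0.2)
      )
    ),
    preprocess = list(min_genes = 100L, hvg_fraction = 0.05,
                      g2m_threshold = 0.2, size_factor_method = "pooled"),
    integrate = list(d = 30L, k_mnn = 20L),
    cluster = list(k_snn = 10L, d = 30L, resolution = 0.4, seed = NULL,
                   min_cells = 10L, imbalance_threshold = 0.9),
    trajectory = list(n_comps = 10L, k = 20L, root = "auto"),
    de = list(p_cut = 0.05, fc_cut = 1.5, shrink_weight = 0.3,
              depth_scale = "log"),
    transfer = list(k = 100L, confidence_threshold = 0.5,
                    distance_threshold = "quantile:99", min_cluster = 10L,
                    hvg_fraction_ref = 0.10, top_n = 478L)
  )
}

#' Build and validate a pipeline configuration
#'
#' Merges user-supplied values over [default_config()]. Unknown blocks or
#' unknown keys within a block are rejected rather than silently ignored,
#' so typos cannot disable a stage parameter.
#'
#' @param user Nested named list of overrides (possibly empty).
#' @return Validated configuration list.
#' @export
pipeline_config <- function(user = list()) {
  defaults <- default_config()
  if (length(user) == 0) return(defaults)
  if (is.null(names(user)) || any(names(user) == ""))
    stop("validation error: configuration blocks must be named")
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("validation error: unknown configuration block(s): ",
         paste(unknown, collapse = ", "))
  # keys whose values are free-form lists, not checked key-by-key
  opaque <- c("populations", "contaminant", "reference")
  for (blk in names(user)) {
    ub <- user[[blk]]
    if (is.null(ub)) { defaults[blk] <- list(NULL); next }
    if (!is.list(ub)) stop("validation error: block '", blk,
                           "' must be a named list")
    bad <- setdiff(names(ub), names(defaults[[blk]]))
    if (length(bad))
      stop(sprintf("validation error: unknown key(s) in block '%s': %s",
                   blk, paste(bad, collapse = ", ")))
    for (key in names(ub)) {
      if (key %in% opaque) defaults[[blk]][key] <- list(ub[[key]])
      else defaults[[blk]][[key]] <- ub[[key]]
    }
  }
  seed <- defaults$global$seed
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed))
    stop("validation error: global$seed must be a single integer")
  defaults$global$seed <- as.integer(seed)
  defaults
}

#' Read a pipeline configuration from YAML
#' @param path Path to a YAML file of configuration blocks.
#' @return Validated configuration list.
#' @export
read_pipeline_config <- function(path) {
  pipeline_config(yaml::read_yaml(path))
}
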