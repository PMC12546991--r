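#' Describe a simulated cell population
#'
#' A population is a cell type with a marker program: a set of genes whose
#' negative-binomial mean is shifted up by `marker_log2fc` relative to the
#' shared per-gene baseline. Counts for gene g in population p are drawn
#' NB(mu, phi) with `Var = mu + phi * mu^2` and
#' `mu = b_g * baseline_mean * 2^marker_log2fc` for markers,
#' `b_g * baseline_mean` otherwise, where `b_g` is a per-gene baseline drawn
#' once per dataset.
#'
#' @param name Population name (unique within a dataset).
#' @param n_cells Cells per dataset (per replicate for query batches).
#' @param baseline_mean Positive scale of the per-gene NB mean.
#' @param marker_genes Integer indices of this population's marker genes.
#' @param marker_log2fc Positive log2 effect size of markers over baseline.
#' @param dispersion NB dispersion phi (> 0).
#' @return A `PopulationSpec` list.
#' @export
population_spec <- function(name, n_cells, baseline_mean, marker_genes,
                            marker_log2fc, dispersion) {
  stopifnot(is.character(name), length(name) == 1)
  n_cells <- as.integer(n_cells)
  if (n_cells < 1L) stop("validation error: n_cells must be >= 1")
  if (baseline_mean <= 0) stop("validation error: baseline_mean must be > 0")
  if (dispersion <= 0) stop("validation error: dispersion must be > 0")
  if (marker_log2fc < 0) stop("validation error: marker_log2fc must be >= 0")
  marker_genes <- as.integer(marker_genes)
  if (anyDuplicated(marker_genes))
    stop("validation error: duplicate marker gene indices")
  structure(list(name = name, n_cells = n_cells,
                 baseline_mean = baseline_mean,
                 marker_genes = marker_genes,
                 marker_log2fc = marker_log2fc,
                 dispersion = dispersion),
            class = "PopulationSpec")
}

.check_population_list <- function(populations, n_genes,
                                   allow_marker_overlap) {
  nm <- vapply(populations, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("validation error: population names not unique")
  all_markers <- unlist(lapply(populations, `[[`, "marker_genes"))
  if (length(all_markers) && max(all_markers) > n_genes)
    stop("validation error: marker index exceeds n_genes")
  if (length(all_markers) && min(all_markers) < 1L)
    stop("validation error: marker index below 1")
  if (!allow_marker_overlap && anyDuplicated(all_markers))
    stop("validation error: marker sets overlap between populations; ",
         "set allow_marker_overlap = TRUE to declare this intentional")
  invisible(nm)
}

# Per-gene baseline scale b_g, log-normal with mean 1 so baseline_mean sets
# the average expression level.
.gene_baselines <- function(n_genes) {
  stats::rlnorm(n_genes, meanlog = -0.5, sdlog = 1)
}

# Expected-mean matrix genes x populations (before batch / library factors).
.population_mu <- function(populations, baselines) {
  mu <- vapply(populations, function(p) {
    m <- baselines * p$baseline_mean
    m[p$marker_genes] <- m[p$marker_genes] * 2^p$marker_log2fc
    m
  }, numeric(length(baselines)))
  colnames(mu) <- vapply(populations, `[[`, character(1), "name")
  mu
}

# NB sampler in (mu, phi) parameterization; Poisson limit for tiny phi.
.rnb <- function(n, mu, phi) {
  if (phi < 1e-10) stats::rpois(n, mu) else
    stats::rnbinom(n, size = 1 / phi, mu = mu)
}

.gene_truth <- function(populations, n_genes, gene_ids) {
  is_marker_of <- character(n_genes)
  true_log2fc <- numeric(n_genes)
  for (p in populations) {
    idx <- p$marker_genes
    has <- is_marker_of[idx] != ""
    is_marker_of[idx] <- ifelse(has, paste(is_marker_of[idx], p$name,
                                           sep = ";"), p$name)
    true_log2fc[idx] <- pmax(true_log2fc[idx], p$marker_log2fc)
  }
  data.frame(gene_id = gene_ids, is_marker_of = is_marker_of,
             true_log2fc = true_log2fc, is_cycle_gene = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a labeled synthetic reference atlas
#'
#' Emulates a labeled in vivo atlas: one count matrix with a ground-truth
#' cell-type label per cell and exactly the requested number of cells per
#' population. Library-size variation is multiplicative log-normal per cell
#' (`lib_size_sd = 0` disables it, giving pure NB counts for moment checks).
#'
#' @param populations List of [population_spec()] objects.
#' @param n_genes Number of genes.
#' @param seed Integer seed; fixed seed gives identical output.
#' @param lib_size_sd SD of the per-cell log-normal library-size factor.
#' @param allow_marker_overlap Declare that marker sets may overlap.
#' @param prefix Cell-id prefix.
#' @param baselines Optional per-gene baseline scales `b_g`; supply the
#'   same vector to [generate_query_batches()] so that reference and query
#'   share the same underlying expression profiles (the situation label
#'   transfer assumes). Drawn from the seed when `NULL`.
#' @return A list with `atlas` (class `ReferenceAtlas`: `gem`, `labels`,
#'   `provenance`) and `truth` (`SyntheticTruth`: `cells`, `genes`, `mu`,
#'   `lib_size`).
#' @export
generate_reference_atlas <- function(populations, n_genes, seed,
                                     lib_size_sd = 0.25,
                                     allow_marker_overlap = FALSE,
                                     prefix = "ref", baselines = NULL) {
  .check_population_list(populations, n_genes, allow_marker_overlap)
  if (!is.null(baselines) && length(baselines) != n_genes)
    stop("validation error: baselines must have length n_genes")
  withr::with_seed(as.integer(seed), {
    if (is.null(baselines)) baselines <- .gene_baselines(n_genes)
    mu <- .population_mu(populations, baselines)
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    blocks <- list(); labels <- character(0); libs <- numeric(0)
    for (p in populations) {
      s <- if (lib_size_sd > 0)
        stats::rlnorm(p$n_cells, 0, lib_size_sd) else rep(1, p$n_cells)
      cell_mu <- outer(mu[, p$name], s)
      y <- .rnb(length(cell_mu), as.vector(cell_mu), p$dispersion)
      blocks[[p$name]] <- matrix(y, nrow = n_genes)
      labels <- c(labels, rep(p$name, p$n_cells))
      libs <- c(libs, s)
    }
    counts <- do.call(cbind, blocks)
    cell_ids <- sprintf("%s_%05d", prefix, seq_len(ncol(counts)))
    gem <- gene_expression_matrix(counts, gene_ids = gene_ids,
                                  cell_ids = cell_ids)
    names(labels) <- cell_ids
    truth <- list(
      cells = data.frame(cell_id = cell_ids, true_type = labels,
                         replicate = "r1", cycle_phase = "G1/S",
                         stringsAsFactors = FALSE),
      genes = .gene_truth(populations, n_genes, gene_ids),
      mu = mu, lib_size = stats::setNames(libs, cell_ids))
    class(truth) <- "SyntheticTruth"
    atlas <- structure(list(gem = gem, labels = labels,
                            provenance = "synthetic"),
                       class = "ReferenceAtlas")
    list(atlas = atlas, truth = truth)
  })
}

#' Generate multi-replicate query batches with batch, cycle and contaminant
#' structure
#'
#' Emulates a two-replicate in vitro scRNA-seq experiment: each population
#' contributes `n_cells` cells per replicate; every replicate applies an
#' independent gene-wise multiplicative batch factor `2^N(0, batch_sd^2)`;
#' a fraction of cells receives an additive log-mean up-shift on a
#' designated cycle-gene program and is labeled G2/M; an optional
#' contaminant population (e.g. residual pluripotent cells) carries its own
#' marker program and truth label.
#'
#' @inheritParams generate_reference_atlas
#' @param n_replicates Number of replicates (>= 1).
#' @param batch_sd SD of the per-gene log2 batch factor (>= 0).
#' @param cycle_fraction Fraction of cells in G2/M phase.
#' @param cycle_gene_count Number of designated cycle genes.
#' @param cycle_log2fc log2 up-shift of cycle genes in G2/M cells.
#' @param contaminant Optional [population_spec()] for the contaminant.
#' @return A list with `gem` and `truth`; `truth$genes$is_cycle_gene` marks
#'   the cycle program and `truth$batch_factors` records the gene x
#'   replicate factors actually applied.
#' @export
generate_query_batches <- function(populations, n_genes, n_replicates = 2,
                                   batch_sd = 0.3, cycle_fraction = 0,
                                   cycle_gene_count = 0, cycle_log2fc = 1.5,
                                   contaminant = NULL, seed = 1,
                                   lib_size_sd = 0.25,
                                   allow_marker_overlap = FALSE,
                                   prefix = "query", baselines = NULL) {
  if (n_replicates < 1) stop("validation error: n_replicates must be >= 1")
  if (batch_sd < 0) stop("validation error: batch_sd must be >= 0")
  if (cycle_gene_count > n_genes)
    stop("validation error: cycle_gene_count exceeds n_genes")
  if (cycle_fraction < 0 || cycle_fraction > 1)
    stop("validation error: cycle_fraction must be in [0, 1]")
  all_pops <- c(populations, if (!is.null(contaminant)) list(contaminant))
  .check_population_list(all_pops, n_genes, allow_marker_overlap)
  if (!is.null(baselines) && length(baselines) != n_genes)
    stop("validation error: baselines must have length n_genes")
  withr::with_seed(as.integer(seed), {
    if (is.null(baselines)) baselines <- .gene_baselines(n_genes)
    mu <- .population_mu(all_pops, baselines)
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    batch_factors <- matrix(2^stats::rnorm(n_genes * n_replicates, 0,
                                           batch_sd),
                            nrow = n_genes,
                            dimnames = list(gene_ids,
                                            paste0("r", seq_len(n_replicates))))
    marker_idx <- unlist(lapply(all_pops, `[[`, "marker_genes"))
    eligible <- setdiff(seq_len(n_genes), marker_idx)
    if (cycle_gene_count > length(eligible))
      stop("validation error: not enough non-marker genes for the cycle program")
    cycle_genes <- sort(sample(eligible, cycle_gene_count))

    total_cells <- sum(vapply(all_pops, `[[`, integer(1), "n_cells")) *
      n_replicates
    n_g2m <- floor(cycle_fraction * total_cells)
    g2m_global <- sample.int(total_cells, n_g2m)

    dispers <- stats::setNames(vapply(all_pops, `[[`, numeric(1),
                                      "dispersion"),
                               colnames(mu))
    cols <- list(); type <- character(0); repl <- character(0)
    libs <- numeric(0)
    cell_counter <- 0L
    phase <- rep("G1/S", total_cells)
    phase[g2m_global] <- "G2/M"
    for (r in seq_len(n_replicates)) {
      for (p in all_pops) {
        s <- if (lib_size_sd > 0)
          stats::rlnorm(p$n_cells, 0, lib_size_sd) else rep(1, p$n_cells)
        base_mu <- mu[, p$name] * batch_factors[, r]
        cell_mu <- outer(base_mu, s)
        idx <- cell_counter + seq_len(p$n_cells)
        in_g2m <- phase[idx] == "G2/M"
        if (any(in_g2m) && cycle_gene_count > 0)
          cell_mu[cycle_genes, in_g2m] <-
            cell_mu[cycle_genes, in_g2m] * 2^cycle_log2fc
        y <- .rnb(length(cell_mu), as.vector(cell_mu), dispers[[p$name]])
        cols[[length(cols) + 1L]] <- matrix(y, nrow = n_genes)
        type <- c(type, rep(p$name, p$n_cells))
        repl <- c(repl, rep(paste0("r", r), p$n_cells))
        libs <- c(libs, s)
        cell_counter <- cell_counter + p$n_cells
      }
    }
    counts <- do.call(cbind, cols)
    cell_ids <- sprintf("%s_%05d", prefix, seq_len(total_cells))
    meta <- data.frame(cell_id = cell_ids, replicate = repl,
                       stringsAsFactors = FALSE)
    gem <- gene_expression_matrix(counts, gene_ids = gene_ids,
                                  cell_ids = cell_ids, cell_meta = meta)
    gtruth <- .gene_truth(all_pops, n_genes, gene_ids)
    gtruth$is_cycle_gene[cycle_genes] <- TRUE
    truth <- list(
      cells = data.frame(cell_id = cell_ids, true_type = type,
                         replicate = repl, cycle_phase = phase,
                         stringsAsFactors = FALSE),
      genes = gtruth, mu = mu, batch_factors = batch_factors,
      cycle_genes = gene_ids[cycle_genes], cycle_log2fc = cycle_log2fc,
      lib_size = stats::setNames(libs, cell_ids))
    class(truth) <- "SyntheticTruth"
    list(gem = gem, truth = truth)
  })
}

#' Generate a linear-trajectory dataset
#'
#' Cells are placed uniformly on a latent coordinate t in `[0, 1]`
#' (an evenly spaced grid). Each program gene's NB log-mean interpolates
#' linearly (hence monotonically) between a start and an end level, half the
#' program rising and half falling; remaining genes are stationary noise.
#' Used as the test bed for diffusion-component and pseudotime recovery.
#'
#' @param n_cells Number of cells (>= 3).
#' @param n_genes Number of genes.
#' @param program_length Number of trajectory program genes (<= n_genes).
#' @param seed Integer seed.
#' @param dispersion NB dispersion of all genes.
#' @param mu_low,mu_high Expression levels at the two ends of the program.
#' @return List with `gem`, `t` (named latent positions) and
#'   `expected_means` (genes x cells matrix of NB means).
#' @export
generate_trajectory_dataset <- function(n_cells, n_genes, program_length,
                                        seed = 1, dispersion = 0.1,
                                        mu_low = 1, mu_high = 20) {
  if (n_cells < 3) stop("validation error: n_cells must be >= 3")
  if (program_length > n_genes)
    stop("validation error: program_length exceeds n_genes")
  withr::with_seed(as.integer(seed), {
    t <- seq(0, 1, length.out = n_cells)
    gene_ids <- sprintf("gene%05d", seq_len(n_genes))
    cell_ids <- sprintf("traj_%05d", seq_len(n_cells))
    lmu <- matrix(log(.gene_baselines(n_genes) * 5), n_genes, n_cells)
    n_up <- ceiling(program_length / 2)
    up <- seq_len(n_up)
    down <- setdiff(seq_len(program_length), up)
    lmu[up, ] <- outer(rep(1, n_up), (1 - t)) * log(mu_low) +
      outer(rep(1, n_up), t) * log(mu_high)
    if (length(down))
      lmu[down, ] <- outer(rep(1, length(down)), (1 - t)) * log(mu_high) +
        outer(rep(1, length(down)), t) * log(mu_low)
    mu <- exp(lmu)
    y <- .rnb(length(mu), as.vector(mu), dispersion)
    gem <- gene_expression_matrix(matrix(y, nrow = n_genes),
                                  gene_ids = gene_ids, cell_ids = cell_ids)
    list(gem = gem, t = stats::setNames(t, cell_ids), expected_means = mu,
         program_genes = gene_ids[seq_len(program_length)])
  })
}
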