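#' Build a design for negative-binomial differential expression
#'
#' Encodes the regression used for all tests: cluster (one-hot, no
#' intercept), replicate (treatment-coded) and sequencing depth (total
#' counts per cell) as predictors of each gene's raw counts under a log
#' link. Depth enters on the log scale by default, the natural scale for a
#' log-link model; the raw scale is retained as an option.
#'
#' @param cluster Per-cell categorical cluster (or condition) labels.
#' @param replicate Per-cell categorical replicate labels (or `NULL`).
#' @param depth Per-cell positive total counts.
#' @param depth_scale `"log"` (default) or `"raw"` (free-coefficient mode
#'   only).
#' @param depth_as `"covariate"` (free coefficient, default) or `"offset"`
#'   (fixed log-depth offset on the link scale).
#' @return A `DesignSpec`: list with model matrix `X`, `cluster_levels`,
#'   `cluster` (factor), coefficient names, and `offset` (per-cell link
#'   offset, zero unless `depth_as = "offset"`).
#' @export
build_design <- function(cluster, replicate = NULL, depth = NULL,
                         depth_scale = c("log", "raw"),
                         depth_as = c("covariate", "offset")) {
  depth_scale <- match.arg(depth_scale)
  depth_as <- match.arg(depth_as)
  cluster <- factor(cluster)
  n <- length(cluster)
  X <- vapply(levels(cluster), function(lv) as.numeric(cluster == lv),
              numeric(n))
  colnames(X) <- paste0("cluster_", levels(cluster))
  if (!is.null(replicate)) {
    replicate <- factor(replicate)
    if (nlevels(replicate) > 1) {
      R <- stats::model.matrix(~replicate)[, -1, drop = FALSE]
      colnames(R) <- paste0("replicate_", levels(replicate)[-1])
      X <- cbind(X, R)
    }
  }
  offset <- rep(0, n)
  if (!is.null(depth)) {
    if (any(depth <= 0)) stop("validation error: depth must be positive")
    if (depth_as == "offset") {
      offset <- log(depth)
    } else {
      dcol <- if (depth_scale == "log") log(depth) else depth
      X <- cbind(X, depth = dcol)
    }
  }
  if (qr(X)$rank < ncol(X))
    stop("validation error: design matrix is rank deficient")
  structure(list(X = X, cluster = cluster,
                 cluster_levels = levels(cluster),
                 coef_names = colnames(X), depth_scale = depth_scale,
                 offset = offset),
            class = "DesignSpec")
}

#' Gene-wise NB dispersion estimates
#'
#' Method-of-moments estimate from a Poisson fit of the design: with
#' `Var = mu + phi mu^2`, `phi_hat = sum((y - mu)^2 - mu) / sum(mu^2)`
#' with a degrees-of-freedom correction, clipped at zero, then shrunk
#' toward the median dispersion across testable genes with weight
#' `shrink_weight` and floored at 1e-8. Constant-zero genes receive the
#' floor and are flagged untestable.
#'
#' @param counts A `GeneExpressionMatrix` or genes x cells count matrix.
#' @param design A `DesignSpec`.
#' @param shrink_weight Weight of the common (median) dispersion
#'   (default 0.3).
#' @return Named numeric vector of dispersions with attribute `untestable`
#'   (logical vector).
#' @export
estimate_dispersion <- function(counts, design, shrink_weight = 0.3) {
  Y <- .count_matrix_of(counts)
  X <- design$X
  n <- ncol(Y); p <- ncol(X)
  if (n - p < 2)
    stop("validation error: fewer than 2 residual degrees of freedom")
  off <- if (is.null(design$offset)) rep(0, n) else design$offset
  raw <- apply(Y, 1, function(y) {
    if (all(y == 0)) return(NA_real_)
    fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson(),
                                           offset = off))
    mu <- fit$fitted.values
    max(0, sum((y - mu)^2 - mu) / sum(mu^2) * n / (n - p))
  })
  untestable <- is.na(raw)
  common <- stats::median(raw[!untestable])
  if (!is.finite(common)) common <- 0
  phi <- (1 - shrink_weight) * raw + shrink_weight * common
  phi[untestable] <- 0
  phi <- pmax(phi, 1e-8)
  names(phi) <- rownames(Y)
  attr(phi, "untestable") <- untestable
  phi
}

.count_matrix_of <- function(counts) {
  if (inherits(counts, "GeneExpressionMatrix")) as.matrix(counts$counts)
  else as.matrix(counts)
}

#' Fit per-gene negative-binomial GLMs
#'
#' For each gene, fits `log mu = X beta` by iteratively reweighted least
#' squares at fixed dispersion (convergence when the deviance change is
#' below 1e-8, at most 100 iterations). Genes that fail to converge are
#' flagged and reported with a warning.
#'
#' @param counts A `GeneExpressionMatrix` or genes x cells count matrix.
#' @param design A `DesignSpec`.
#' @param dispersions Per-gene dispersions from [estimate_dispersion()].
#' @return An `NbFit`: list with `coefficients` (genes x p), `loglik`,
#'   `converged`, `dispersions`, `design`, `counts`.
#' @export
fit_nb_glm <- function(counts, design, dispersions) {
  Y <- .count_matrix_of(counts)
  X <- design$X
  if (length(dispersions) != nrow(Y))
    stop("validation error: one dispersion per gene required")
  p <- ncol(X)
  beta <- matrix(NA_real_, nrow(Y), p,
                 dimnames = list(rownames(Y), colnames(X)))
  ll <- numeric(nrow(Y)); conv <- logical(nrow(Y))
  off <- if (is.null(design$offset)) rep(0, ncol(Y)) else design$offset
  for (g in seq_len(nrow(Y))) {
    f <- .nb_fit_one(X, Y[g, ], dispersions[g], off)
    beta[g, ] <- f$beta; ll[g] <- f$loglik; conv[g] <- f$converged
  }
  if (any(!conv))
    warning(sum(!conv), " gene(s) did not converge; coefficients reported")
  structure(list(coefficients = beta, loglik = ll, converged = conv,
                 dispersions = dispersions, design = design, counts = Y),
            class = "NbFit")
}

.nb_fit_one <- function(X, y, phi, offset = rep(0, length(y))) {
  fam <- if (phi < 1e-8) stats::poisson() else
    MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = fam, offset = offset,
    control = stats::glm.control(epsilon = 1e-8, maxit = 100)))
  mu <- pmax(fit$fitted.values, 1e-300)
  ll <- if (phi < 1e-8) sum(stats::dpois(y, mu, log = TRUE)) else
    sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
  list(beta = fit$coefficients, loglik = ll, converged = fit$converged)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control:
#' `p_adj(i) = min over j with rank >= rank(i) of (m / j) p_(j)`, capped at
#' 1. Applied over all genes tested in a contrast.
#'
#' @param p Numeric vector of raw p-values.
#' @return Adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Likelihood-ratio test of a contrast
#'
#' Tests `c' beta = 0` per gene by refitting under the null (the design
#' reparameterized onto the orthocomplement of the contrast) and comparing
#' log-likelihoods: `LRT = 2 (ll_full - ll_null)`, chi-squared with 1 df.
#' The log2 fold change is the contrast value divided by log(2), and
#' p-values are Benjamini-Hochberg adjusted over all tested genes.
#'
#' @param fit An `NbFit`.
#' @param contrast Numeric vector over the design coefficients.
#' @return A `MarkerTable` data.frame: `gene_id`, `log2fc`, `p_raw`,
#'   `p_adj`, `mean_target`, `mean_other`, ordered as the input genes.
#' @export
test_contrast <- function(fit, contrast) {
  X <- fit$design$X
  p <- ncol(X)
  contrast <- as.numeric(contrast)
  if (length(contrast) != p)
    stop("validation error: contrast length must match the ", p,
         " design coefficients (", paste(colnames(X), collapse = ", "), ")")
  if (all(contrast == 0)) stop("validation error: zero contrast")
  Q <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)
  N <- Q[, -1, drop = FALSE]          # basis of the null space of c'
  X0 <- X %*% N
  Y <- fit$counts
  off <- if (is.null(fit$design$offset)) rep(0, ncol(Y)) else
    fit$design$offset
  lrt <- numeric(nrow(Y))
  for (g in seq_len(nrow(Y))) {
    f0 <- .nb_fit_one(X0, Y[g, ], fit$dispersions[g], off)
    lrt[g] <- max(0, 2 * (fit$loglik[g] - f0$loglik))
  }
  est <- as.numeric(fit$coefficients %*% contrast)
  p_raw <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  p_raw[is.na(est)] <- NA_real_
  grp <- .contrast_groups(fit$design, contrast)
  out <- data.frame(
    gene_id = rownames(Y),
    log2fc = est / log(2),
    p_raw = p_raw,
    p_adj = adjust_bh(p_raw),
    mean_target = if (length(grp$pos)) rowMeans(Y[, grp$pos, drop = FALSE])
      else NA_real_,
    mean_other = if (length(grp$neg)) rowMeans(Y[, grp$neg, drop = FALSE])
      else NA_real_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("MarkerTable", "data.frame")
  out
}

.contrast_groups <- function(design, contrast) {
  cl_idx <- seq_along(design$cluster_levels)
  w <- contrast[cl_idx]
  pos_lv <- design$cluster_levels[w > 0]
  neg_lv <- design$cluster_levels[w < 0]
  list(pos = which(design$cluster %in% pos_lv),
       neg = which(design$cluster %in% neg_lv))
}

#' Contrast vector for one cluster against the rest
#'
#' `+1` on the target cluster coefficient and `-1/(m-1)` on each of the
#' other m-1 cluster coefficients; replicate and depth coefficients are
#' untouched (they cancel in the additive model). With two clusters this
#' reduces exactly to the pairwise contrast.
#'
#' @param design A `DesignSpec`.
#' @param target Target cluster level.
#' @return Numeric contrast vector over the design coefficients.
#' @export
contrast_vs_rest <- function(design, target) {
  lv <- design$cluster_levels
  target <- as.character(target)
  if (!target %in% lv) stop("unknown cluster level: ", target)
  v <- numeric(ncol(design$X))
  names(v) <- colnames(design$X)
  v[paste0("cluster_", target)] <- 1
  others <- setdiff(lv, target)
  v[paste0("cluster_", others)] <- -1 / length(others)
  v
}

#' Marker genes of one cluster
#'
#' Convenience wrapper: tests the target cluster against the average of
#' all other clusters with the NB likelihood-ratio machinery, refusing
#' clusters with fewer than 3 cells.
#'
#' @param counts A `GeneExpressionMatrix` or genes x cells count matrix.
#' @param design A `DesignSpec` built with cluster labels.
#' @param target Target cluster level.
#' @param fit Optional pre-computed `NbFit` (shared across targets).
#' @param dispersions Optional pre-computed dispersions.
#' @return A `MarkerTable` (see [test_contrast()]).
#' @export
derive_markers <- function(counts, design, target, fit = NULL,
                           dispersions = NULL) {
  if (length(design$cluster_levels) < 2)
    stop("validation error: need >= 2 clusters")
  sizes <- table(design$cluster)
  if (sizes[[as.character(target)]] < 3)
    stop("cluster ", target, " has fewer than 3 cells; refusing to test")
  if (is.null(fit)) {
    if (is.null(dispersions))
      dispersions <- estimate_dispersion(counts, design)
    fit <- fit_nb_glm(counts, design, dispersions)
  }
  test_contrast(fit, contrast_vs_rest(design, target))
}

#' Compare two differential-expression gene sets
#'
#' Thresholds each marker table at `p_adj < p_cut` and |fold change| >
#' `fc_cut` and reports the Venn partition of the two significant sets.
#'
#' @param tableA,tableB `MarkerTable`s over the same gene universe.
#' @param p_cut Adjusted p-value cut (e.g. 0.05).
#' @param fc_cut Fold-change cut on the natural scale (e.g. 1.5 or 2);
#'   applied to |log2fc| > log2(fc_cut).
#' @return List with `counts` (named: `A`, `B`, `both`, `A_only`,
#'   `B_only`) and `genes` (the corresponding id vectors).
#' @export
compare_deg_sets <- function(tableA, tableB, p_cut = 0.05, fc_cut = 1.5) {
  if (!setequal(tableA$gene_id, tableB$gene_id))
    stop("validation error: marker tables have different gene universes")
  sig <- function(tb) tb$gene_id[!is.na(tb$p_adj) & tb$p_adj < p_cut &
                                   abs(tb$log2fc) > log2(fc_cut)]
  A <- sig(tableA); B <- sig(tableB)
  list(counts = c(A = length(A), B = length(B),
                  both = length(intersect(A, B)),
                  A_only = length(setdiff(A, B)),
                  B_only = length(setdiff(B, A))),
       genes = list(A = A, B = B, both = intersect(A, B),
                    A_only = setdiff(A, B), B_only = setdiff(B, A)))
}
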