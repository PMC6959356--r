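#' Specification of the Gaussian-mixture cell-state simulation
#'
#' Control cells draw their scalar cell state from N(mean1, sd^2); each case
#' cell independently draws from an outlier component N(mean2, sd^2) with
#' probability `outlier_frac` and from the control component otherwise.
#' `mean1 = 5` and `sd = 1` are the reference conditions; the separation
#' `mean2 - mean1` is therefore expressed in SD units.
#'
#' @param n_per_group cells per group (default 1000).
#' @param mean1 control component mean (default 5).
#' @param mean2 outlier component mean (default 7, i.e. 2 SD separation).
#' @param sd common component SD (default 1).
#' @param outlier_frac probability in [0, 1) that a case cell comes from
#'   the outlier component.
#' @param fixed_outlier_count if `TRUE`, exactly
#'   `round(outlier_frac * n_per_group)` case cells are outliers instead of
#'   a Bernoulli draw per cell.
#' @param rng_seed optional integer seed.
#' @return An object of class `gaussian_mixture_spec`.
#' @export
gaussian_mixture_spec <- function(n_per_group = 1000, mean1 = 5, mean2 = 7,
                                  sd = 1, outlier_frac = 0.1,
                                  fixed_outlier_count = FALSE,
                                  rng_seed = NULL) {
  stopifnot(n_per_group >= 2, sd > 0, outlier_frac >= 0, outlier_frac < 1)
  structure(
    list(n_per_group = as.integer(n_per_group), mean1 = mean1, mean2 = mean2,
         sd = sd, outlier_frac = outlier_frac,
         fixed_outlier_count = isTRUE(fixed_outlier_count),
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "gaussian_mixture_spec"
  )
}

#' Simulate cell-state scores from the two-group Gaussian mixture
#'
#' @param spec a [gaussian_mixture_spec].
#' @return List with `scores` (named numeric, one entry per cell),
#'   `partition` (a [cell_partition] with `set_label = "case"`) and
#'   `n_outliers` (the realized number of outlier-component case cells).
#' @export
simulate_gaussian <- function(spec) {
  stopifnot(inherits(spec, "gaussian_mixture_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  n <- spec$n_per_group
  ids <- c(sprintf("case_%04d", seq_len(n)), sprintf("ctrl_%04d", seq_len(n)))
  labels <- stats::setNames(rep(c("case", "control"), each = n), ids)
  is_outlier <- if (spec$fixed_outlier_count) {
    k <- round(spec$outlier_frac * n)
    sample(rep(c(TRUE, FALSE), c(k, n - k)))
  } else {
    stats::runif(n) < spec$outlier_frac
  }
  mu_case <- ifelse(is_outlier, spec$mean2, spec$mean1)
  scores <- stats::setNames(
    c(stats::rnorm(n, mu_case, spec$sd), stats::rnorm(n, spec$mean1, spec$sd)),
    ids)
  list(scores = scores,
       partition = cell_partition(labels, "case"),
       n_outliers = sum(is_outlier))
}

#' Specification of the count-matrix simulation
#'
#' A negative-binomial gene model driven by a continuous latent cell state:
#' each cell's latent state z is a draw from the Gaussian mixture of
#' `mixture`; gene g has log mean
#' `baseline_log_mean[g] + de_loading[g] * (z - mean1)`, with loading 0 for
#' non-differential genes. Baseline log means default to draws from
#' N(1, 0.5) (mean count around 3, typical of shallow droplet-based
#' scRNA-seq); counts are library-size normalized to the median depth and
#' log1p-transformed.
#'
#' @param n_genes number of genes (default 500).
#' @param frac_de_genes fraction of genes responding to the latent state
#'   (default 0.1).
#' @param de_loading effect of the latent state on each DE gene's log mean
#'   (scalar, recycled, or one value per DE gene; default 0.5).
#' @param dispersion negative-binomial size parameter (default 10).
#' @param baseline_log_mean optional vector of per-gene baseline log means;
#'   drawn from N(1, 0.5) when `NULL`.
#' @param mixture a [gaussian_mixture_spec] for the latent state and the
#'   rank-matching reference (its `n_per_group` sets the cell count).
#' @param rng_seed optional integer seed.
#' @return An object of class `count_sim_spec`.
#' @export
count_sim_spec <- function(n_genes = 500, frac_de_genes = 0.1,
                           de_loading = 0.5, dispersion = 10,
                           baseline_log_mean = NULL,
                           mixture = gaussian_mixture_spec(n_per_group = 300),
                           rng_seed = NULL) {
  stopifnot(n_genes >= 2, frac_de_genes > 0, frac_de_genes <= 1,
            dispersion > 0, inherits(mixture, "gaussian_mixture_spec"))
  structure(
    list(n_genes = as.integer(n_genes), frac_de_genes = frac_de_genes,
         de_loading = de_loading, dispersion = dispersion,
         baseline_log_mean = baseline_log_mean, mixture = mixture,
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed)),
    class = "count_sim_spec"
  )
}

#' Simulate a count matrix driven by a continuous latent cell state
#'
#' Draws latent states and case/control labels from the Gaussian mixture in
#' `spec$mixture` (these draws double as the rank-matching reference),
#' samples negative-binomial counts whose DE-gene log means follow the
#' latent state, normalizes to median library size with a log1p transform,
#' scores every cell on the DE-gene signature after per-cell z-scoring, and
#' assigns case/control labels by rank-matching that trajectory score to the
#' reference simulation. A cell whose library is all zeros is resampled
#' once; a second failure is an error.
#'
#' @param spec a [count_sim_spec].
#' @return List with `expr` (cells x genes normalized log matrix),
#'   `signature` (the DE genes as a [gene_signature]), `partition` (labels
#'   from rank matching), `trajectory` (the per-cell DE-gene score used for
#'   matching), `latent` (the true latent states) and `reference` (the
#'   Gaussian-mixture reference simulation).
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "count_sim_spec"))
  if (!is.null(spec$rng_seed)) set.seed(spec$rng_seed)
  ref <- simulate_gaussian(spec$mixture)
  z <- ref$scores
  n_cells <- length(z)
  g_ids <- sprintf("gene_%04d", seq_len(spec$n_genes))
  base <- if (is.null(spec$baseline_log_mean))
    stats::rnorm(spec$n_genes, mean = 1, sd = 0.5)
  else rep_len(spec$baseline_log_mean, spec$n_genes)
  n_de <- max(1L, round(spec$frac_de_genes * spec$n_genes))
  loading <- c(rep_len(spec$de_loading, n_de), rep(0, spec$n_genes - n_de))
  log_mu <- outer(z - spec$mixture$mean1, loading) +
    matrix(base, n_cells, spec$n_genes, byrow = TRUE)
  draw <- function() matrix(
    stats::rnbinom(n_cells * spec$n_genes, size = spec$dispersion,
                   mu = exp(log_mu)),
    n_cells, spec$n_genes, dimnames = list(names(z), g_ids))
  counts <- draw()
  lib <- rowSums(counts)
  if (any(lib == 0)) {
    counts2 <- draw()
    counts[lib == 0, ] <- counts2[lib == 0, ]
    lib <- rowSums(counts)
    if (any(lib == 0))
      stop("cell(s) with all-zero counts after resampling: ",
           paste(utils::head(names(z)[lib == 0], 5L), collapse = ", "),
           call. = FALSE)
  }
  expr <- log1p(counts / lib * stats::median(lib))
  sig <- gene_signature("de_genes", g_ids[seq_len(n_de)])
  trajectory <- score_signatures(expr, sig)[, 1L]
  part <- rank_match_labels(trajectory, ref$scores, ref$partition)
  list(expr = expr, signature = sig, partition = part,
       trajectory = trajectory, latent = z, reference = ref)
}

#' Transfer labels between simulations by score rank
#'
#' The i-th ranked cell of the target score vector receives the condition
#' label of the i-th ranked cell of the reference simulation, so the
#' reference's label-vs-rank structure is imposed on the target exactly.
#'
#' @param target_scores named numeric vector to be labeled.
#' @param reference_scores named numeric vector of the reference simulation.
#' @param reference_partition the reference's [cell_partition].
#' @return A [cell_partition] over the target cells with the reference's
#'   set label and group sizes.
#' @export
rank_match_labels <- function(target_scores, reference_scores,
                              reference_partition) {
  stopifnot(inherits(reference_partition, "cell_partition"))
  if (length(target_scores) != length(reference_scores))
    stop("target and reference simulations must have the same cell count",
         call. = FALSE)
  r_target <- rank_cells(target_scores, "high")
  r_ref <- rank_cells(reference_scores, "high")
  labels <- stats::setNames(reference_partition$labels[r_ref], r_target)
  cell_partition(labels[names(target_scores)],
                 reference_partition$set_label)
}
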