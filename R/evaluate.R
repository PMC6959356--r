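#' Derive a reproducible child seed from a master seed
#'
#' Deterministic integer mixing of a master seed with index coordinates
#' (grid cell, replicate, ...), kept below 2^31 so the result is always a
#' valid R seed. Distinct coordinate tuples give distinct streams, so grid
#' cells are independently reproducible.
#'
#' @param master integer master seed.
#' @param ... integer coordinates.
#' @return An integer seed.
#' @export
derive_seed <- function(master, ...) {
  s <- as.numeric(master) %% 2147483647
  for (v in c(...)) s <- (s * 69069 + as.numeric(v) + 1) %% 2147483647
  as.integer(s)
}

# one simulated dataset -> permutation p-value, per scheme
run_replicate <- function(scheme, sep, frac, params, n_per_group,
                          counts_template, seed) {
  if (scheme == "gaussian") {
    sim <- simulate_gaussian(gaussian_mixture_spec(
      n_per_group = n_per_group, mean2 = 5 + sep, outlier_frac = frac,
      rng_seed = seed))
    scores <- sim$scores
    part <- sim$partition
  } else {
    mix <- gaussian_mixture_spec(n_per_group = n_per_group, mean2 = 5 + sep,
                                 outlier_frac = frac)
    cs <- count_sim_spec(
      n_genes = counts_template$n_genes,
      frac_de_genes = counts_template$frac_de_genes,
      de_loading = if (sep == 0 && counts_template$null_by_loading) 0
                   else counts_template$de_loading,
      dispersion = counts_template$dispersion,
      mixture = mix, rng_seed = seed)
    sim <- simulate_counts(cs)
    scores <- sim$trajectory
    part <- sim$partition
  }
  p <- params
  p$rng_seed <- derive_seed(seed, 7L)
  res <- permutation_pvalue(scores, part, p)
  list(p_value = res$p_value,
       n_outliers = if (scheme == "gaussian") sim$n_outliers
                    else sim$reference$n_outliers)
}

#' Null calibration of CSEA p-values
#'
#' Runs the full pipeline on repeated null simulations (outlier component
#' mean equal to the control mean for the Gaussian scheme; latent state
#' decoupled from expression via zero DE loadings for the count scheme) and
#' compares the permutation p-value distribution against uniform. The
#' uniformity allowance combines the permutation-grid discreteness bound
#' `1 / n_permutations` with the one-sample KS sampling term
#' `1.36 / sqrt(replicates)`.
#'
#' @param scheme `"gaussian"` or `"counts"`.
#' @param replicates number of null datasets (at least 50; default 200).
#' @param params a [csea_params].
#' @param n_per_group cells per group in each simulated dataset.
#' @param counts_spec template [count_sim_spec] for the count scheme
#'   (its mixture's `n_per_group` is overridden by `n_per_group`).
#' @param seed master seed.
#' @return List with the p-values, the KS distance from uniform, the
#'   allowance `bound`, and logical `uniform`.
#' @export
null_calibration <- function(scheme = c("gaussian", "counts"),
                             replicates = 200, params = csea_params(),
                             n_per_group = if (scheme == "gaussian") 1000 else 300,
                             counts_spec = count_sim_spec(), seed = 1) {
  scheme <- match.arg(scheme)
  stopifnot(replicates >= 50)
  tmpl <- list(n_genes = counts_spec$n_genes,
               frac_de_genes = counts_spec$frac_de_genes,
               de_loading = counts_spec$de_loading,
               dispersion = counts_spec$dispersion,
               null_by_loading = TRUE)
  p_values <- vapply(seq_len(replicates), function(r) {
    run_replicate(scheme, sep = 0, frac = 0.1, params = params,
                  n_per_group = n_per_group, counts_template = tmpl,
                  seed = derive_seed(seed, 991L, r))$p_value
  }, numeric(1))
  ks <- max(abs(stats::ecdf(p_values)(seq(0, 1, by = 0.001)) -
                  seq(0, 1, by = 0.001)))
  bound <- 1 / params$n_permutations + 1.36 / sqrt(replicates)
  list(p_values = p_values, ks_distance = ks, bound = bound,
       uniform = ks <= bound)
}

#' Power grid over mean separation and outlier fraction
#'
#' For every combination of separation (outlier-component mean shift in SD
#' units) and outlier fraction, simulates `replicates` seeded datasets, runs
#' each through scoring, ranking, the enrichment score and the permutation
#' test, and records rejection at level `alpha` (raw permutation p < alpha;
#' the validation tests one signature at a time, so no multiplicity
#' correction applies). Power is the rejection rate per grid cell.
#'
#' @param separations numeric vector of mean separations in SD units.
#' @param fractions numeric vector of outlier fractions in [0, 1), by
#'   default the outlier share of the total population (both groups
#'   pooled), the scale on which detection limits are usually quoted; with
#'   equal group sizes a total share f corresponds to a per-case-cell
#'   outlier probability of 2f. Set `fraction_of = "case"` to pass the
#'   case-group proportion directly.
#' @param fraction_of `"total"` (default) or `"case"`: the denominator of
#'   `fractions`.
#' @param replicates simulated datasets per grid cell (default 20).
#' @param scheme `"gaussian"` (scores simulated directly) or `"counts"`
#'   (negative-binomial expression scored on the DE-gene signature).
#' @param n_per_group cells per group.
#' @param alpha rejection level (default 0.05).
#' @param params a [csea_params].
#' @param counts_spec template [count_sim_spec] for the count scheme.
#' @param seed master seed; replicate (i, j, r) uses a seed derived from it
#'   so the table is exactly reproducible.
#' @return An object of class `csea_power_grid`: rejection and realized
#'   outlier-count arrays (separation x fraction x replicate), the power
#'   matrix, and the grid metadata.
#' @export
power_grid <- function(separations, fractions, replicates = 20,
                       scheme = c("gaussian", "counts"),
                       n_per_group = if (scheme == "gaussian") 1000 else 300,
                       alpha = 0.05, params = csea_params(),
                       counts_spec = count_sim_spec(),
                       fraction_of = c("total", "case"), seed = 1) {
  scheme <- match.arg(scheme)
  fraction_of <- match.arg(fraction_of)
  stopifnot(length(separations) >= 1, length(fractions) >= 1,
            replicates >= 1, alpha > 0, alpha < 1,
            all(fractions >= 0), all(fractions < 1))
  case_fracs <- if (fraction_of == "total") 2 * fractions else fractions
  if (any(case_fracs >= 1))
    stop("an outlier share of ", max(fractions), " of the total population ",
         "exceeds the case group", call. = FALSE)
  tmpl <- list(n_genes = counts_spec$n_genes,
               frac_de_genes = counts_spec$frac_de_genes,
               de_loading = counts_spec$de_loading,
               dispersion = counts_spec$dispersion,
               null_by_loading = FALSE)
  dims <- c(length(separations), length(fractions), replicates)
  reject <- array(NA, dims)
  n_out <- array(NA_integer_, dims)
  for (i in seq_along(separations)) {
    for (j in seq_along(fractions)) {
      for (r in seq_len(replicates)) {
        res <- run_replicate(scheme, separations[i], case_fracs[j], params,
                             n_per_group, tmpl,
                             seed = derive_seed(seed, i, j, r))
        reject[i, j, r] <- res$p_value < alpha
        n_out[i, j, r] <- res$n_outliers
      }
    }
  }
  power <- apply(reject, c(1, 2), mean)
  dimnames(power) <- list(separation = as.character(separations),
                          fraction = as.character(fractions))
  structure(
    list(rejections = reject, n_outliers = n_out, power = power,
         separations = separations, fractions = fractions,
         replicates = replicates, alpha = alpha, scheme = scheme,
         n_per_group = n_per_group, fraction_of = fraction_of, seed = seed),
    class = "csea_power_grid"
  )
}

#' @export
print.csea_power_grid <- function(x, ...) {
  cat(sprintf("csea_power_grid (%s scheme, %d x %d cells/group, %d replicates)\n",
              x$scheme, x$n_per_group, 2L, x$replicates))
  print(round(x$power, 2))
  invisible(x)
}

#' Detection threshold along one grid axis
#'
#' The detection threshold is the smallest scanned value at which the test
#' rejects in a majority (> 50 percent) of replicates, with detection also
#' holding at every larger scanned value. Returns `Inf` when majority
#' detection is never stably reached; if earlier isolated detections exist
#' below the stable region, the threshold of the stable region is returned
#' with a warning about non-monotone power.
#'
#' @param grid a `csea_power_grid` from [power_grid]. The axis not scanned
#'   must have length 1 (subset the grid request accordingly).
#' @param axis `"fraction"` or `"separation"`.
#' @return The threshold value on the scanned axis (same units as the grid:
#'   a fraction in [0,1) or a separation in SD units), or `Inf`.
#' @export
detection_threshold <- function(grid, axis = c("fraction", "separation")) {
  axis <- match.arg(axis)
  stopifnot(inherits(grid, "csea_power_grid"))
  if (axis == "fraction") {
    if (length(grid$separations) != 1L)
      stop("scanning fractions requires a single separation in the grid",
           call. = FALSE)
    values <- grid$fractions
    power <- grid$power[1L, ]
  } else {
    if (length(grid$fractions) != 1L)
      stop("scanning separations requires a single fraction in the grid",
           call. = FALSE)
    values <- grid$separations
    power <- grid$power[, 1L]
  }
  det <- power > 0.5
  n <- length(det)
  if (!det[n]) {
    if (any(det))
      warning("majority detection reached at interior grid values only; ",
              "no stable crossing", call. = FALSE)
    return(Inf)
  }
  k <- n
  while (k > 1L && det[k - 1L]) k <- k - 1L
  if (k > 1L && any(det[seq_len(k - 1L)]))
    warning("non-monotone empirical power below the stable detection region",
            call. = FALSE)
  values[k]
}
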