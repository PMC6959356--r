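test_that("gaussian-mixture simulation is seed-reproducible and label-correct", {
  spec <- gaussian_mixture_spec(n_per_group = 50, mean2 = 7,
                                outlier_frac = 0.2, rng_seed = 101)
  a <- simulate_gaussian(spec)
  b <- simulate_gaussian(spec)
  expect_identical(a$scores, b$scores)
  expect_identical(a$partition$labels, b$partition$labels)
  expect_identical(a$partition$n, 100L)
  expect_identical(a$partition$n_set, 50L)
  expect_identical(a$partition$set_label, "case")
})

test_that("control scores track N(5, 1) and marginals pass KS at n = 10^4", {
  sims <- lapply(1:20, function(s) simulate_gaussian(
    gaussian_mixture_spec(n_per_group = 400, outlier_frac = 0.1,
                          rng_seed = 200 + s)))
  ctrl_means <- vapply(sims, function(x)
    mean(x$scores[x$partition$labels == "control"]), numeric(1))
  expect_true(all(abs(ctrl_means - 5) < 3 / sqrt(400)))

  big <- simulate_gaussian(gaussian_mixture_spec(n_per_group = 10000,
                                                 mean2 = 8, outlier_frac = 0.3,
                                                 rng_seed = 77))
  ctrl <- big$scores[big$partition$labels == "control"]
  expect_gt(stats::ks.test(ctrl, "pnorm", 5, 1)$p.value, 0.001)
  case <- big$scores[big$partition$labels == "case"]
  pmix <- function(q) 0.7 * pnorm(q, 5, 1) + 0.3 * pnorm(q, 8, 1)
  expect_gt(stats::ks.test(case, pmix)$p.value, 0.001)
})

test_that("outlier_frac 0 and mean2 = mean1 both collapse to the exact null", {
  a <- simulate_gaussian(gaussian_mixture_spec(n_per_group = 5000,
                                               mean2 = 40, outlier_frac = 0,
                                               rng_seed = 5))
  case <- a$scores[a$partition$labels == "case"]
  expect_gt(stats::ks.test(case, "pnorm", 5, 1)$p.value, 0.001)
  expect_identical(a$n_outliers, 0L)

  b <- simulate_gaussian(gaussian_mixture_spec(n_per_group = 5000, mean2 = 5,
                                               outlier_frac = 0.3,
                                               rng_seed = 6))
  expect_gt(stats::ks.test(b$scores[b$partition$labels == "case"],
                           "pnorm", 5, 1)$p.value, 0.001)
})

test_that("fixed-outlier-count mode realizes exactly the requested count", {
  a <- simulate_gaussian(gaussian_mixture_spec(n_per_group = 200, mean2 = 9,
                                               outlier_frac = 0.1,
                                               fixed_outlier_count = TRUE,
                                               rng_seed = 8))
  expect_identical(a$n_outliers, 20L)
})

test_that("count simulation recovers the latent state and is reproducible", {
  spec <- count_sim_spec(mixture = gaussian_mixture_spec(
    n_per_group = 300, mean2 = 7, outlier_frac = 0.1), rng_seed = 15)
  a <- simulate_counts(spec)
  b <- simulate_counts(spec)
  expect_identical(a$expr, b$expr)
  expect_identical(a$partition$labels, b$partition$labels)

  expect_identical(dim(a$expr), c(600L, 500L))
  expect_length(a$signature$positive, 50L)

  # DE-gene trajectory score tracks the true latent state
  expect_gt(cor(a$latent, a$trajectory, method = "spearman"), 0.9)
})

test_that("baseline depth shifts cancel after normalization and z-scoring", {
  mix <- gaussian_mixture_spec(n_per_group = 60, mean2 = 7,
                               outlier_frac = 0.1)
  base <- rnorm(200, 1, 0.5)
  a <- simulate_counts(count_sim_spec(n_genes = 200, baseline_log_mean = base,
                                      dispersion = 1e6, mixture = mix,
                                      rng_seed = 31))
  b <- simulate_counts(count_sim_spec(n_genes = 200,
                                      baseline_log_mean = base + log(2),
                                      dispersion = 1e6, mixture = mix,
                                      rng_seed = 31))
  # doubling every gene's mean rescales depth only: after library
  # normalization and per-cell z-scoring the trajectory scores agree up to
  # resampling noise
  expect_gt(cor(a$trajectory, b$trajectory), 0.9)
  # and the reference (latent states and their labels) is untouched
  expect_identical(a$latent, b$latent)
  expect_identical(a$reference$partition$labels, b$reference$partition$labels)
})

test_that("rank matching transfers labels by rank and preserves group sizes", {
  ids_ref <- sprintf("r%02d", 1:10)
  ids_new <- sprintf("n%02d", 1:10)
  ref_scores <- stats::setNames(10:1, ids_ref)
  ref_part <- cell_partition(
    stats::setNames(rep(c("case", "control"), each = 5), ids_ref), "case")
  target <- stats::setNames(rnorm(10), ids_new)

  part <- rank_match_labels(target, ref_scores, ref_part)
  # reference cases occupy the top half of ranks -> top target cells are cases
  top <- rank_cells(target)[1:5]
  expect_true(all(part$labels[top] == "case"))
  expect_identical(part$n_set, ref_part$n_set)

  # idempotent under repetition
  part2 <- rank_match_labels(target, ref_scores, ref_part)
  expect_identical(part$labels, part2$labels)

  # counting preserved on random instances
  set.seed(61)
  for (i in 1:10) {
    n <- sample(10:40, 1)
    rs <- stats::setNames(rnorm(n), sprintf("r%03d", 1:n))
    rp <- random_partition(names(rs), sample(2:(n - 2), 1))
    tg <- stats::setNames(rnorm(n), sprintf("t%03d", 1:n))
    expect_identical(rank_match_labels(tg, rs, rp)$n_set, rp$n_set)
  }

  expect_error(rank_match_labels(target[1:5], ref_scores, ref_part),
               "same cell count")
})
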