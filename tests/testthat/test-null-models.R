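test_that("permutation p-value conventions: raw fraction, zero, and add-one bound", {
  set.seed(9)
  ids <- sprintf("c%03d", 1:60)
  # set members hold the top scores: observed ES = 1 beats every shuffle
  s <- stats::setNames(sort(rnorm(60), decreasing = TRUE), ids)
  part <- cell_partition(
    stats::setNames(rep(c("case", "control"), c(10, 50)), ids), "case")
  res <- permutation_pvalue(s, part, csea_params(n_permutations = 50,
                                                 rng_seed = 1))
  expect_equal(res$es, 1)
  expect_equal(res$p_value, 0)

  # pseudo-count keeps p away from zero
  res2 <- permutation_pvalue(s, part,
                             csea_params(n_permutations = 50, rng_seed = 1,
                                         pseudo_count = TRUE))
  expect_equal(res2$p_value, 1 / 51)
  expect_gte(res2$p_value, 1 / 51)

  # identical seeds reproduce the permutation null exactly
  res3 <- permutation_pvalue(s, part, csea_params(n_permutations = 50,
                                                  rng_seed = 1))
  expect_identical(res$perm_es, res3$perm_es)
})

test_that("permutation p-values are uniform under an exchangeable null", {
  set.seed(17)
  n_rep <- 200
  pvals <- vapply(seq_len(n_rep), function(r) {
    ids <- sprintf("c%03d", 1:100)
    s <- stats::setNames(rnorm(100, 5), ids)   # scores independent of labels
    part <- cell_partition(
      stats::setNames(sample(rep(c("case", "control"), 50)), ids), "case")
    permutation_pvalue(s, part, csea_params(n_permutations = 100))$p_value
  }, numeric(1))
  grid <- seq(0, 1, by = 0.001)
  ks <- max(abs(stats::ecdf(pvals)(grid) - grid))
  expect_lte(ks, 1 / 100 + 1.36 / sqrt(n_rep))
  # and the rejection rate at 0.05 is near nominal
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.06)
})

test_that("matched genesets preserve size and structure and respect the pool", {
  set.seed(5)
  n_genes <- 60
  m <- matrix(rnorm(10 * n_genes, mean = rep(seq(0, 6, length.out = n_genes),
                                             each = 10), sd = 0.1),
              10, n_genes,
              dimnames = list(sprintf("c%02d", 1:10),
                              sprintf("g%02d", seq_len(n_genes))))
  sig <- gene_signature("s", c("g05", "g20", "g40"), c("g10", "g50"))
  ctrl <- matched_geneset(sig, m, pool_size = 5, rng_seed = 1)

  expect_length(ctrl$positive, 3)
  expect_length(ctrl$negative, 2)
  expect_length(intersect(c(ctrl$positive, ctrl$negative),
                          c(sig$positive, sig$negative)), 0)
  expect_false(anyDuplicated(c(ctrl$positive, ctrl$negative)) > 0)

  # every pick lies in the gene's nearest-mean pool, recomputed by full sort
  means <- colMeans(m)
  picks <- c(ctrl$positive, ctrl$negative)
  origs <- c(sig$positive, sig$negative)
  universe <- setdiff(colnames(m), origs)
  for (k in seq_along(origs)) {
    d <- sort(abs(means[universe] - means[origs[k]]))
    # without-replacement sampling may push a pick past rank pool_size by at
    # most the number of genes already taken
    expect_lte(abs(means[picks[k]] - means[origs[k]]),
               unname(d[5 + k - 1]) + 1e-12)
  }

  # deterministic when exactly one candidate matches and pool_size = 1
  m2 <- matrix(rep(c(1, 2, 3, 1.01, 2.1, 3.2), each = 4), 4, 6,
               dimnames = list(sprintf("c%d", 1:4),
                               c("a", "b", "c", "am", "bm", "cm")))
  ctrl2 <- matched_geneset(gene_signature("t", c("a", "b", "c")), m2,
                           pool_size = 1, rng_seed = 3)
  expect_identical(sort(ctrl2$positive), c("am", "bm", "cm"))

  # pool exhaustion is a clear error
  expect_error(
    matched_geneset(gene_signature("t", c("a", "b", "c")), m2[, 1:4],
                    pool_size = 1, rng_seed = 3),
    "pool exhausted")
})

test_that("geneset null p-value follows the control-ES exceedance convention", {
  set.seed(11)
  m <- toy_expr(30, 40, seed = 12)
  ids <- rownames(m)
  part <- random_partition(ids, 15)
  sig <- gene_signature("s", c("g01", "g02", "g03"))
  out <- geneset_null_pvalue(sig, m, part, csea_params(rng_seed = 2),
                             n_sets = 25, pool_size = 10)
  expect_length(out$control_es, 25)
  expect_equal(out$p_value, mean(out$control_es >= out$true$es))
  expect_gte(out$p_value, 0); expect_lte(out$p_value, 1)

  # n_sets = 1 reduces to a single comparison in {0, 1}
  one <- geneset_null_pvalue(sig, m, part, csea_params(rng_seed = 2),
                             n_sets = 1, pool_size = 10)
  expect_true(one$p_value %in% c(0, 1))
})

test_that("three-part screening applies BH per family and strict bounds", {
  # textbook BH check on the true-p family
  res <- data.frame(signature = letters[1:4],
                    p_true = c(0.01, 0.02, 0.04, 0.5),
                    p_control = rep(0.8, 4),
                    leading_edge_size = rep(100L, 4))
  out <- screen_signatures(res)
  expect_equal(out$corrected_p_true, c(0.04, 0.04, 16 / 300, 0.5),
               tolerance = 1e-12)
  expect_identical(out$retained, c(TRUE, TRUE, FALSE, FALSE))

  # boundary: leading edge of exactly 1000 is rejected (strict <)
  res2 <- data.frame(signature = c("keep", "edge"),
                     p_true = c(0.01, 0.01),
                     p_control = c(0.5, 0.5),
                     leading_edge_size = c(999L, 1000L))
  out2 <- screen_signatures(res2)
  expect_identical(out2$retained, c(TRUE, FALSE))

  # a significant control p disqualifies the signature
  res3 <- data.frame(signature = "x", p_true = 0.001, p_control = 0.01,
                     leading_edge_size = 10L)
  expect_false(screen_signatures(res3)$retained)

  # monotone: lowering a true p never removes a retained signature
  res4 <- res
  res4$p_true[2] <- 0.001
  out4 <- screen_signatures(res4)
  expect_true(all(out4$retained[out$retained]))
})

test_that("tight matching yields less variable control ES than random sets", {
  set.seed(23)
  # genes with strongly distinct means so matching matters
  n_genes <- 80; n_cells <- 40
  mu <- seq(0, 8, length.out = n_genes)
  m <- matrix(rnorm(n_cells * n_genes, rep(mu, each = n_cells), 0.3),
              n_cells, n_genes,
              dimnames = list(sprintf("c%02d", seq_len(n_cells)),
                              sprintf("g%02d", seq_len(n_genes))))
  part <- random_partition(rownames(m), 20)
  sig <- gene_signature("s", c("g70", "g75", "g78"))  # high-mean genes
  tab <- match_sensitivity(sig, m, part, pool_sizes = c(1, NA),
                           n_draws = 100, params = csea_params(rng_seed = 4))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$pool, c("1", "unmatched"))
  expect_lt(tab$sd_es[tab$pool == "1"], tab$sd_es[tab$pool == "unmatched"])
})
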