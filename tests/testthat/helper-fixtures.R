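# Shared fixtures and independent oracles, built in code at test time.

# small dense cells x genes matrix with distinct per-cell profiles
toy_expr <- function(n_cells = 4, n_genes = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(n_cells * n_genes, mean = 2), n_cells, n_genes,
              dimnames = list(sprintf("cell%02d", seq_len(n_cells)),
                              sprintf("g%02d", seq_len(n_genes))))
  m
}

# brute-force enrichment score: explicit loop over every prefix, no cumsum
brute_force_es <- function(scores, labels, set_label, p = 1,
                           direction = "high") {
  ord <- order(if (direction == "high") -scores else scores, names(scores),
               method = "radix")
  r <- scores[ord]
  hit <- labels[names(r)] == set_label
  n_r <- sum(abs(r[hit])^p)
  n_miss <- sum(!hit)
  best <- -Inf; best_i <- NA_integer_
  for (i in seq_along(r)) {
    idx <- seq_len(i)
    d <- sum(abs(r[idx][hit[idx]])^p) / n_r - sum(!hit[idx]) / n_miss
    if (d > best + 1e-15) { best <- d; best_i <- i }
  }
  list(es = best, argmax = best_i, ranked = names(r))
}

# one-sided KS from the two empirical rank CDFs, by direct counting
brute_force_ks <- function(ranked, labels, set_label) {
  hit <- labels[ranked] == set_label
  ns <- sum(hit); nc <- sum(!hit)
  max(sapply(seq_along(ranked),
             function(i) sum(hit[1:i]) / ns - sum(!hit[1:i]) / nc))
}

random_partition <- function(cell_ids, n_set, set_label = "case") {
  lab <- rep("control", length(cell_ids))
  lab[sample.int(length(cell_ids), n_set)] <- set_label
  cell_partition(stats::setNames(lab, cell_ids), set_label)
}
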