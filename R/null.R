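#' Permutation p-value for a CSEA enrichment score
#'
#' Shuffles the condition labels across cells (preserving group sizes) the
#' requested number of times, recomputes the enrichment score for each
#' shuffle, and reports the fraction of permuted scores at least as large as
#' the observed one. With `pseudo_count` on, the add-one form
#' `(k + 1) / (n + 1)` is used instead, bounding the p-value away from zero;
#' the default raw fraction can return exactly 0 when the observed ES
#' exceeds every permuted ES.
#'
#' @param scores named numeric vector of per-cell signature scores.
#' @param partition a [cell_partition] over the same cells.
#' @param params a [csea_params] object (weight exponent, permutation count,
#'   seed, direction, pseudo-count flag).
#' @return A `csea_result` (see [enrichment_score]) with `p_value` and
#'   `perm_es` (the permuted ES values) filled in.
#' @export
permutation_pvalue <- function(scores, partition, params = csea_params()) {
  stopifnot(inherits(params, "csea_params"))
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  ranked <- rank_cells(scores, params$direction)
  obs <- enrichment_score(scores, partition, params$weight_exponent,
                          params$direction, ranked = ranked)
  w <- if (params$weight_exponent == 0) rep(1, length(ranked))
       else abs(scores[ranked])^params$weight_exponent
  n <- partition$n
  perm_es <- vapply(seq_len(params$n_permutations), function(b) {
    hit <- logical(n)
    hit[sample.int(n, partition$n_set)] <- TRUE
    es_running_sum(w, hit)$es
  }, numeric(1))
  k <- sum(perm_es >= obs$es)
  obs$p_value <- if (params$pseudo_count) (k + 1) / (params$n_permutations + 1)
                 else k / params$n_permutations
  obs$n_permutations <- params$n_permutations
  obs$perm_es <- perm_es
  obs
}

#' Build an expression-matched random geneset
#'
#' Constructs a control signature matched to the input signature in size and
#' in per-gene mean expression: for each signature gene present in the
#' matrix, the `pool_size` genes with the closest mean expression (over all
#' cells of the normalized log matrix) form a candidate pool, and one
#' candidate is sampled uniformly. Sampling is without replacement across
#' the output so the control set contains no duplicate genes, and the
#' positive/negative structure of the input is mirrored.
#'
#' @param sig a [gene_signature].
#' @param expr cells x genes normalized log expression matrix.
#' @param pool_size number of nearest-mean candidates per gene (default 20).
#' @param exclude_signature_genes keep all original signature genes out of
#'   the control set (default `TRUE`).
#' @param rng_seed optional integer seed.
#' @return A [gene_signature] named `<name>_matched`.
#' @export
matched_geneset <- function(sig, expr, pool_size = 20,
                            exclude_signature_genes = TRUE, rng_seed = NULL) {
  stopifnot(pool_size >= 1)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  means <- Matrix::colMeans(expr)
  genes <- colnames(expr)
  sig_genes <- c(sig$positive, sig$negative)
  universe <- if (exclude_signature_genes) setdiff(genes, sig_genes) else genes
  if (length(universe) < pool_size)
    stop("candidate pool exhausted: fewer than pool_size genes available; ",
         "use a larger gene universe or a smaller pool", call. = FALSE)
  taken <- character(0)
  draw_for <- function(g) {
    cand <- setdiff(universe, g)
    d <- abs(means[cand] - means[[g]])
    pool <- cand[order(d, cand, method = "radix")][seq_len(pool_size)]
    avail <- setdiff(pool, taken)
    if (!length(avail))
      stop("candidate pool exhausted for gene '", g,
           "'; use a larger gene universe or a smaller pool", call. = FALSE)
    avail[sample.int(length(avail), 1L)]
  }
  pick_all <- function(gs) {
    vapply(gs, function(g) {
      p <- draw_for(g)
      taken <<- c(taken, p)
      p
    }, character(1), USE.NAMES = FALSE)
  }
  pos <- pick_all(intersect(sig$positive, genes))
  neg <- pick_all(intersect(sig$negative, genes))
  gene_signature(paste0(sig$name, "_matched"), pos, neg)
}

#' Matched-geneset null p-value for a signature
#'
#' Validation-grade null model: draws `n_sets` expression-matched control
#' genesets, scores cells on each, computes each control's enrichment score,
#' and reports the fraction of control scores at least as large as the true
#' signature's score.
#'
#' @param sig a [gene_signature].
#' @param expr cells x genes normalized log expression matrix.
#' @param partition a [cell_partition].
#' @param params a [csea_params] (its seed governs the control draws).
#' @param n_sets number of matched control genesets (1000 for validation).
#' @param pool_size nearest-mean candidate pool size (see
#'   [matched_geneset]).
#' @return List with `p_value`, the true `csea_result`, and `control_es`.
#' @export
geneset_null_pvalue <- function(sig, expr, partition, params = csea_params(),
                                n_sets = 1000, pool_size = 20) {
  stopifnot(n_sets >= 1)
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  true_scores <- score_signatures(expr, sig)[, 1L]
  true_res <- enrichment_score(true_scores, partition,
                               params$weight_exponent, params$direction)
  control_es <- vapply(seq_len(n_sets), function(b) {
    ctrl <- matched_geneset(sig, expr, pool_size = pool_size)
    s <- score_signatures(expr, ctrl)[, 1L]
    enrichment_score(s, partition, params$weight_exponent,
                     params$direction)$es
  }, numeric(1))
  list(p_value = mean(control_es >= true_res$es),
       true = true_res, control_es = control_es)
}

#' Screen signatures with the three-part filter
#'
#' Applies Benjamini-Hochberg correction across signatures, separately to
#' the true-signature p-values and to the matched-control p-values, then
#' retains signatures passing all of: corrected true p < 0.05, corrected
#' control p > 0.05, and leading-edge size < 1000 cells (all strict). The
#' control filter discards signatures whose matched random geneset is itself
#' enriched, i.e. enrichments explained by mean expression alone.
#'
#' @param results data frame with columns `signature`, `p_true`,
#'   `p_control` and `leading_edge_size`.
#' @param alpha significance level for the true-signature filter and the
#'   control guard (default 0.05).
#' @param max_leading_edge leading-edge size bound (default 1000).
#' @return The input with `corrected_p_true`, `corrected_p_control` and
#'   logical `retained` columns appended.
#' @export
screen_signatures <- function(results, alpha = 0.05, max_leading_edge = 1000) {
  need <- c("signature", "p_true", "p_control", "leading_edge_size")
  if (!all(need %in% names(results)))
    stop("results must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  results$corrected_p_true <- stats::p.adjust(results$p_true, method = "BH")
  results$corrected_p_control <- stats::p.adjust(results$p_control, method = "BH")
  results$retained <- results$corrected_p_true < alpha &
    results$corrected_p_control > alpha &
    results$leading_edge_size < max_leading_edge
  results
}

#' Control-geneset ES distributions across matching stringencies
#'
#' Draws control genesets at several nearest-mean pool sizes (smaller pool =
#' tighter expression matching) and fully at random ("unmatched"), and
#' summarizes the resulting enrichment-score distributions. Tight matching
#' should give the least variable control scores; unmatched sets the most.
#'
#' @param sig a [gene_signature].
#' @param expr cells x genes normalized log expression matrix.
#' @param partition a [cell_partition].
#' @param pool_sizes integer pool sizes to scan; `NA` entries (or the string
#'   "unmatched") request fully random draws from the non-signature
#'   universe.
#' @param n_draws control sets per matching level.
#' @param params a [csea_params].
#' @return Data frame with one row per matching level: mean, SD and
#'   quartiles of the control ES over `n_draws` draws.
#' @export
match_sensitivity <- function(sig, expr, partition,
                              pool_sizes = c(1, 5, 20, NA),
                              n_draws = 100, params = csea_params()) {
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  sig_genes <- c(sig$positive, sig$negative)
  universe <- setdiff(colnames(expr), sig_genes)
  lev <- ifelse(is.na(pool_sizes) | pool_sizes == "unmatched",
                "unmatched", as.character(pool_sizes))
  rows <- lapply(seq_along(pool_sizes), function(i) {
    es <- vapply(seq_len(n_draws), function(b) {
      ctrl <- if (lev[i] == "unmatched") {
        npos <- length(intersect(sig$positive, colnames(expr)))
        nneg <- length(intersect(sig$negative, colnames(expr)))
        g <- sample(universe, npos + nneg)
        gene_signature(paste0(sig$name, "_random"),
                       g[seq_len(npos)],
                       if (nneg) g[npos + seq_len(nneg)] else character())
      } else {
        matched_geneset(sig, expr, pool_size = as.integer(lev[i]))
      }
      s <- score_signatures(expr, ctrl)[, 1L]
      enrichment_score(s, partition, params$weight_exponent,
                       params$direction)$es
    }, numeric(1))
    q <- stats::quantile(es, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(pool = lev[i], n_draws = n_draws, mean_es = mean(es),
               sd_es = stats::sd(es), q25 = q[1], median = q[2], q75 = q[3])
  })
  do.call(rbind, rows)
}
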