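#' Run the full CSEA screening pipeline over a signature collection
#'
#' For each signature: scores all cells (per-cell z-scoring over all genes,
#' signed signature sum), computes the enrichment of the condition set at
#' the chosen tail with a label-permutation p-value, repeats the test on one
#' expression-matched random geneset as a specificity control, and finally
#' applies the three-part screen (BH-corrected true p < 0.05, corrected
#' control p > 0.05, leading edge < 1000 cells).
#'
#' @param expr cells x genes normalized log expression matrix.
#' @param partition a [cell_partition]; its cells must match the matrix
#'   rows.
#' @param signatures list of [gene_signature] objects (e.g. from
#'   [read_gmt]).
#' @param params a [csea_params].
#' @param pool_size nearest-mean candidate pool size for the matched
#'   control genesets (default 20).
#' @param alpha,max_leading_edge screening thresholds (see
#'   [screen_signatures]).
#' @param seed master seed; per-signature permutation and matching seeds
#'   are derived from it.
#' @return List with `table` (the screened results data frame) and
#'   `details` (per signature: the true and control `csea_result` objects
#'   and the matched control signature).
#' @export
csea_run <- function(expr, partition, signatures, params = csea_params(),
                     pool_size = 20, alpha = 0.05, max_leading_edge = 1000,
                     seed = 1) {
  validate_expression(expr)
  stopifnot(inherits(partition, "cell_partition"))
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  if (!setequal(rownames(expr), names(partition$labels)))
    stop("expression matrix and partition must cover the same cells",
         call. = FALSE)
  scores <- score_signatures(expr, signatures)
  details <- vector("list", length(signatures))
  names(details) <- colnames(scores)
  rows <- lapply(seq_along(signatures), function(k) {
    sig <- signatures[[k]]
    p_true <- params
    p_true$rng_seed <- derive_seed(seed, k, 1L)
    res_true <- permutation_pvalue(scores[, k], partition, p_true)
    ctrl <- matched_geneset(sig, expr, pool_size = pool_size,
                            rng_seed = derive_seed(seed, k, 2L))
    ctrl_scores <- score_signatures(expr, ctrl)[, 1L]
    p_ctrl <- params
    p_ctrl$rng_seed <- derive_seed(seed, k, 3L)
    res_ctrl <- permutation_pvalue(ctrl_scores, partition, p_ctrl)
    details[[k]] <<- list(true = res_true, control = res_ctrl,
                          control_signature = ctrl)
    data.frame(signature = sig$name,
               set = partition$set_label,
               es = res_true$es,
               p_true = res_true$p_value,
               es_control = res_ctrl$es,
               p_control = res_ctrl$p_value,
               leading_edge_size = length(res_true$leading_edge),
               leading_edge_subset_size = length(res_true$leading_edge_subset))
  })
  table <- screen_signatures(do.call(rbind, rows), alpha = alpha,
                             max_leading_edge = max_leading_edge)
  list(table = table, details = details)
}
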