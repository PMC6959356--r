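#' Center and scale each cell's expression profile
#'
#' Standardizes every cell profile (row) of a normalized log expression
#' matrix to mean 0 and standard deviation 1 across genes. The population
#' (divide-by-n) standard deviation is used; signature scores only require a
#' self-consistent convention, and the population form makes the all-genes
#' score identically zero.
#'
#' @param expr cells x genes matrix of normalized log expression.
#' @return A dense cells x genes matrix of per-cell z-scores.
#' @export
zscore_cells <- function(expr) {
  validate_expression(expr)
  if (ncol(expr) < 2L)
    stop("z-scoring needs at least 2 genes per cell", call. = FALSE)
  x <- as.matrix(expr)
  mom <- cell_moments(x)
  bad <- which(mom$sd <= 0)
  if (length(bad))
    stop("cell(s) with zero expression variance across genes: ",
         paste(utils::head(rownames(x)[bad], 5L), collapse = ", "),
         call. = FALSE)
  (x - mom$mean) / mom$sd
}

# per-cell mean and population SD over all genes; works on sparse input
# without densifying
cell_moments <- function(expr) {
  mu <- Matrix::rowMeans(expr)
  ex2 <- Matrix::rowMeans(expr^2)
  list(mean = mu, sd = sqrt(pmax(ex2 - mu^2, 0)))
}

#' Score cells on a gene signature
#'
#' Given a per-cell z-scored matrix, the score of a cell is the sum of its
#' z-values over the signature's positive genes minus the sum over its
#' negative genes, divided by the number of signature genes present in the
#' matrix. Signature genes absent from the matrix are dropped with a
#' warning; the normalization denominator counts only present genes so that
#' scores stay comparable across datasets with different gene coverage.
#'
#' @param expr_z per-cell z-scored cells x genes matrix (see
#'   [zscore_cells]).
#' @param sig a [gene_signature].
#' @param warn_missing warn when signature genes are absent from the matrix.
#' @return Named numeric vector of per-cell signature scores.
#' @export
score_signature <- function(expr_z, sig, warn_missing = TRUE) {
  pos <- intersect(sig$positive, colnames(expr_z))
  neg <- intersect(sig$negative, colnames(expr_z))
  n_total <- length(sig$positive) + length(sig$negative)
  n_used <- length(pos) + length(neg)
  if (n_used == 0L)
    stop("no gene of signature '", sig$name, "' is present in the matrix",
         call. = FALSE)
  if (warn_missing && n_used < n_total)
    warning(sprintf("signature '%s': %d of %d genes absent from matrix, dropped",
                    sig$name, n_total - n_used, n_total), call. = FALSE)
  s <- numeric(nrow(expr_z))
  if (length(pos)) s <- s + Matrix::rowSums(expr_z[, pos, drop = FALSE])
  if (length(neg)) s <- s - Matrix::rowSums(expr_z[, neg, drop = FALSE])
  stats::setNames(as.numeric(s) / n_used, rownames(expr_z))
}

#' Score cells on many signatures without densifying the matrix
#'
#' Computes per-cell moments over all genes, then z-scores only the union of
#' signature genes, so large sparse matrices are never fully densified.
#'
#' @param expr cells x genes normalized log expression matrix.
#' @param signatures list of [gene_signature] objects.
#' @return cells x signatures matrix of scores.
#' @export
score_signatures <- function(expr, signatures) {
  validate_expression(expr)
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  mom <- cell_moments(expr)
  if (any(mom$sd <= 0))
    stop("cell(s) with zero expression variance across genes: ",
         paste(utils::head(rownames(expr)[mom$sd <= 0], 5L), collapse = ", "),
         call. = FALSE)
  used <- intersect(unique(unlist(lapply(signatures, function(s)
    c(s$positive, s$negative)))), colnames(expr))
  sub_z <- (as.matrix(expr[, used, drop = FALSE]) - mom$mean) / mom$sd
  out <- vapply(signatures, function(s) score_signature(sub_z, s),
                numeric(nrow(expr)))
  dimnames(out) <- list(rownames(expr),
                        vapply(signatures, `[[`, character(1), "name"))
  out
}
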