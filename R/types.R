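#' Validate a cells x genes expression matrix
#'
#' An expression matrix in this package is a base or \pkg{Matrix} sparse
#' matrix of library-normalized log expression with cells in rows and genes
#' in columns. Row names are cell identifiers, column names gene symbols;
#' both must be unique, and all values finite. Identifiers are matched
#' case-sensitively throughout, with no symbol aliasing.
#'
#' @param x matrix-like object with complete dimnames.
#' @return `x`, invisibly, after validation.
#' @export
validate_expression <- function(x) {
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("expression matrix must have cell (row) and gene (column) names", call. = FALSE)
  if (anyDuplicated(rownames(x)))
    stop("duplicate cell identifiers in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("duplicate gene identifiers in expression matrix", call. = FALSE)
  vals <- if (methods::is(x, "sparseMatrix")) x@x else x
  if (any(!is.finite(vals)))
    stop("expression matrix contains NA/NaN/Inf values", call. = FALSE)
  invisible(x)
}

#' Construct a two-group cell partition
#'
#' Defines the cell set S tested for enrichment: all cells carrying
#' `set_label`, against the complement formed by the single other label
#' (e.g., MS vs control).
#'
#' @param labels named character vector, cell_id -> condition label.
#'   Exactly two distinct labels must be present.
#' @param set_label the label whose cells form the set of interest S.
#' @return An object of class `cell_partition` with elements `labels`,
#'   `set_label`, `n` (total cells) and `n_set` (size of S).
#' @export
cell_partition <- function(labels, set_label) {
  if (is.null(names(labels)) || any(names(labels) == ""))
    stop("labels must be named by cell identifier", call. = FALSE)
  if (anyDuplicated(names(labels)))
    stop("duplicate cell identifiers in labels", call. = FALSE)
  labels <- stats::setNames(as.character(labels), names(labels))
  lev <- unique(labels)
  if (length(lev) != 2L)
    stop("exactly two condition labels required, found ", length(lev), call. = FALSE)
  if (!set_label %in% lev)
    stop("set label '", set_label, "' not present in labels", call. = FALSE)
  n_set <- sum(labels == set_label)
  if (n_set == 0L || n_set == length(labels))
    stop("both condition groups must be non-empty", call. = FALSE)
  structure(
    list(labels = labels, set_label = set_label,
         n = length(labels), n_set = n_set),
    class = "cell_partition"
  )
}

#' @export
print.cell_partition <- function(x, ...) {
  cat(sprintf("cell_partition: %d cells, set '%s' (%d) vs complement (%d)\n",
              x$n, x$set_label, x$n_set, x$n - x$n_set))
  invisible(x)
}

#' Construct a gene signature
#'
#' A signature has a positive subset and an optional negative subset of gene
#' symbols; when scored, negative-subset expression is subtracted from
#' positive-subset expression.
#'
#' @param name signature name.
#' @param positive character vector of gene symbols.
#' @param negative character vector of gene symbols (may be empty).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(name, positive, negative = character()) {
  positive <- unique(as.character(positive))
  negative <- unique(as.character(negative))
  if (length(positive) + length(negative) == 0L)
    stop("signature '", name, "' has no genes", call. = FALSE)
  both <- intersect(positive, negative)
  if (length(both))
    stop("signature '", name, "' lists genes in both positive and negative subsets: ",
         paste(both, collapse = ", "), call. = FALSE)
  structure(list(name = name, positive = positive, negative = negative),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d positive, %d negative genes\n",
              x$name, length(x$positive), length(x$negative)))
  invisible(x)
}

#' CSEA test parameters
#'
#' @param weight_exponent non-negative exponent applied to |score| in the hit
#'   weights. 0 recovers a one-sided Kolmogorov-Smirnov statistic; 1 (the
#'   default) weights set members by score magnitude.
#' @param n_permutations number of label permutations for the null (default
#'   100).
#' @param rng_seed optional integer seed; permutations are reproducible when
#'   set.
#' @param direction which tail of the ranking is tested: `"high"` ranks cells
#'   by descending score, `"low"` by ascending score.
#' @param pseudo_count if `TRUE`, permutation p-values use the add-one
#'   correction (k+1)/(n+1) so they are never exactly zero.
#' @return An object of class `csea_params`.
#' @export
csea_params <- function(weight_exponent = 1, n_permutations = 100,
                        rng_seed = NULL, direction = c("high", "low"),
                        pseudo_count = FALSE) {
  direction <- match.arg(direction)
  stopifnot(is.numeric(weight_exponent), length(weight_exponent) == 1L,
            weight_exponent >= 0, n_permutations >= 1)
  structure(
    list(weight_exponent = weight_exponent,
         n_permutations = as.integer(n_permutations),
         rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
         direction = direction,
         pseudo_count = isTRUE(pseudo_count)),
    class = "csea_params"
  )
}

#' @export
print.csea_result <- function(x, ...) {
  cat(sprintf("csea_result: ES = %.4f at rank %d (leading-edge subset %d/%d cells)\n",
              x$es, x$argmax_rank, length(x$leading_edge_subset),
              length(x$leading_edge)))
  if (!is.na(x$p_value))
    cat(sprintf("  permutation p = %.4g (%d permutations)\n",
                x$p_value, x$n_permutations))
  invisible(x)
}
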