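#' Read an expression matrix from MatrixMarket or dense delimited text
#'
#' Supports the cellranger-style triplet layout (`matrix.mtx` plus one-column
#' gene and cell sidecar files) and dense TSV/CSV. Orientation is normalized
#' to cells x genes using the sidecar lengths; a square matrix whose sidecars
#' have equal lengths is rejected as ambiguous rather than guessed. Dense
#' files without sidecars must carry a header row of gene names and a first
#' column of cell identifiers.
#'
#' @param path_matrix path to a `.mtx` MatrixMarket file or a dense
#'   tab/comma-separated file (dialect chosen by extension, `.csv` = comma).
#' @param path_genes,path_cells optional sidecar files; the first column of
#'   each is used. Required for MatrixMarket input.
#' @return A cells x genes matrix of normalized log expression (sparse
#'   `dgCMatrix` for MatrixMarket input, base matrix otherwise).
#' @export
read_expression <- function(path_matrix, path_genes = NULL, path_cells = NULL) {
  if (is_mtx(path_matrix)) {
    if (is.null(path_genes) || is.null(path_cells))
      stop("MatrixMarket input requires gene and cell sidecar files", call. = FALSE)
    m <- tryCatch(Matrix::readMM(path_matrix),
                  error = function(e) stop("malformed MatrixMarket file: ",
                                           conditionMessage(e), call. = FALSE))
    m <- methods::as(m, "CsparseMatrix")
    genes <- read_id_column(path_genes)
    cells <- read_id_column(path_cells)
    m <- orient_cells_by_genes(m, cells, genes)
  } else {
    sep <- if (grepl("\\.csv$", path_matrix, ignore.case = TRUE)) "," else "\t"
    first <- strsplit(readLines(path_matrix, n = 1L), sep, fixed = TRUE)[[1]]
    has_header <- suppressWarnings(is.na(as.numeric(first[length(first)])))
    if (!is.null(path_genes) && !is.null(path_cells)) {
      m <- as.matrix(utils::read.table(path_matrix, sep = sep, header = FALSE,
                                       skip = as.integer(has_header)))
      dimnames(m) <- NULL
      m <- orient_cells_by_genes(m, read_id_column(path_cells),
                                 read_id_column(path_genes))
    } else {
      if (!has_header)
        stop("dense input without sidecars must have a header row of gene names",
             call. = FALSE)
      df <- utils::read.table(path_matrix, sep = sep, header = TRUE,
                              row.names = 1L, check.names = FALSE)
      m <- as.matrix(df)
    }
  }
  if (!methods::is(m, "sparseMatrix")) storage.mode(m) <- "double"
  validate_expression(m)
  m
}

is_mtx <- function(path) {
  grepl("\\.mtx$", path, ignore.case = TRUE) ||
    startsWith(readLines(path, n = 1L), "%%MatrixMarket")
}

read_id_column <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "")
  df[[1]]
}

orient_cells_by_genes <- function(m, cells, genes) {
  cg <- nrow(m) == length(cells) && ncol(m) == length(genes)
  gc <- nrow(m) == length(genes) && ncol(m) == length(cells)
  if (cg && gc)
    stop("square matrix with equally long sidecars: orientation is ambiguous",
         call. = FALSE)
  if (!cg && !gc)
    stop(sprintf("matrix is %d x %d but sidecars list %d cells and %d genes",
                 nrow(m), ncol(m), length(cells), length(genes)), call. = FALSE)
  if (gc) m <- Matrix::t(m)
  dimnames(m) <- list(cells, genes)
  m
}

#' Write an expression matrix
#'
#' MatrixMarket output (when `path_matrix` ends in `.mtx`) writes the
#' coordinate triplet with 17 significant digits so that read/write round
#' trips are value-exact; gene and cell sidecars are written alongside.
#' Dense output writes a TSV with a gene-name header and cell-id row names,
#' also at full precision.
#'
#' @param expr cells x genes matrix.
#' @param path_matrix output path (`.mtx` selects MatrixMarket).
#' @param path_genes,path_cells sidecar paths, required for MatrixMarket.
#' @return `path_matrix`, invisibly.
#' @export
write_expression <- function(expr, path_matrix, path_genes = NULL,
                             path_cells = NULL) {
  validate_expression(expr)
  if (grepl("\\.mtx$", path_matrix, ignore.case = TRUE)) {
    if (is.null(path_genes) || is.null(path_cells))
      stop("MatrixMarket output requires gene and cell sidecar paths", call. = FALSE)
    m <- methods::as(methods::as(expr, "CsparseMatrix"), "TsparseMatrix")
    header <- c("%%MatrixMarket matrix coordinate real general",
                sprintf("%d %d %d", nrow(m), ncol(m), length(m@x)))
    entries <- sprintf("%d %d %.17g", m@i + 1L, m@j + 1L, m@x)
    writeLines(c(header, entries), path_matrix)
    writeLines(rownames(expr), path_cells)
    writeLines(colnames(expr), path_genes)
  } else {
    sep <- if (grepl("\\.csv$", path_matrix, ignore.case = TRUE)) "," else "\t"
    dense <- as.matrix(expr)
    lines <- c(paste(c("cell_id", colnames(dense)), collapse = sep),
               vapply(seq_len(nrow(dense)), function(i) {
                 paste(c(rownames(dense)[i], sprintf("%.17g", dense[i, ])),
                       collapse = sep)
               }, character(1)))
    writeLines(lines, path_matrix)
    if (!is.null(path_genes)) writeLines(colnames(dense), path_genes)
    if (!is.null(path_cells)) writeLines(rownames(dense), path_cells)
  }
  invisible(path_matrix)
}

#' Read gene signatures from a GMT file
#'
#' Each GMT line is `name<TAB>description<TAB>gene...`. With
#' `merge_up_dn = TRUE` (the MSigDB-style convention), a pair of lines named
#' `X_UP` and `X_DN` is merged into one signed signature `X` whose positive
#' subset is the UP genes and negative subset the DN genes; unpaired lines
#' become positive-only signatures under their full names.
#'
#' @param path GMT file path.
#' @param merge_up_dn merge `_UP`/`_DN` pairs into signed signatures.
#' @return Named list of [gene_signature] objects.
#' @export
read_gmt <- function(path, merge_up_dn = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  raw <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- unique(f[-(1:2)][nzchar(f[-(1:2)])])
    if (length(f) < 3L || length(genes) == 0L)
      stop("GMT line '", f[1], "' has an empty gene list", call. = FALSE)
    list(name = f[1], genes = genes)
  })
  names(raw) <- vapply(raw, `[[`, character(1), "name")
  if (anyDuplicated(names(raw)))
    stop("duplicate signature names in GMT file", call. = FALSE)
  sigs <- list()
  if (merge_up_dn) {
    stems <- sub("_(UP|DN)$", "", names(raw))
    suffix <- ifelse(grepl("_UP$", names(raw)), "UP",
                     ifelse(grepl("_DN$", names(raw)), "DN", ""))
    for (st in unique(stems)) {
      idx <- which(stems == st)
      sf <- suffix[idx]
      if (all(c("UP", "DN") %in% sf) && length(idx) == 2L) {
        sigs[[st]] <- gene_signature(
          st,
          positive = raw[[idx[sf == "UP"]]]$genes,
          negative = raw[[idx[sf == "DN"]]]$genes)
      } else {
        for (i in idx)
          sigs[[raw[[i]]$name]] <- gene_signature(raw[[i]]$name, raw[[i]]$genes)
      }
    }
  } else {
    for (r in raw) sigs[[r$name]] <- gene_signature(r$name, r$genes)
  }
  sigs
}

#' Write gene signatures to a GMT file
#'
#' Signed signatures are written as `name_UP` / `name_DN` line pairs;
#' positive-only signatures as single lines.
#'
#' @param signatures list of [gene_signature] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  if (inherits(signatures, "gene_signature")) signatures <- list(signatures)
  lines <- unlist(lapply(signatures, function(s) {
    if (length(s$negative)) {
      c(paste(c(paste0(s$name, "_UP"), "na", s$positive), collapse = "\t"),
        paste(c(paste0(s$name, "_DN"), "na", s$negative), collapse = "\t"))
    } else {
      paste(c(s$name, "na", s$positive), collapse = "\t")
    }
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column cell label table as a cell partition
#'
#' @param path tab-separated file with cell_id and condition label columns.
#' @param set_label label whose cells form the set of interest.
#' @param header does the file carry a header row?
#' @return A [cell_partition].
#' @export
read_labels <- function(path, set_label, header = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = header,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L)
    stop("label file must have cell_id and label columns", call. = FALSE)
  if (anyDuplicated(df[[1]]))
    stop("duplicate cell identifiers in label file", call. = FALSE)
  cell_partition(stats::setNames(df[[2]], df[[1]]), set_label)
}

#' Write cell labels
#'
#' @param partition a [cell_partition].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(partition, path) {
  utils::write.table(
    data.frame(cell_id = names(partition$labels), label = partition$labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a screening results table with a leading-edge JSON sidecar
#'
#' The TSV carries one row per signature (ES, p-values, corrected p-values,
#' leading-edge sizes, retention flag); the JSON sidecar stores the full
#' leading-edge cell memberships keyed by signature name.
#'
#' @param screened data frame from [screen_signatures].
#' @param details per-signature list carrying `csea_result` objects (as
#'   produced by [csea_run]); used for the JSON sidecar. May be `NULL`.
#' @param path_tsv,path_json output paths (`path_json` optional).
#' @return `path_tsv`, invisibly.
#' @export
write_results <- function(screened, details = NULL, path_tsv,
                          path_json = NULL) {
  utils::write.table(screened, path_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(path_json) && !is.null(details)) {
    edge <- lapply(details, function(d)
      list(leading_edge = d$true$leading_edge,
           leading_edge_subset = d$true$leading_edge_subset))
    jsonlite::write_json(edge, path_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path_tsv)
}
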