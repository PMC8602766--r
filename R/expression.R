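#' Construct a cells-by-genes expression matrix
#'
#' Bundles a numeric matrix of pre-processed expression values (cells in
#' rows, genes in columns) with cell and gene identifiers and, optionally,
#' per-cell ordinal stage labels.  The package performs no QC or
#' normalization: values are consumed as supplied and distances are
#' Euclidean on this matrix.
#'
#' @param values numeric matrix, `N` cells by `D` genes; all values finite.
#' @param cell_ids character vector of `N` unique cell identifiers.
#'   Defaults to `rownames(values)` or `cell_1 ... cell_N`.
#' @param gene_ids character vector of `D` unique gene identifiers.
#'   Defaults to `colnames(values)` or `gene_1 ... gene_D`.
#' @param stage_labels optional factor or vector of `N` ordinal stage
#'   labels (e.g. developmental time points), used only for root selection
#'   and evaluation, never by the core algorithm.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `stage_labels`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), 5, 4)
#' em <- expression_matrix(x)
#' dim(em)
expression_matrix <- function(values, cell_ids = NULL, gene_ids = NULL,
                              stage_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2L) stop("need at least 2 cells, got ", n)
  if (d < 1L) stop("need at least 1 gene")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at cell ", bad[1L],
         ", gene ", bad[2L])
  }
  if (is.null(cell_ids)) cell_ids <- rownames(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(values)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(d))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != n) stop("cell_ids length does not match rows")
  if (length(gene_ids) != d) stop("gene_ids length does not match columns")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  if (!is.null(stage_labels)) {
    if (length(stage_labels) != n)
      stop("stage_labels length does not match the number of cells")
    if (!is.factor(stage_labels)) {
      lev <- unique(stage_labels)
      # numeric stage indices order naturally; names keep supplied order
      if (is.numeric(stage_labels)) lev <- sort(lev)
      stage_labels <- factor(stage_labels, levels = lev)
    }
  }
  rownames(values) <- cell_ids
  colnames(values) <- gene_ids
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         stage_labels = stage_labels),
    class = "expression_matrix"
  )
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "cells x",
      ncol(x$values), "genes\n")
  if (!is.null(x$stage_labels))
    cat("stages:", paste(levels(x$stage_labels), collapse = ", "), "\n")
  invisible(x)
}

# Accept either an expression_matrix or a bare numeric matrix.
as_expr_values <- function(x) {
  if (inherits(x, "expression_matrix")) return(x$values)
  as.matrix(x)
}
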