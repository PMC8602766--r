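#' Kernel distance between cells
#'
#' The kernel distance induced by the Bhattacharyya kernel is
#' `D_ij = sqrt(-2 logG_ij)`: the Euclidean distance between the cells'
#' (implicit) feature-space images, since `|y_i|^2 = logG_ii = 0` and
#' `<y_i, y_j> = logG_ij`.  Unlike the plain Bhattacharyya distance
#' `-log G_ij` (see [bhattacharyya_distance()]), this metric satisfies the
#' triangle inequality.  It is always computed from the full `logG`,
#' before any dimension reduction, so no spectral truncation error enters
#' the pseudotime.
#'
#' @param kernel a [bhattacharyya_kernel()] result.
#' @return An object of class `kernel_distance`: list with `D` (dense
#'   symmetric `N x N`, zero diagonal) and `cell_ids`.
#' @export
kernel_distance <- function(kernel) {
  stopifnot(inherits(kernel, "bhattacharyya_kernel"))
  lg <- kernel$logG
  off_max <- max(lg - diag(diag(lg)))
  if (off_max > 1e-8)
    stop("internal error: positive off-diagonal logG entry (",
         fmtnum(off_max), ") violates the kernel bound G <= 1")
  lg[lg > 0] <- 0
  D <- sqrt(-2 * lg)
  diag(D) <- 0
  structure(list(D = D, cell_ids = kernel$cell_ids),
            class = "kernel_distance")
}

#' Bhattacharyya distance (reference only)
#'
#' `-log G_ij`, the classical Bhattacharyya distance between the two
#' cells' diffusion distributions.  It does not satisfy the triangle
#' inequality and is not used by the pipeline, which relies on
#' [kernel_distance()] instead; it is exported for comparison.
#'
#' @param kernel a [bhattacharyya_kernel()] result.
#' @return dense symmetric `N x N` matrix of `-log G` values.
#' @export
bhattacharyya_distance <- function(kernel) {
  stopifnot(inherits(kernel, "bhattacharyya_kernel"))
  Db <- -log(pmax(kernel$G, 1e-300))
  diag(Db) <- 0
  Db
}

#' Select root cells
#'
#' Chooses `R` root cells with the following priority: explicit
#' `root_ids` are used verbatim; otherwise, if stage labels are given, the
#' candidates are restricted to the earliest stage and the `R` cells with
#' the largest sum of kernel distances to all other cells are taken;
#' without labels the same row-sum criterion is applied globally.  Ties
#' are broken by ascending cell index.
#'
#' @param dist a [kernel_distance()] result.
#' @param labels optional per-cell stage labels (factor: level order is
#'   the stage order; otherwise order of first appearance is used).
#' @param root_ids optional explicit cell identifiers to use as roots.
#' @param R number of roots (default 1).
#' @param earliest optional label value naming the earliest stage;
#'   defaults to the first level of `labels`.
#' @return integer vector of root indices, named by cell id.
#' @export
select_roots <- function(dist, labels = NULL, root_ids = NULL, R = 1,
                         earliest = NULL) {
  stopifnot(inherits(dist, "kernel_distance"))
  n <- nrow(dist$D)
  if (!is_count(R) || R < 1L) stop("R must be a positive integer")
  if (R > n) stop("R = ", R, " exceeds the number of cells N = ", n)
  if (!is.null(root_ids)) {
    roots <- match(as.character(root_ids), dist$cell_ids)
    if (anyNA(roots))
      stop("unknown root cell id(s): ",
           paste(root_ids[is.na(roots)], collapse = ", "))
    names(roots) <- dist$cell_ids[roots]
    return(roots)
  }
  rs <- rowSums(dist$D)
  cand <- seq_len(n)
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("labels length does not match the number of cells")
    if (!is.factor(labels)) labels <- factor(labels, levels = unique(labels))
    if (is.null(earliest)) earliest <- levels(labels)[1L]
    cand <- which(labels == earliest)
    if (length(cand) == 0L) stop("no cells carry the earliest label '",
                                 earliest, "'")
    if (R > length(cand))
      stop("R = ", R, " exceeds the ", length(cand),
           " cells in the earliest stage")
  }
  ord <- cand[order(-rs[cand], cand)]
  roots <- ord[seq_len(R)]
  names(roots) <- dist$cell_ids[roots]
  roots
}

#' Normalized pseudotime from root cells
#'
#' The raw pseudotime of cell `i` is its summed kernel distance to the
#' root set, `Tr_i = sum_r D[r, i]`, then min-max normalized to `[0, 1]`.
#' With a single root the root itself sits at pseudotime 0.  If all raw
#' values coincide (e.g. all cells identical) a zero vector is returned
#' with a warning instead of NaN.
#'
#' @param dist a [kernel_distance()] result.
#' @param roots integer root indices, e.g. from [select_roots()].
#' @return An object of class `pseudotime`: a named numeric vector in
#'   `[0, 1]` with attributes `roots` (indices) and `raw` (the
#'   pre-normalization distances).
#' @export
compute_pseudotime <- function(dist, roots) {
  stopifnot(inherits(dist, "kernel_distance"))
  n <- nrow(dist$D)
  roots <- as.integer(roots)
  if (length(roots) == 0L) stop("root set is empty")
  if (any(roots < 1L | roots > n)) stop("root index out of range")
  raw <- colSums(dist$D[roots, , drop = FALSE])
  rng <- range(raw)
  if (rng[1L] == rng[2L]) {
    warning("all raw pseudotime values are equal; returning zeros")
    tt <- rep(0, n)
  } else {
    tt <- (raw - rng[1L]) / (rng[2L] - rng[1L])
  }
  names(tt) <- dist$cell_ids
  structure(tt, class = "pseudotime", roots = roots, raw = raw)
}

#' @export
print.pseudotime <- function(x, ...) {
  cat("pseudotime over", length(x), "cells; root(s):",
      paste(attr(x, "roots"), collapse = ", "), "\n")
  print(stats::quantile(unclass(x)))
  invisible(x)
}
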