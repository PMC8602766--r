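#' Build the k-nearest-neighbour graph with adaptive kernel widths
#'
#' For each cell, finds its `k` nearest cells by Euclidean distance on the
#' supplied expression matrix, with the cell itself always counted as its
#' own first neighbour.  The local kernel width `sigma[i]` is the distance
#' from cell `i` to its k-th nearest neighbour (self included), so that
#' the Gaussian affinity adapts to local density.  Ties in distance are
#' broken by ascending cell index for determinism.
#'
#' @param X an [expression_matrix()] or numeric cells-by-genes matrix.
#' @param k neighbour count, self included; `2 <= k <= N` for the kernel
#'   pipeline (`k = 1` is allowed here but rejected downstream).
#' @param sigma_scale multiplier applied to every `sigma[i]` (default 1).
#'
#' @return An object of class `neighbor_graph`: list with `k`, `idx`
#'   (`N x k` integer matrix, row `i` = neighbour indices of cell `i`,
#'   self first, then by increasing distance), `dist` (matching Euclidean
#'   distances), `sigma` (per-cell width, floored at 1e-12), `cell_ids`.
#' @export
#' @examples
#' X <- matrix(c(0, 1, 10), ncol = 1)
#' g <- build_knn(X, k = 2)
#' g$sigma  # 1 1 9
build_knn <- function(X, k, sigma_scale = 1) {
  V <- as_expr_values(X)
  n <- nrow(V)
  cell_ids <- rownames(V)
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(n))
  if (!is_count(k) || k < 1L) stop("k must be a positive integer")
  k <- as.integer(k)
  if (k > n) stop("k = ", k, " exceeds the number of cells N = ", n)
  if (!all(is.finite(V))) stop("expression matrix contains non-finite values")
  if (!(is.numeric(sigma_scale) && length(sigma_scale) == 1L &&
        sigma_scale > 0)) stop("sigma_scale must be a positive scalar")

  dm <- as.matrix(stats::dist(V))
  idx <- matrix(0L, n, k)
  ndist <- matrix(0, n, k)
  all_i <- seq_len(n)
  for (i in all_i) {
    di <- dm[i, ]
    ord <- order(di, all_i)           # ties broken by ascending index
    ord <- c(i, ord[ord != i])[seq_len(k)]  # self is always first
    idx[i, ] <- ord
    ndist[i, ] <- di[ord]
  }
  sigma <- ndist[, k] * sigma_scale
  floored <- sigma < 1e-12
  if (any(floored)) {
    # k = 1 keeps only the zero self-distance, so flooring is expected
    if (k > 1L)
      warning(sum(floored), " cell(s) with duplicate coordinates: ",
              "sigma floored at 1e-12")
    sigma[floored] <- 1e-12
  }
  structure(
    list(k = k, idx = idx, dist = ndist, sigma = sigma,
         n_cells = n, cell_ids = cell_ids),
    class = "neighbor_graph"
  )
}

#' @export
print.neighbor_graph <- function(x, ...) {
  cat("neighbor_graph:", x$n_cells, "cells, k =", x$k, "\n")
  invisible(x)
}

#' Adaptive-bandwidth Gaussian affinity kernel
#'
#' Converts neighbour distances into symmetric Gaussian affinities
#' `K(i, j) = exp(-d(i, j)^2 / (2 sigma_i sigma_j))` on the symmetrized
#' edge set of the kNN graph (if `i` lists `j` but not vice versa, the
#' edge is mirrored with the same weight), zero elsewhere.  The raw kernel
#' is then normalized by the per-cell sums `Z_i = sum_j K(i, j)` as
#' `K(i, j) / (Z_i Z_j)`, which keeps it symmetric.
#'
#' @param graph a [build_knn()] result with `k >= 2`.
#' @return An object of class `affinity_kernel`: list with `K` (sparse
#'   symmetric `dgCMatrix` of normalized affinities), `Z` (per-cell
#'   normalizers of the raw kernel), `cell_ids`.
#' @export
gaussian_affinity <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  if (graph$k < 2L)
    stop("k = 1 gives an edgeless graph; the kernel requires k >= 2")
  n <- graph$n_cells
  k <- graph$k
  ii <- rep(seq_len(n), times = k)
  jj <- as.vector(graph$idx)
  dd <- as.vector(graph$dist)
  # canonical undirected edges (the weight formula is symmetric in i, j)
  ci <- pmin(ii, jj)
  cj <- pmax(ii, jj)
  key <- (ci - 1) * n + cj
  keep <- !duplicated(key)
  ci <- ci[keep]; cj <- cj[keep]; dd <- dd[keep]
  w <- exp(-dd^2 / (2 * graph$sigma[ci] * graph$sigma[cj]))
  off <- ci != cj
  K <- Matrix::sparseMatrix(
    i = c(ci, cj[off]), j = c(cj, ci[off]), x = c(w, w[off]),
    dims = c(n, n)
  )
  Z <- Matrix::rowSums(K)
  if (any(Z <= 0)) stop("internal error: all-zero affinity row")
  Kn <- Matrix::Diagonal(x = 1 / Z) %*% K %*% Matrix::Diagonal(x = 1 / Z)
  structure(
    list(K = methods::as(Kn, "CsparseMatrix"), Z = Z,
         cell_ids = graph$cell_ids),
    class = "affinity_kernel"
  )
}

#' Row-stochastic Markov transition matrix
#'
#' Normalizes each row of the normalized affinity kernel to sum to one,
#' yielding the transition matrix of the random walk on the symmetrized
#' kNN graph.  Self-affinities are retained (the walk is aperiodic).
#'
#' @param kernel a [gaussian_affinity()] result.
#' @return An object of class `transition_matrix`: list with `M` (sparse
#'   row-stochastic `dgCMatrix` sharing the kernel's sparsity pattern) and
#'   `cell_ids`.
#' @export
markov_matrix <- function(kernel) {
  stopifnot(inherits(kernel, "affinity_kernel"))
  rs <- Matrix::rowSums(kernel$K)
  if (any(rs <= 0)) stop("affinity kernel has an all-zero row")
  M <- Matrix::Diagonal(x = 1 / rs) %*% kernel$K
  structure(
    list(M = methods::as(M, "CsparseMatrix"), cell_ids = kernel$cell_ids),
    class = "transition_matrix"
  )
}

# Number of connected components of the symmetrized kNN graph, plus the
# per-cell component membership.  Used by the pipeline's connectivity gate.
graph_components <- function(graph) {
  stopifnot(inherits(graph, "neighbor_graph"))
  n <- graph$n_cells
  ii <- rep(seq_len(n), times = graph$k)
  jj <- as.vector(graph$idx)
  g <- igraph::graph_from_edgelist(cbind(ii, jj), directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  list(n = comp$no, membership = as.integer(comp$membership),
       sizes = as.integer(comp$csize))
}
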