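#' Stationary operator of the random walk with restart
#'
#' At each step the walker either follows an edge of the Markov matrix
#' with probability `p` or teleports back to its seed cell with restart
#' probability `1 - p`.  Letting the walk run to stationarity gives, for
#' every seed cell, a probability distribution over all cells:
#' `S = (1 - p) (I - p M)^{-1}`, computed by a direct linear solve rather
#' than explicit inversion, with rows renormalized to absorb round-off.
#' Row `i` of `S` is the diffusion representation of cell `i`; on a
#' connected graph every entry is strictly positive.  The accumulated
#' transition matrix used by diffusion pseudotime corresponds to the
#' `p = 1` limit, which is rejected here (the resolvent diverges).
#'
#' @param M a [markov_matrix()] result (or a row-stochastic base matrix).
#' @param p walk-continuation probability, strictly between 0 and 1.
#'   Default 0.9, which weighs global connectivity heavily while keeping
#'   the restart anchor.
#' @return An object of class `diffusion_matrix`: list with `S` (dense
#'   `N x N` matrix, each row a probability distribution), `p`,
#'   `cell_ids`.
#' @export
rwr_stationary <- function(M, p = 0.9) {
  if (!(is.numeric(p) && length(p) == 1L && is.finite(p)))
    stop("p must be a single number")
  if (p >= 1)
    stop("p = 1 is the diffusion-pseudotime (DPT) limit and is not ",
         "supported: the stationary operator (1-p)(I-pM)^{-1} requires ",
         "p < 1")
  if (p <= 0) stop("p must lie strictly in (0, 1)")
  cell_ids <- NULL
  if (inherits(M, "transition_matrix")) {
    cell_ids <- M$cell_ids
    M <- M$M
  }
  n <- nrow(M)
  rs <- Matrix::rowSums(M)
  if (max(abs(rs - 1)) > 1e-8) stop("M is not row-stochastic")
  if (n < 2000L) {
    A <- diag(n) - p * as.matrix(M)
    S <- solve(A, diag(1 - p, n))
  } else {
    A <- Matrix::Diagonal(n) - p * M
    S <- as.matrix(Matrix::solve(A, Matrix::Diagonal(n) * (1 - p)))
  }
  S[S < 0] <- 0            # round-off only; true entries are positive
  S <- S / rowSums(S)
  if (!is.null(cell_ids)) dimnames(S) <- list(cell_ids, cell_ids)
  structure(list(S = S, p = p, cell_ids = cell_ids),
            class = "diffusion_matrix")
}

#' Bhattacharyya kernel between diffusion distributions
#'
#' The Bhattacharyya coefficient between two discrete distributions `p`
#' and `q` over the same cells is `sum_x sqrt(p_x q_x)`, a similarity in
#' (0, 1] equal to 1 iff the distributions coincide.  Applied to all pairs
#' of rows of the diffusion matrix this gives the kernel matrix
#' `G = sqrt(S) %*% t(sqrt(S))` (square root taken elementwise).  The
#' diagonal is exactly 1 by normalization and is clamped to 1 to remove
#' round-off; `logG` is the elementwise logarithm (entries floored at
#' 1e-300 before the log), a symmetric non-positive matrix with zero
#' diagonal that drives both the embedding and the pseudotime metric.
#'
#' @param S a [rwr_stationary()] result.
#' @return An object of class `bhattacharyya_kernel`: list with `G`,
#'   `logG` (both dense symmetric `N x N`), `cell_ids`.
#' @export
bhattacharyya_kernel <- function(S) {
  stopifnot(inherits(S, "diffusion_matrix"))
  R <- sqrt(S$S)
  G <- tcrossprod(R)
  G <- (G + t(G)) / 2
  G[G > 1] <- 1
  diag(G) <- 1
  logG <- log(pmax(G, 1e-300))
  diag(logG) <- 0
  structure(list(G = G, logG = logG, cell_ids = S$cell_ids),
            class = "bhattacharyya_kernel")
}

#' Low-dimensional spectral embedding of the log-kernel
#'
#' Decomposes the symmetric (indefinite, zero-trace) matrix `logG` by a
#' symmetric eigendecomposition; the singular values of `logG` are the
#' absolute eigenvalues.  The `d` largest singular values are retained and
#' the coordinates are `Y_d = V_d diag(sqrt(sigma_d))`.  Signs are fixed
#' deterministically: each eigenvector is flipped so its largest-magnitude
#' entry is positive.
#'
#' @param kernel a [bhattacharyya_kernel()] result.
#' @param d target dimension, `1 <= d <= N`; 2 or 3 for visualization.
#' @return An object of class `cell_embedding`: list with `Y` (`N x d`
#'   coordinates), `singular_values` (the retained `d`, non-increasing),
#'   `eigenvalues` (signed, same order), `d`, `cell_ids`.
#' @export
embed_kernel <- function(kernel, d = 2) {
  stopifnot(inherits(kernel, "bhattacharyya_kernel"))
  n <- nrow(kernel$logG)
  if (!is_count(d) || d < 1L) stop("d must be a positive integer")
  d <- as.integer(d)
  if (d > n) stop("d = ", d, " exceeds the number of cells N = ", n)
  eig <- eigen(kernel$logG, symmetric = TRUE)
  sv <- abs(eig$values)
  ord <- order(sv, decreasing = TRUE)
  sv <- sv[ord]
  lam <- eig$values[ord]
  V <- eig$vectors[, ord, drop = FALSE]
  tol <- if (sv[1L] > 0) sv[1L] * 1e-12 else 0
  nz <- sum(sv > tol)
  if (d > nz)
    warning("only ", nz, " non-zero singular values; trailing ",
            d - nz, " embedding column(s) are zero")
  keep <- seq_len(d)
  Vd <- V[, keep, drop = FALSE]
  svd_d <- sv[keep]
  svd_d[keep > nz] <- 0
  for (j in seq_len(d)) {       # deterministic sign convention
    col <- Vd[, j]
    m <- which.max(abs(col))
    if (col[m] < 0) Vd[, j] <- -col
  }
  Y <- Vd * rep(sqrt(svd_d), each = n)
  rownames(Y) <- kernel$cell_ids
  structure(
    list(Y = Y, singular_values = svd_d, eigenvalues = lam[keep],
         d = d, cell_ids = kernel$cell_ids),
    class = "cell_embedding"
  )
}
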