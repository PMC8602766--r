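kernel_chain <- function(X, k = 4, p = 0.9) {
  bhattacharyya_kernel(rwr_stationary(markov_matrix(
    gaussian_affinity(build_knn(X, k))), p))
}

test_that("kernel distance follows sqrt(-2 logG) with zero diagonal", {
  # scalar chain from the 2-cell diffusion closed form:
  # G12 = 2 sqrt(.55 * .45) => D12 = sqrt(-2 log G12) ~ 0.1002
  M <- structure(list(M = methods::as(Matrix::Matrix(matrix(0.5, 2, 2),
                                                     sparse = TRUE),
                                      "CsparseMatrix"),
                      cell_ids = c("a", "b")),
                 class = "transition_matrix")
  K <- bhattacharyya_kernel(rwr_stationary(M, 0.9))
  D <- kernel_distance(K)
  g12 <- 2 * sqrt(0.55 * 0.45)
  expect_equal(D$D[1, 2], sqrt(-2 * log(g12)), tolerance = 1e-12)
  expect_equal(D$D[1, 2], 0.1002, tolerance = 1e-3)
  expect_equal(diag(D$D), c(0, 0), ignore_attr = TRUE)
  expect_equal(D$D, t(D$D))
})

test_that("kernel distance satisfies the triangle inequality on exhaustive triples", {
  for (seed in 1:4) {
    X <- rand_connected_instance(15, k = 4, seed = seed)
    D <- kernel_distance(kernel_chain(X))$D
    n <- nrow(D)
    worst <- 0
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (l in (j + 1):n) {
      worst <- max(worst,
                   D[i, j] - D[i, l] - D[l, j],
                   D[i, l] - D[i, j] - D[j, l],
                   D[j, l] - D[j, i] - D[i, l])
    }
    expect_lte(worst, 1e-10)
  }
})

test_that("the plain Bhattacharyya distance is exposed but can break the triangle inequality", {
  X <- rand_connected_instance(15, k = 4, seed = 2)
  K <- kernel_chain(X)
  Db <- bhattacharyya_distance(K)
  expect_equal(Db, -log(K$G), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(diag(Db), rep(0, 15), ignore_attr = TRUE)
})

test_that("root selection honors explicit ids, stage labels and index tie-breaks", {
  X <- matrix(seq(0, 10, length.out = 11), ncol = 1)
  rownames(X) <- paste0("c", 1:11)
  D <- kernel_distance(kernel_chain(X))

  expect_equal(unname(select_roots(D, root_ids = "c7")), 7L)
  expect_error(select_roots(D, root_ids = "nope"), "unknown root")

  # earliest label group at one end of a chain: the extreme cell of that
  # group maximizes the distance row-sum
  labs <- factor(rep(c("early", "late"), c(4, 7)), levels = c("early", "late"))
  expect_equal(unname(select_roots(D, labels = labs)), 1L)
  # label order is the factor's, not lexicographic
  labs2 <- factor(rep(c("P6", "E10.5"), c(4, 7)), levels = c("P6", "E10.5"))
  expect_equal(unname(select_roots(D, labels = labs2)), 1L)
  expect_equal(unname(select_roots(D, labels = labs2, earliest = "E10.5")),
               11L)

  # perfectly symmetric two-cell instance: tie broken by ascending index
  X2 <- matrix(c(0, 1), ncol = 1)
  D2 <- kernel_distance(kernel_chain(X2, k = 2))
  expect_equal(unname(select_roots(D2)), 1L)

  expect_error(select_roots(D, R = 12), "exceeds")
})

test_that("pseudotime is min-max normalized, rooted at zero and rank-stable", {
  X <- matrix(c(0, 1, 2.2, 3.1, 4.4, 6), ncol = 1)
  D <- kernel_distance(kernel_chain(X, k = 3))
  pt <- compute_pseudotime(D, roots = 1L)
  expect_equal(min(pt), 0)
  expect_equal(max(pt), 1)
  expect_equal(unname(unclass(pt)[1]), 0)
  # monotone along the chain
  expect_true(all(diff(as.numeric(pt)) > 0))

  # normalization idempotence
  raw <- attr(pt, "raw")
  once <- (raw - min(raw)) / (max(raw) - min(raw))
  twice <- (once - min(once)) / (max(once) - min(once))
  expect_equal(once, twice)

  # ranking invariant under strictly increasing transforms of the raw values
  expect_equal(rank(as.numeric(pt)), unname(rank(exp(raw))))

  # multi-root: summed distance rows
  pt2 <- compute_pseudotime(D, roots = c(1L, 2L))
  expect_equal(attr(pt2, "raw"), colSums(D$D[1:2, ]))

  # identical cells keep distinct self-anchored diffusion rows, so their
  # kernel distances are equal but positive: normalization gives 0/1
  Xd <- matrix(c(1, 1, 1), ncol = 1)
  suppressWarnings(Dd <- kernel_distance(kernel_chain(Xd, k = 3)))
  expect_gt(Dd$D[1, 2], 0)
  expect_equal(Dd$D[1, 2], Dd$D[1, 3])
  ptd <- compute_pseudotime(Dd, 1L)
  expect_equal(as.numeric(ptd), c(0, 1, 1))

  # a fully degenerate distance matrix collapses to zeros with a warning
  D0 <- structure(list(D = matrix(0, 3, 3), cell_ids = c("a", "b", "c")),
                  class = "kernel_distance")
  expect_warning(pt0 <- compute_pseudotime(D0, 1L), "equal")
  expect_equal(as.numeric(pt0), c(0, 0, 0))
})

test_that("noiseless linear trajectories are recovered almost perfectly", {
  sim <- simulate_branching(120, 30, "linear", noise_sd = 0, seed = 42)
  ip <- difftraj:::infer_pseudotime(sim$X, k = 10, p = 0.9)
  tau <- kendall_accuracy(ip$pt, sim$truth$true_pseudotime)
  expect_gte(tau, 0.95)
})
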