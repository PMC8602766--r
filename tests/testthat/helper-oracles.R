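# Independent oracles and fixture builders used across the test files.

# Jittered 1-D line (optionally with low-variance extra dimensions) whose
# kNN graph is connected; connectivity is verified, not assumed.
rand_connected_instance <- function(n, k, d = 2, seed = 1) {
  set.seed(seed)
  for (try in 1:20) {
    X <- matrix(cumsum(runif(n, 0.2, 1)), ncol = 1)
    if (d > 1) X <- cbind(X, matrix(rnorm(n * (d - 1), sd = 0.3), n))
    g <- build_knn(X, k)
    if (difftraj:::graph_components(g)$n == 1L) return(X)
  }
  stop("could not build a connected instance")
}

# Dense, loop-based evaluation of the kNN / adaptive Gaussian affinity /
# row-normalized Markov chain, written independently of the package's
# sparse path (same tie-break and sigma conventions).
oracle_knn_markov <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  dm <- as.matrix(stats::dist(X))
  A <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    ord <- order(dm[i, ], seq_len(n))
    A[i, ] <- c(i, ord[ord != i])[seq_len(k)]
  }
  sigma <- pmax(vapply(seq_len(n), function(i) max(dm[i, A[i, ]]),
                       numeric(1)), 1e-12)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in A[i, ]) {
      w <- exp(-dm[i, j]^2 / (2 * sigma[i] * sigma[j]))
      K[i, j] <- w
      K[j, i] <- w
    }
  }
  Z <- rowSums(K)
  Kn <- K / outer(Z, Z)
  M <- Kn / rowSums(Kn)
  list(A = A, sigma = sigma, K = Kn, M = M)
}

# Truncated Neumann series of the restart walk: sum_{t=0}^{T} (1-p) p^t M^t
neumann_S <- function(M, p, Tn) {
  M <- as.matrix(M)
  n <- nrow(M)
  P <- diag(n)
  S <- matrix(0, n, n)
  for (t in 0:Tn) {
    S <- S + (1 - p) * p^t * P
    P <- P %*% M
  }
  S
}

# Kendall tau-b by exhaustive pair enumeration with tie corrections
tau_b_bruteforce <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; Tx <- 0; Ty <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    dx <- x[i] - x[j]
    dy <- y[i] - y[j]
    if (dx == 0 && dy == 0) { Tx <- Tx + 1; Ty <- Ty + 1 }
    else if (dx == 0) Tx <- Tx + 1
    else if (dy == 0) Ty <- Ty + 1
    else if (sign(dx) == sign(dy)) C <- C + 1
    else D <- D + 1
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - Tx) * (n0 - Ty))
}

# Deterministic Y-shaped point set: a sparse trunk along the x axis and
# two dense arms whose only bridge to the trunk is the trunk-top cell, so
# branch membership is unambiguous at the junction (the arms fill their
# own kNN lists before reaching the trunk).  Returns coordinates plus
# truth labels.
y_fixture <- function() {
  trunk <- cbind(seq(0, 5, by = 0.5), 0)
  i <- 0:19
  s <- 0.45 / sqrt(2)
  armA <- cbind(5 + s + 0.1 * i / sqrt(2), s + 0.1 * i / sqrt(2))
  armB <- cbind(5 + s + 0.1 * i / sqrt(2), -s - 0.1 * i / sqrt(2))
  X <- rbind(trunk, armA, armB)
  rownames(X) <- sprintf("c%02d", seq_len(nrow(X)))
  list(X = X,
       truth = c(rep("trunk", nrow(trunk)),
                 rep("armA", nrow(armA)),
                 rep("armB", nrow(armB))))
}

# full pipeline shorthand for tests
quick_pipeline <- function(X, k = 10, p = 0.9, ...) {
  suppressWarnings(run_pipeline(X, k = k, p = p, ...))
}
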