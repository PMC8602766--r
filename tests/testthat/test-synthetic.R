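test_that("the simulator is seed-deterministic and validates its arguments", {
  a <- simulate_branching(300, 50, "bifurcating", noise_sd = 0.2, seed = 1)
  b <- simulate_branching(300, 50, "bifurcating", noise_sd = 0.2, seed = 1)
  expect_identical(a$X$values, b$X$values)
  expect_identical(a$truth$true_pseudotime, b$truth$true_pseudotime)
  c <- simulate_branching(300, 50, "bifurcating", noise_sd = 0.2, seed = 2)
  expect_false(identical(a$X$values, c$X$values))

  expect_error(simulate_branching(5, 50, "linear"), "n_cells")
  expect_error(simulate_branching(50, 3, "linear"), "n_genes")
  expect_error(simulate_branching(50, 20, "spiral"), "arg")
})

test_that("the two-level topology carries five segments and three terminal fates", {
  sim <- simulate_branching(400, 40, "two_level", noise_sd = 0.1, seed = 3)
  segs <- sim$truth$segments
  expect_equal(nrow(segs), 5L)
  terminals <- segs$name[!(segs$name %in% segs$parent)]
  expect_equal(sort(terminals), c("armA", "armB1", "armB2"))
  expect_setequal(unique(sim$truth$true_fate), terminals)
  # trunk cells precede every arm cell in true pseudotime
  tt <- sim$truth$true_pseudotime
  expect_lt(max(tt[sim$truth$true_branch == "trunk"]),
            min(tt[sim$truth$true_branch != "trunk"]))
})

test_that("noiseless linear data vary monotonically and isometrically along pseudotime", {
  sim <- simulate_branching(60, 20, "linear", noise_sd = 0, seed = 5)
  ord <- order(sim$truth$true_pseudotime)
  E <- sim$X$values[ord, ]
  # program genes are non-decreasing along true pseudotime; noise genes flat
  mono <- apply(E, 2, function(col) all(diff(col) >= -1e-12))
  expect_true(all(mono))
  # equally spaced pseudotimes are equidistant in expression space
  t_sorted <- sim$truth$true_pseudotime[ord]
  d01 <- sqrt(sum((E[10, ] - E[1, ])^2))
  d02 <- sqrt(sum((E[25, ] - E[10, ])^2))
  expect_equal(d01 / (t_sorted[10] - t_sorted[1]),
               d02 / (t_sorted[25] - t_sorted[10]), tolerance = 1e-8)
})

test_that("Kendall accuracy matches exhaustive pair enumeration and flags degenerate input", {
  stages <- c(1, 1, 2, 2, 3, 3)
  pt <- c(0, .1, .5, .4, .8, .9)
  expect_equal(kendall_accuracy(pt, stages),
               tau_b_bruteforce(pt, stages), tolerance = 1e-12)
  # tau-b is 1 / -1 for perfect (anti)concordance without ties
  expect_equal(kendall_accuracy(sort(pt), 1:6), 1)
  expect_equal(kendall_accuracy(rev(sort(pt)), 1:6), -1)
  # with tied stages the tie-corrected maximum is below 1
  expect_equal(kendall_accuracy(sort(pt), stages),
               tau_b_bruteforce(sort(pt), stages), tolerance = 1e-12)

  # binned mode discretizes pseudotime into stage-sized groups first:
  # ranking (0, .1, .4, .5, .8, .9) into sizes (2, 2, 2) reproduces the
  # stage sequence exactly here
  expect_equal(kendall_accuracy(pt, stages, mode = "binned"), 1)
  # a shuffled ordering bins to (2, 2, 1, 1, 3, 3), hand-derived
  pt2 <- c(.5, .4, 0, .1, .8, .9)
  expect_equal(kendall_accuracy(pt2, stages, mode = "binned"),
               tau_b_bruteforce(c(2, 2, 1, 1, 3, 3), stages),
               tolerance = 1e-12)

  expect_error(kendall_accuracy(pt, rep(1, 6)), "constant")
  expect_error(kendall_accuracy(rep(0.5, 6), stages), "constant")
  expect_error(kendall_accuracy(pt, stages[-1]), "length")

  # factor stages use level order, not lexicographic order
  f <- factor(c("E10.5", "E10.5", "P6", "P6"), levels = c("E10.5", "P6"))
  expect_equal(kendall_accuracy(c(.1, .2, .8, .9), f),
               tau_b_bruteforce(c(.1, .2, .8, .9), c(1, 1, 2, 2)),
               tolerance = 1e-12)
  expect_gt(kendall_accuracy(c(.1, .2, .8, .9), f), 0.8)
  f_rev <- factor(c("E10.5", "E10.5", "P6", "P6"), levels = c("P6", "E10.5"))
  expect_lt(kendall_accuracy(c(.1, .2, .8, .9), f_rev), 0)
})

test_that("the subsampling robustness protocol is exact on identity resamples and stable on clean data", {
  sim <- simulate_branching(80, 20, "linear", noise_sd = 0, seed = 7)
  ident <- robustness_protocol(sim$X, fraction = 1, n_reps = 3, k = 8,
                               seed = 1)
  expect_equal(ident$mean, 1)
  expect_equal(ident$sd, 0)

  rb <- robustness_protocol(sim$X, fraction = 0.9, n_reps = 10, k = 8,
                            seed = 2)
  expect_gte(rb$mean, 0.99)
  expect_equal(length(rb$rho), 10L)

  # reproducible for a fixed seed
  rb2 <- robustness_protocol(sim$X, fraction = 0.9, n_reps = 10, k = 8,
                             seed = 2)
  expect_identical(rb$rho, rb2$rho)

  expect_error(robustness_protocol(sim$X, fraction = 0.05, n_reps = 2,
                                   k = 10), "smaller than k")
  expect_error(robustness_protocol(sim$X, fraction = 1.2), "fraction")
})
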