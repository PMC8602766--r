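#' Simulate a branching single-cell trajectory with known truth
#'
#' Generates cells on a latent lineage tree traversed at unit speed.
#' Each tree segment owns a disjoint subset of "program" genes with
#' non-negative loadings; a gene ramps linearly from baseline to its
#' plateau while the cell traverses the owning segment and stays saturated
#' afterwards, so expression varies smoothly and monotonically along every
#' lineage path and sibling arms diverge into different gene programs.
#' Per-segment loading vectors are scaled so that latent path length is
#' proportional to pseudotime (8 expression units from root to leaf),
#' making equally spaced cells on a noiseless linear topology exactly
#' equidistant.  Genes not owned by any segment are pure noise.  I.i.d.
#' Gaussian noise with standard deviation `noise_sd` is added to every
#' entry, emulating pre-processed (log-scale) expression.
#'
#' Topologies: `linear` (one segment), `bifurcating` (trunk for the first
#' half of pseudotime, then two arms), `trifurcating` (trunk then three
#' arms), `two_level` (trunk, a first split at t = 1/3, then one arm
#' splits again at t = 2/3: five segments, three terminal fates).
#' Each cell draws a terminal fate uniformly and a pseudotime
#' `t ~ U(0, 1)`; its segment is the one on the fate's path containing
#' `t`, so trunk cells always precede arm cells.
#'
#' @param n_cells number of cells (>= 10).
#' @param n_genes number of genes (>= 5).
#' @param topology one of `"linear"`, `"bifurcating"`, `"trifurcating"`,
#'   `"two_level"`.
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   expression units (default 0.2; root-to-leaf signal length is 8).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @param n_stages number of equal-width pseudotime bins exposed as
#'   ordinal stage labels on the returned matrix (default 6), emulating
#'   experimental stage annotations.
#' @return list with `X` (an [expression_matrix()] carrying stage labels)
#'   and `truth` (class `synthetic_truth`: `cell_id`,
#'   `true_pseudotime`, `true_branch` (segment name), `true_fate`,
#'   `stage`, plus `topology`, `segments`, `noise_sd`, `seed`).
#' @export
#' @examples
#' sim <- simulate_branching(60, 20, "bifurcating", noise_sd = 0.1, seed = 1)
#' table(sim$truth$true_branch)
simulate_branching <- function(n_cells, n_genes,
                               topology = c("linear", "bifurcating",
                                            "trifurcating", "two_level"),
                               noise_sd = 0.2, seed = NULL,
                               n_stages = 6L) {
  topology <- match.arg(topology)
  if (!is_count(n_cells) || n_cells < 10L) stop("n_cells must be >= 10")
  if (!is_count(n_genes) || n_genes < 5L) stop("n_genes must be >= 5")
  if (!(is.numeric(noise_sd) && length(noise_sd) == 1L && noise_sd >= 0))
    stop("noise_sd must be a non-negative number")

  segs <- topology_segments(topology)
  n_seg <- nrow(segs)
  if (n_genes < n_seg)
    stop("need at least ", n_seg, " genes for the ", topology, " topology")
  terminals <- segs$name[!(segs$name %in% segs$parent)]

  with_seed(seed, {
    fate <- sample(terminals, n_cells, replace = TRUE)
    t <- stats::runif(n_cells)
    # segment containing t on the fate's root path (t = 1 -> terminal)
    paths <- lapply(segs$name, function(s) seg_path(segs, s))
    names(paths) <- segs$name
    seg_of <- vapply(seq_len(n_cells), function(i) {
      on_path <- paths[[fate[i]]]
      hit <- on_path[segs[match(on_path, segs$name), "t0"] <= t[i] &
                     t[i] <= segs[match(on_path, segs$name), "t1"]]
      hit[length(hit)]
    }, character(1))

    # disjoint program-gene blocks, one per segment; the rest is noise
    per_seg <- max(1L, min(floor(0.7 * n_genes / n_seg),
                           floor(n_genes / n_seg)))
    gene_pool <- sample.int(n_genes)
    blocks <- split(gene_pool[seq_len(per_seg * n_seg)],
                    rep(seq_len(n_seg), each = per_seg))
    speed <- 8  # latent expression units per unit pseudotime
    loadings <- lapply(seq_len(n_seg), function(s) {
      u <- abs(stats::rnorm(per_seg)) + 0.2
      u / sqrt(sum(u^2)) * speed * (segs$t1[s] - segs$t0[s])
    })

    E <- matrix(0, n_cells, n_genes)
    for (s in seq_len(n_seg)) {
      on_path <- vapply(paths[fate], function(p) segs$name[s] %in% p,
                        logical(1))
      ramp <- pmin(pmax((t - segs$t0[s]) / (segs$t1[s] - segs$t0[s]), 0), 1)
      ramp[!on_path] <- 0
      E[, blocks[[s]]] <- E[, blocks[[s]]] +
        outer(ramp, loadings[[s]])
    }
    if (noise_sd > 0)
      E <- E + matrix(stats::rnorm(n_cells * n_genes, sd = noise_sd),
                      n_cells, n_genes)

    cell_ids <- sprintf("cell_%03d", seq_len(n_cells))
    gene_ids <- sprintf("gene_%03d", seq_len(n_genes))
    stage <- as.integer(cut(t, breaks = seq(0, 1, length.out = n_stages + 1),
                            include.lowest = TRUE))
    X <- expression_matrix(E, cell_ids, gene_ids,
                           stage_labels = factor(stage,
                                                 levels = seq_len(n_stages)))
    truth <- structure(
      list(cell_id = cell_ids, true_pseudotime = t, true_branch = seg_of,
           true_fate = fate, stage = stage, topology = topology,
           segments = segs, noise_sd = noise_sd, seed = seed),
      class = "synthetic_truth"
    )
    list(X = X, truth = truth)
  })
}

# segment tables: t0/t1 in pseudotime, parent = NA for the trunk
topology_segments <- function(topology) {
  switch(topology,
    linear = data.frame(name = "trunk", parent = NA_character_,
                        t0 = 0, t1 = 1, stringsAsFactors = FALSE),
    bifurcating = data.frame(
      name = c("trunk", "armA", "armB"),
      parent = c(NA, "trunk", "trunk"),
      t0 = c(0, 0.5, 0.5), t1 = c(0.5, 1, 1),
      stringsAsFactors = FALSE),
    trifurcating = data.frame(
      name = c("trunk", "armA", "armB", "armC"),
      parent = c(NA, "trunk", "trunk", "trunk"),
      t0 = c(0, 0.5, 0.5, 0.5), t1 = c(0.5, 1, 1, 1),
      stringsAsFactors = FALSE),
    two_level = data.frame(
      name = c("trunk", "armA", "armB", "armB1", "armB2"),
      parent = c(NA, "trunk", "trunk", "armB", "armB"),
      t0 = c(0, 1 / 3, 1 / 3, 2 / 3, 2 / 3),
      t1 = c(1 / 3, 1, 2 / 3, 1, 1),
      stringsAsFactors = FALSE),
    stop("unknown topology '", topology, "'")
  )
}

# root-to-segment path (vector of segment names, trunk first)
seg_path <- function(segs, name) {
  path <- name
  while (!is.na(segs$parent[match(path[1L], segs$name)]))
    path <- c(segs$parent[match(path[1L], segs$name)], path)
  path
}

#' Kendall rank accuracy of a pseudotime against ordinal stages
#'
#' Computes the tie-aware Kendall tau-b between inferred pseudotime and
#' the ordinal stage index.  In `"binned"` mode the inferred pseudotime
#' is first discretized into inferred stage numbers: cells are ranked by
#' pseudotime and assigned stage bins whose sizes match the observed
#' stage group sizes, then tau-b is computed between the two stage
#' numberings.
#'
#' @param pt a [compute_pseudotime()] result or numeric vector.
#' @param stages per-cell ordinal stage labels (factor: level order is
#'   the stage order; numeric used as-is).
#' @param mode `"direct"` (default) or `"binned"`.
#' @return Kendall tau-b (scalar in `[-1, 1]`).
#' @export
kendall_accuracy <- function(pt, stages, mode = c("direct", "binned")) {
  mode <- match.arg(mode)
  x <- as.numeric(pt)
  if (length(stages) != length(x))
    stop("pseudotime and stages have different lengths")
  s <- stage_index(stages)
  if (length(unique(s)) < 2L)
    stop("stages are constant; Kendall correlation is undefined")
  if (length(unique(x)) < 2L)
    stop("pseudotime is constant; Kendall correlation is undefined")
  if (mode == "binned") {
    sizes <- tabulate(match(s, sort(unique(s))))
    x <- inferred_stage(x, sizes)
  }
  unname(stats::cor(x, s, method = "kendall"))
}

stage_index <- function(stages) {
  if (is.numeric(stages)) return(as.numeric(stages))
  if (!is.factor(stages)) stages <- factor(stages, levels = unique(stages))
  as.numeric(stages)
}

# assign inferred stage numbers by pseudotime rank, matching the observed
# stage group sizes (ties in pseudotime broken by cell index)
inferred_stage <- function(x, sizes) {
  ord <- order(x, seq_along(x))
  out <- integer(length(x))
  out[ord] <- rep(seq_along(sizes), times = sizes)
  out
}

#' Subsampling robustness protocol
#'
#' Runs the full pseudotime pipeline on the complete dataset to obtain a
#' reference ordering, then repeatedly draws a random subsample of cells
#' without replacement, re-runs the pipeline on the subsample with the
#' same parameters, and reports the Spearman rank correlation between the
#' subsample pseudotime and the reference pseudotime restricted to the
#' sampled cells.  If the reference root is inside a subsample it is
#' reused; otherwise a root is re-selected on the subsample by the same
#' rule.
#'
#' @param X an [expression_matrix()].
#' @param fraction subsample fraction in `(0, 1]` (default 0.9).
#' @param n_reps number of repetitions (default 50).
#' @param k,p pipeline parameters (see [build_knn()], [rwr_stationary()]).
#' @param root_ids,R root selection, as in [select_roots()]; stage labels
#'   attached to `X` are used when present.
#' @param seed RNG seed for the subsampling.
#' @return list with `mean`, `sd` and the per-rep vector `rho`.
#' @export
robustness_protocol <- function(X, fraction = 0.9, n_reps = 50,
                                k = 10, p = 0.9, root_ids = NULL, R = 1,
                                seed = NULL) {
  stopifnot(inherits(X, "expression_matrix"))
  if (!(is.numeric(fraction) && length(fraction) == 1L &&
        fraction > 0 && fraction <= 1))
    stop("fraction must lie in (0, 1]")
  if (!is_count(n_reps) || n_reps < 1L) stop("n_reps must be >= 1")
  n <- nrow(X$values)
  m <- floor(fraction * n)
  if (m < k) stop("subsample of ", m, " cells is smaller than k = ", k)

  ref <- infer_pseudotime(X, k = k, p = p, root_ids = root_ids, R = R)
  ref_pt <- as.numeric(ref$pt)
  ref_root_ids <- X$cell_ids[attr(ref$pt, "roots")]

  rho <- with_seed(seed, {
    vapply(seq_len(n_reps), function(rep) {
      # the pipeline is undefined on a disconnected kNN graph, so a
      # subsample that happens to sever the graph is redrawn
      for (attempt in 1:100) {
        idx <- sort(sample.int(n, m))
        Xs <- expression_matrix(
          X$values[idx, , drop = FALSE],
          cell_ids = X$cell_ids[idx],
          stage_labels = if (is.null(X$stage_labels)) NULL else
            X$stage_labels[idx]
        )
        if (graph_components(build_knn(Xs, k))$n == 1L) break
        if (attempt == 100)
          stop("could not draw a connected subsample; increase k or ",
               "the fraction")
      }
      sub_roots <- intersect(ref_root_ids, Xs$cell_ids)
      sub <- infer_pseudotime(
        Xs, k = k, p = p,
        root_ids = if (length(sub_roots) > 0) sub_roots else NULL,
        R = R
      )
      stats::cor(as.numeric(sub$pt), ref_pt[idx], method = "spearman")
    }, numeric(1))
  })
  list(mean = mean(rho), sd = stats::sd(rho), rho = rho)
}

# knn -> affinity -> Markov -> RWR -> kernel -> distance -> pseudotime,
# without the embedding or branch steps (shared by the robustness
# protocol and run_pipeline)
infer_pseudotime <- function(X, k = 10, p = 0.9, root_ids = NULL, R = 1,
                             earliest = NULL) {
  if (!inherits(X, "expression_matrix")) X <- expression_matrix(X)
  g <- build_knn(X, k)
  comp <- graph_components(g)
  if (comp$n > 1L)
    stop("kNN graph has ", comp$n, " connected components; increase k")
  kern <- bhattacharyya_kernel(rwr_stationary(markov_matrix(
    gaussian_affinity(g)), p))
  Dk <- kernel_distance(kern)
  roots <- select_roots(Dk, labels = X$stage_labels, root_ids = root_ids,
                        R = R, earliest = earliest)
  list(graph = g, kernel = kern, dist = Dk, roots = roots,
       pt = compute_pseudotime(Dk, roots))
}
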