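#' Branch assignment by reverse search on the kNN graph
#'
#' Scans cells in decreasing pseudotime order and grows candidate groups
#' from their neighbour sets; a branch split is confirmed when one cell's
#' neighbourhood bridges two or more candidate groups that have each
#' already collected at least `n` members.  Concretely, for the current
#' cell's neighbour set:
#' \itemize{
#'   \item intersects exactly one candidate group: the neighbours are
#'     merged into it;
#'   \item intersects no candidate group: a new candidate group is opened
#'     from the not-yet-labelled neighbours;
#'   \item intersects two or more candidate groups: if at least two of
#'     them have `>= n` members each, those become determined branches
#'     (the scan cell is recorded as a bifurcation cell) and the
#'     remainder merges into one candidate group; otherwise everything
#'     merges into one candidate group.
#' }
#' A branch consumes the cells it was promoted with: they take no
#' further part in candidate-group formation, so the determination front
#' does not creep backwards along the trunk.  After the scan, leftover
#' candidate groups that touch through the symmetrized kNN graph are
#' merged; each merged component becomes a branch if it holds at least
#' `n` cells or is the lowest-pseudotime (trunk) component, while
#' smaller disconnected stragglers are assigned to the determined branch
#' with the closest member in kernel distance (with a warning).
#' Branches are finally relabeled by ascending minimum pseudotime, so
#' branch 1 is the initial (trunk) segment and every cell in it precedes
#' the cells of later branches.
#'
#' @param pt a [compute_pseudotime()] result (or numeric vector).
#' @param graph the [build_knn()] graph used by the pipeline.
#' @param n minimum number of cells required to form a sub-branch;
#'   defaults to `ceiling(N / 25)`.  Larger `n` merges small sub-branches
#'   (coarser trees), smaller `n` reveals finer splits.
#' @param dist a [kernel_distance()] result, used only to route
#'   stragglers to their nearest determined branch; may be omitted for
#'   topologies where no such assignment occurs.
#' @return An object of class `branch_assignment`: list with `branch_of`
#'   (named integer vector, labels `1..B`), `n_branches`,
#'   `bifurcation_cells` (scan cells that confirmed a split), `n`.
#' @export
detect_branches <- function(pt, graph, n = NULL, dist = NULL) {
  stopifnot(inherits(graph, "neighbor_graph"))
  tt <- as.numeric(pt)
  N <- graph$n_cells
  if (length(tt) != N) stop("pseudotime and graph cover different cells")
  if (is.null(n)) n <- ceiling(N / 25)
  if (!is_count(n) || n < 1L) stop("n must be a positive integer")
  if (n > N) stop("n = ", n, " exceeds the number of cells N = ", N)
  n <- as.integer(n)
  Dm <- if (is.null(dist)) NULL else dist$D

  # decreasing pseudotime; ties broken by descending cell index
  rseq <- order(-tt, -seq_len(N))

  founder_of <- integer(N)  # branch whose promotion consumed the cell
  label_of <- integer(N)    # final label (promotion or late assignment)
  group_of <- integer(N)    # 0 = in no candidate group
  groups <- list()          # candidate groups (index vectors)
  live <- logical(0)
  n_br <- 0L
  bifurcation <- integer(0)

  new_group <- function(cells) {
    if (length(cells) == 0L) return(invisible())
    groups[[length(groups) + 1L]] <<- cells
    live[length(groups)] <<- TRUE
    group_of[cells] <<- length(groups)
  }
  promote <- function(cells) {
    n_br <<- n_br + 1L
    founder_of[cells] <<- n_br
    label_of[cells] <<- n_br
    group_of[cells] <<- 0L
  }
  drop_groups <- function(gs) {
    for (g in gs) {
      groups[[g]] <<- integer(0)
      live[g] <<- FALSE
    }
  }
  # per-cell assignment to the branch with the closest founding member
  assign_nearest <- function(cells) {
    if (length(cells) == 0L) return(invisible())
    if (is.null(Dm))
      stop("late branch assignment requires the kernel distance matrix; ",
           "pass `dist`")
    members <- split(which(founder_of > 0), founder_of[founder_of > 0])
    labs <- as.integer(names(members))
    for (c0 in cells) {
      dmin <- vapply(members, function(m) min(Dm[c0, m]), numeric(1))
      label_of[c0] <<- labs[which.min(dmin)]
      group_of[c0] <<- 0L
    }
  }

  for (id in rseq) {
    nb <- graph$idx[id, ]
    nb_active <- nb[label_of[nb] == 0L]
    pg_hit <- unique(group_of[nb_active][group_of[nb_active] > 0L])

    if (length(pg_hit) == 0L) {
      # no candidate touched (cells consumed by branches are skipped):
      # the unlabelled neighbours seed a new candidate group
      new_group(unique(nb_active))
    } else if (length(pg_hit) == 1L) {
      g <- pg_hit
      groups[[g]] <- unique(c(groups[[g]], nb_active))
      group_of[groups[[g]]] <- g
    } else {
      sizes <- lengths(groups[pg_hit])
      big <- pg_hit[sizes >= n]
      if (length(big) >= 2L) {
        for (g in big) promote(groups[[g]])
        drop_groups(big)
        bifurcation <- c(bifurcation, id)
        rest <- setdiff(pg_hit, big)
        pool <- unique(c(unlist(groups[rest]),
                         nb_active[label_of[nb_active] == 0L]))
        drop_groups(rest)
        new_group(pool)
      } else {
        pool <- unique(c(unlist(groups[pg_hit]), nb_active))
        drop_groups(pg_hit)
        new_group(pool)
      }
    }
  }

  # close out leftover candidate groups: merge graph-connected ones; a
  # merged component becomes a branch if it is the only leftover (or when
  # no branch exists yet) or has >= n cells; stray smaller components are
  # routed to the nearest determined branch
  left <- which(live & lengths(groups) > 0)
  if (length(left) > 0L) {
    comps <- merge_connected(groups[left], graph)
    keep_all <- n_br == 0L
    sizes <- lengths(comps)
    if (length(comps) > 1L)
      warning(length(comps), " disconnected leftover groups after the ",
              "scan")
    # the lowest-pseudotime component is the trunk and always kept
    trunk_comp <- which.min(vapply(comps, function(cc) min(tt[cc]),
                                   numeric(1)))
    for (ci in seq_along(comps)) {
      if (ci == trunk_comp || keep_all || sizes[ci] >= n) {
        promote(comps[[ci]])
      } else {
        assign_nearest(comps[[ci]])
      }
    }
  }
  if (any(label_of == 0L))
    stop("internal error: unassigned cells after the reverse scan")

  # relabel by ascending minimum pseudotime: branch 1 = trunk
  tmin <- vapply(split(tt, label_of), min, numeric(1))
  old <- as.integer(names(tmin))
  newlab <- integer(max(old))
  newlab[old[order(tmin, old)]] <- seq_along(old)
  label_of <- newlab[label_of]
  names(label_of) <- graph$cell_ids

  structure(
    list(branch_of = label_of, n_branches = length(old),
         bifurcation_cells = bifurcation, n = n,
         cell_ids = graph$cell_ids),
    class = "branch_assignment"
  )
}

# union groups that touch through the symmetrized kNN graph; returns the
# merged components as a list of index vectors
merge_connected <- function(glist, graph) {
  gl <- length(glist)
  if (gl == 1L) return(glist)
  adj <- knn_adjacency(graph)
  parent <- seq_len(gl)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_len(gl - 1L)) for (b in seq(a + 1L, gl)) {
    if (any(adj[glist[[a]], glist[[b]]] > 0)) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  comp <- vapply(seq_len(gl), find, integer(1))
  lapply(unique(comp), function(u) unique(unlist(glist[comp == u])))
}

# dense 0/1 adjacency of the symmetrized kNN graph (self-loops removed)
knn_adjacency <- function(graph) {
  N <- graph$n_cells
  adj <- matrix(0L, N, N)
  for (i in seq_len(N)) adj[i, graph$idx[i, ]] <- 1L
  adj <- adj | t(adj)
  diag(adj) <- 0L
  adj
}

#' @export
print.branch_assignment <- function(x, ...) {
  cat("branch_assignment:", x$n_branches, "branch(es) over",
      length(x$branch_of), "cells (n =", x$n, ")\n")
  print(table(x$branch_of))
  invisible(x)
}

#' Per-branch summary table
#'
#' @param branches a [detect_branches()] result.
#' @param pt the matching [compute_pseudotime()] vector.
#' @return data.frame with one row per branch (ascending label): `branch`,
#'   `size`, `t_min`, `t_max`; bifurcation cell ids are attached as the
#'   `bifurcation_cells` attribute.
#' @export
branch_summary <- function(branches, pt) {
  stopifnot(inherits(branches, "branch_assignment"))
  tt <- as.numeric(pt)
  b <- branches$branch_of
  if (length(tt) != length(b))
    stop("pseudotime and branch assignment cover different cells")
  if (length(b) == 0L || branches$n_branches < 1L)
    stop("empty branch assignment")
  labs <- sort(unique(b))
  out <- data.frame(
    branch = labs,
    size = as.integer(tabulate(b, nbins = max(labs))[labs]),
    t_min = vapply(labs, function(l) min(tt[b == l]), numeric(1)),
    t_max = vapply(labs, function(l) max(tt[b == l]), numeric(1))
  )
  attr(out, "bifurcation_cells") <-
    branches$cell_ids[branches$bifurcation_cells]
  out
}
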