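#' Read an expression matrix from TSV/CSV or Matrix Market files
#'
#' Delimited files must have a header row of gene identifiers and a first
#' column of cell identifiers (cells in rows).  Matrix Market (`mtx`)
#' triplet files need companion plain-text identifier files (one id per
#' line); orientation is detected from the companion lengths and the
#' matrix is transposed to cells-by-genes if it arrives genes-by-cells.
#' Non-finite values are rejected with the offending cell named.
#'
#' @param path path to the matrix file.
#' @param format `"tsv"`, `"csv"` or `"mtx"`; default guessed from the
#'   file extension.
#' @param cells_file,genes_file companion identifier files (mtx only).
#' @param stage_labels optional per-cell stage labels to attach.
#' @param transpose set `TRUE` if a delimited file is genes-by-cells.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, format = NULL, cells_file = NULL,
                            genes_file = NULL, stage_labels = NULL,
                            transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     tsv = "tsv", txt = "tsv", csv = "csv", mtx = "mtx",
                     stop("cannot guess format of '", path,
                          "'; pass format="))
  }
  format <- match.arg(format, c("tsv", "csv", "mtx"))
  if (format == "mtx") {
    if (is.null(cells_file) || is.null(genes_file))
      stop("mtx input requires cells_file and genes_file companions")
    m <- as.matrix(Matrix::readMM(path))
    cells <- readLines(cells_file)
    genes <- readLines(genes_file)
    if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
      # cells x genes already
    } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
      m <- t(m)
    } else {
      stop("mtx dimensions ", nrow(m), " x ", ncol(m),
           " match neither companion file (", length(cells), " cells, ",
           length(genes), " genes)")
    }
    vals <- m
    cell_ids <- cells
    gene_ids <- genes
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            comment.char = "")
    if (ncol(df) < 2L) stop("malformed ", format, " file: ", path)
    cell_ids <- as.character(df[[1L]])
    vals <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(vals))
      stop("non-numeric expression values in ", path)
    gene_ids <- colnames(vals)
    if (transpose) {
      tmp <- cell_ids; cell_ids <- gene_ids; gene_ids <- tmp
      vals <- t(vals)
    }
  }
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-finite value for cell '", cell_ids[bad[1L, 1L]],
         "' (gene '", gene_ids[bad[1L, 2L]], "')")
  expression_matrix(vals, cell_ids, gene_ids, stage_labels = stage_labels)
}

# two-column (or more) TSV writers, 12 significant digits
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], fmtnum)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write pseudotime as a two-column TSV
#' @param pt a [compute_pseudotime()] result.
#' @param path output path.
#' @export
write_pseudotime <- function(pt, path) {
  write_tsv(data.frame(cell_id = names(pt),
                       pseudotime = as.numeric(pt)), path)
}

#' Write branch labels as a two-column TSV
#' @param branches a [detect_branches()] result.
#' @param path output path.
#' @export
write_branches <- function(branches, path) {
  write_tsv(data.frame(cell_id = names(branches$branch_of),
                       branch = unname(branches$branch_of)), path)
}

#' Run the full trajectory-inference pipeline
#'
#' Executes kNN graph construction, the adaptive Gaussian affinity and
#' Markov matrix, the random-walk-with-restart stationary operator, the
#' Bhattacharyya kernel, the spectral embedding, root selection,
#' pseudotime and branch detection, optionally writing all artifacts to
#' `out_dir` (`embedding.tsv`, `pseudotime.tsv`, `branches.tsv`,
#' `summary.tsv`, `config.json`, `run.log`).  The kNN graph must be
#' connected: the stationary distributions are strictly positive (and the
#' log-kernel finite) only on a connected graph.  By default a
#' disconnected graph aborts with guidance to increase `k`; with
#' `allow_components = TRUE` the largest component is analyzed and cells
#' outside it are reported as branch 0 with pseudotime NA.
#'
#' @param X an [expression_matrix()] (or path readable by
#'   [read_expression()]).
#' @param k neighbours, self included (default 10).
#' @param p walk-continuation probability (default 0.9).
#' @param d embedding dimension (default 2).
#' @param n minimum sub-branch size; default `ceiling(N / 25)`.
#' @param root_ids,root_label,R root selection: explicit ids, or the
#'   stage label whose cells are root candidates, or neither (global
#'   distance-sum rule); `R` roots are taken.
#' @param seed recorded in the config and used for any randomized step
#'   (the pipeline itself is deterministic).
#' @param out_dir optional output directory (created if needed).
#' @param allow_components analyze the largest component instead of
#'   failing on a disconnected graph.
#' @return list of class `trajectory_run` with `graph`, `kernel`,
#'   `embedding`, `dist`, `roots`, `pseudotime`, `branches`, `summary`,
#'   `config`.
#' @export
run_pipeline <- function(X, k = 10, p = 0.9, d = 2, n = NULL,
                         root_ids = NULL, root_label = NULL, R = 1,
                         seed = NULL, out_dir = NULL,
                         allow_components = FALSE) {
  if (is.character(X)) X <- read_expression(X)
  stopifnot(inherits(X, "expression_matrix"))
  N <- nrow(X$values)
  if (k > N) stop("k = ", k, " exceeds the number of cells N = ", N)
  if (is.null(n)) n <- ceiling(N / 25)

  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("cells N = ", N, ", genes D = ", ncol(X$values))
  note("parameters: k = ", k, ", p = ", p, ", d = ", d, ", n = ", n,
       ", R = ", R, if (!is.null(seed)) paste0(", seed = ", seed) else "")

  g_all <- build_knn(X, k)
  comp <- graph_components(g_all)
  note("kNN graph components: ", comp$n)
  excluded <- integer(0)
  if (comp$n > 1L) {
    if (!allow_components)
      stop("kNN graph has ", comp$n, " connected components; increase k ",
           "(or set allow_components = TRUE to analyze the largest ",
           "component)")
    main <- which.max(comp$sizes)
    keep <- which(comp$membership == main)
    excluded <- setdiff(seq_len(N), keep)
    warning(length(excluded), " cell(s) outside the largest component ",
            "are excluded (branch 0, pseudotime NA)")
    note(length(excluded), " cells excluded as disconnected")
    Xa <- expression_matrix(
      X$values[keep, , drop = FALSE], X$cell_ids[keep],
      X$gene_ids,
      stage_labels = if (is.null(X$stage_labels)) NULL else
        X$stage_labels[keep]
    )
  } else {
    keep <- seq_len(N)
    Xa <- X
  }

  g <- if (length(excluded) > 0L) build_knn(Xa, k) else g_all
  kern <- bhattacharyya_kernel(rwr_stationary(markov_matrix(
    gaussian_affinity(g)), p))
  emb <- embed_kernel(kern, d)
  Dk <- kernel_distance(kern)
  roots <- select_roots(
    Dk, labels = Xa$stage_labels,
    root_ids = root_ids, R = R, earliest = root_label
  )
  note("root cell(s): ", paste(names(roots), collapse = ", "))
  pt <- compute_pseudotime(Dk, roots)
  br <- detect_branches(pt, g, n = n, dist = Dk)
  note("branches: ", br$n_branches)
  summ <- branch_summary(br, pt)

  # re-expand to the full cell set when cells were excluded
  full_pt <- rep(NA_real_, N)
  full_pt[keep] <- as.numeric(pt)
  names(full_pt) <- X$cell_ids
  full_branch <- integer(N)
  full_branch[keep] <- br$branch_of
  names(full_branch) <- X$cell_ids

  config <- list(N = N, D = ncol(X$values), k = k, p = p, d = d, n = n,
                 R = R, root_ids = root_ids, root_label = root_label,
                 roots = names(roots), seed = seed,
                 allow_components = allow_components,
                 n_components = comp$n, n_branches = br$n_branches)

  res <- structure(
    list(graph = g, kernel = kern, embedding = emb, dist = Dk,
         roots = roots, pseudotime = pt, branches = br, summary = summ,
         full_pseudotime = full_pt, full_branch = full_branch,
         config = config, log = log_lines),
    class = "trajectory_run"
  )
  if (!is.null(out_dir)) write_run(res, X, out_dir)
  res
}

#' @export
print.trajectory_run <- function(x, ...) {
  cat("trajectory_run: N =", x$config$N, " k =", x$config$k,
      " p =", x$config$p, "\n")
  cat("root(s):", paste(names(x$roots), collapse = ", "),
      "; branches:", x$branches$n_branches, "\n")
  invisible(x)
}

write_run <- function(res, X, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emb <- as.data.frame(res$embedding$Y)
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  emb <- cbind(data.frame(cell_id = res$embedding$cell_ids), emb)
  write_tsv(emb, file.path(out_dir, "embedding.tsv"))
  write_tsv(data.frame(cell_id = names(res$full_pseudotime),
                       pseudotime = unname(res$full_pseudotime)),
            file.path(out_dir, "pseudotime.tsv"))
  write_tsv(data.frame(cell_id = names(res$full_branch),
                       branch = unname(res$full_branch)),
            file.path(out_dir, "branches.tsv"))
  write_tsv(res$summary, file.path(out_dir, "summary.tsv"))
  jsonlite::write_json(res$config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null",
                       digits = NA)
  writeLines(res$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
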