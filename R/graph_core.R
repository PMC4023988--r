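#' Construct a binary bipartite graph
#'
#' A bipartite (two-mode) graph links `n1` mode-1 nodes to `n2` mode-2 nodes.
#' Edges run only between modes and are binary: a pair is either tied or not.
#' Internally nodes are indexed 1..n1 and 1..n2; optional string labels are
#' kept per mode for I/O.
#'
#' @param edges two-column integer matrix (or data.frame) of edges; column 1
#'   holds mode-1 indices in 1..n1, column 2 mode-2 indices in 1..n2.
#' @param n1,n2 node counts of the two modes.
#' @param names1,names2 optional character labels per mode; defaults are
#'   `m1_<i>` / `m2_<j>`.
#' @return An object of class `bipartite_graph` with fields `n1`, `n2`,
#'   `edges` (deduplicated, ordered), `names1`, `names2`.
#' @examples
#' g <- bipartite_graph(cbind(c(1, 1, 2), c(1, 2, 2)), n1 = 2, n2 = 3)
#' g
#' @export
bipartite_graph <- function(edges, n1, n2, names1 = NULL, names2 = NULL) {
  n1 <- as.integer(n1)
  n2 <- as.integer(n2)
  if (length(n1) != 1L || length(n2) != 1L || is.na(n1) || is.na(n2) ||
      n1 < 1L || n2 < 1L) {
    stop("n1 and n2 must be positive integers")
  }
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) stop("edges must have two columns")
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("edges contain missing values")
  if (nrow(edges) > 0L &&
      (min(edges[, 1L]) < 1L || max(edges[, 1L]) > n1 ||
       min(edges[, 2L]) < 1L || max(edges[, 2L]) > n2)) {
    stop("edge endpoints out of range for the given mode sizes")
  }
  key <- (edges[, 1L] - 1) * as.double(n2) + edges[, 2L]
  if (anyDuplicated(key)) {
    edges <- edges[!duplicated(key), , drop = FALSE]
    key <- key[!duplicated(key)]
  }
  edges <- edges[order(key), , drop = FALSE]
  dimnames(edges) <- list(NULL, c("mode1", "mode2"))
  if (is.null(names1)) names1 <- paste0("m1_", seq_len(n1))
  if (is.null(names2)) names2 <- paste0("m2_", seq_len(n2))
  stopifnot(length(names1) == n1, length(names2) == n2)
  structure(
    list(n1 = n1, n2 = n2, edges = edges,
         names1 = as.character(names1), names2 = as.character(names2)),
    class = "bipartite_graph"
  )
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat(sprintf("Bipartite graph: %d x %d nodes, %d edges (density %.4g)\n",
              x$n1, x$n2, nrow(x$edges), graph_density(x)))
  invisible(x)
}

#' Number of edges of a bipartite graph
#' @param graph a `bipartite_graph`.
#' @return Integer edge count.
#' @export
n_edges <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  nrow(graph$edges)
}

#' Edge density of a bipartite graph
#'
#' The fraction of realized ties among the `n1 * n2` possible ones.
#' @param graph a `bipartite_graph`.
#' @return Density in `[0, 1]`.
#' @export
graph_density <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  nrow(graph$edges) / (as.double(graph$n1) * graph$n2)
}

#' Biadjacency matrix of a bipartite graph
#'
#' @param graph a `bipartite_graph`.
#' @param sparse return a sparse `Matrix` (default) or a dense base matrix.
#' @return The `n1 x n2` binary matrix `B` with `B[i, j] = 1` iff mode-1 node
#'   `i` is tied to mode-2 node `j`.
#' @examples
#' g <- bipartite_graph(cbind(c(1, 1, 2, 2), c(1, 2, 2, 3)), 2, 3)
#' biadjacency(g, sparse = FALSE)
#' @export
biadjacency <- function(graph, sparse = TRUE) {
  stopifnot(inherits(graph, "bipartite_graph"))
  B <- Matrix::sparseMatrix(
    i = graph$edges[, 1L], j = graph$edges[, 2L], x = 1,
    dims = c(graph$n1, graph$n2),
    dimnames = list(graph$names1, graph$names2)
  )
  if (sparse) B else as.matrix(B)
}

#' Build a bipartite graph from a biadjacency matrix
#'
#' @param B an `n1 x n2` binary matrix (base or `Matrix`); dimnames, if
#'   present, become node labels.
#' @return A `bipartite_graph`.
#' @export
as_bipartite <- function(B) {
  B <- methods::as(methods::as(Matrix::Matrix(B, sparse = TRUE), "dMatrix"),
                   "generalMatrix")
  if (!all(B@x %in% c(0, 1))) {
    stop("biadjacency entries must be 0 or 1 (binary bipartite graph)")
  }
  idx <- Matrix::which(B != 0, arr.ind = TRUE)
  bipartite_graph(idx, nrow(B), ncol(B),
                  names1 = rownames(B), names2 = colnames(B))
}

#' Read a bipartite edge list (TSV)
#'
#' Expects at least two tab-separated columns: mode-1 id, mode-2 id. Lines
#' starting with `#` are treated as comments/headers and skipped. Node ids may
#' be arbitrary strings; they are mapped to indices in stable sorted order so
#' the same file always yields the same graph. Duplicate rows are collapsed
#' with a warning.
#'
#' @param path file path.
#' @return A `bipartite_graph`.
#' @export
read_bipartite_edgelist <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty edge list: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed edge list row at line %d of %s (need 2 tab-separated columns)",
                 lineno[bad[1L]], path))
  }
  src <- vapply(parts, `[[`, "", 1L)
  dst <- vapply(parts, `[[`, "", 2L)
  names1 <- sort(unique(src))
  names2 <- sort(unique(dst))
  i <- match(src, names1)
  j <- match(dst, names2)
  if (anyDuplicated(cbind(i, j))) {
    warning("duplicate edges in ", path, " collapsed to single ties")
  }
  bipartite_graph(cbind(i, j), length(names1), length(names2),
                  names1 = names1, names2 = names2)
}

#' Write a bipartite edge list (TSV)
#'
#' Inverse of [read_bipartite_edgelist()]: one `source<TAB>target` row per
#' edge, a `#`-prefixed header line first.
#'
#' @param graph a `bipartite_graph`.
#' @param path output file path.
#' @export
write_bipartite_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "bipartite_graph"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#source\ttarget", con)
  if (nrow(graph$edges) > 0L) {
    writeLines(paste(graph$names1[graph$edges[, 1L]],
                     graph$names2[graph$edges[, 2L]], sep = "\t"), con)
  }
  invisible(path)
}

#' Read/write a biadjacency matrix
#'
#' Matrix Market (`format = "mtx"`) or dense CSV with row/column names
#' (`format = "csv"`).
#'
#' @param path file path.
#' @param format `"mtx"` or `"csv"`; default guessed from the file extension.
#' @return `read_biadjacency` returns a `bipartite_graph`.
#' @export
read_biadjacency <- function(path, format = c("auto", "mtx", "csv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  if (format == "mtx") {
    as_bipartite(Matrix::readMM(path))
  } else {
    m <- as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
    as_bipartite(m)
  }
}

#' @rdname read_biadjacency
#' @param graph a `bipartite_graph` to write.
#' @export
write_biadjacency <- function(graph, path, format = c("auto", "mtx", "csv")) {
  stopifnot(inherits(graph, "bipartite_graph"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "csv"
  }
  if (format == "mtx") {
    Matrix::writeMM(biadjacency(graph), path)
  } else {
    utils::write.csv(biadjacency(graph, sparse = FALSE), path)
  }
  invisible(path)
}

#' Construct a weighted one-mode graph
#'
#' A square symmetric non-negative weight matrix with zero diagonal, the
#' container for one-mode projections and the combined meta-matrix. Projection
#' diagonals (per-node membership counts) are dropped at construction: they
#' carry no between-node community information.
#'
#' @param weights square symmetric non-negative matrix (base or `Matrix`);
#'   any nonzero diagonal is an error.
#' @param mode_tag optional provenance tag: `"mode1-projection"`,
#'   `"mode2-projection"` or `"meta"`.
#' @return An object of class `weighted_graph` with fields `n`, `weights`
#'   (sparse symmetric), `mode_tag`.
#' @export
weighted_graph <- function(weights, mode_tag = NULL) {
  W <- methods::as(methods::as(Matrix::Matrix(weights, sparse = TRUE), "dMatrix"),
                   "generalMatrix")
  if (nrow(W) != ncol(W)) stop("weight matrix must be square")
  if (!Matrix::isSymmetric(W)) stop("weight matrix must be symmetric")
  if (any(W@x < 0)) stop("weights must be non-negative")
  if (any(Matrix::diag(W) != 0)) stop("weight matrix must have a zero diagonal")
  W <- Matrix::drop0(W)
  if (!is.null(mode_tag)) {
    mode_tag <- match.arg(mode_tag, c("mode1-projection", "mode2-projection", "meta"))
  }
  structure(list(n = nrow(W), weights = W, mode_tag = mode_tag),
            class = "weighted_graph")
}

#' @export
print.weighted_graph <- function(x, ...) {
  cat(sprintf("Weighted graph: %d nodes, %d edges, total weight %g%s\n",
              x$n, Matrix::nnzero(x$weights) / 2L,
              sum(x$weights) / 2,
              if (is.null(x$mode_tag)) "" else paste0(" [", x$mode_tag, "]")))
  invisible(x)
}

#' Construct a partition (community assignment)
#'
#' Each node carries exactly one community label; labels are canonicalized to
#' `1..k` in order of first appearance, so two partitions with the same
#' grouping compare equal regardless of the incoming label values.
#'
#' @param labels vector of community labels, one per node (any atomic type).
#' @return An integer vector of canonical labels with class `bicomm_partition`
#'   and attribute `k` (number of communities).
#' @examples
#' partition(c("b", "b", "a", "b"))  # -> 1 1 2 1, k = 2
#' @export
partition <- function(labels) {
  if (length(labels) == 0L) stop("partition must cover at least one node")
  if (anyNA(labels)) stop("partition labels must not be missing")
  lab <- match(labels, unique(labels))
  structure(as.integer(lab), k = max(lab), class = "bicomm_partition")
}

#' Number of communities of a partition
#' @param p a `bicomm_partition` (or raw label vector).
#' @return Integer community count.
#' @export
n_communities <- function(p) {
  if (inherits(p, "bicomm_partition")) attr(p, "k") else length(unique(p))
}

#' @export
print.bicomm_partition <- function(x, ...) {
  cat(sprintf("Partition of %d nodes into %d communities\n",
              length(x), n_communities(x)))
  sizes <- tabulate(unclass(x))
  cat("sizes:", paste(sizes, collapse = " "), "\n")
  invisible(x)
}

#' Write per-mode partitions to a TSV file
#'
#' Output columns are `node_id`, `mode` (1 or 2) and `community`, rows ordered
#' by mode then node index, so the file is deterministic for a given input.
#'
#' @param graph the `bipartite_graph` the partitions refer to (provides node
#'   labels and mode sizes).
#' @param p1,p2 community labels for mode-1 and mode-2 nodes (partitions or
#'   plain vectors covering all nodes of their mode).
#' @param path output file path.
#' @export
write_partition <- function(graph, p1, p2, path) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (length(p1) == 0L || length(p2) == 0L) stop("empty partition")
  if (length(p1) != graph$n1 || length(p2) != graph$n2) {
    stop("partitions must cover all nodes of both modes")
  }
  df <- data.frame(
    node_id = c(graph$names1, graph$names2),
    mode = rep(1:2, c(graph$n1, graph$n2)),
    community = c(as.integer(partition(p1)), as.integer(partition(p2)))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a partition TSV written by [write_partition()]
#'
#' @param path file path.
#' @return A list with elements `p1` and `p2`, the per-mode partitions (named
#'   by node id).
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "integer"))
  p1 <- partition(df$community[df$mode == 1L])
  names(p1) <- df$node_id[df$mode == 1L]
  p2 <- partition(df$community[df$mode == 2L])
  names(p2) <- df$node_id[df$mode == 2L]
  list(p1 = p1, p2 = p2)
}
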