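#' Weighted one-mode projection of a bipartite graph
#'
#' The mode-1 projection is `B %*% t(B)`: its off-diagonal entry (i, i')
#' counts the mode-2 neighbors shared by mode-1 nodes i and i' (e.g. how many
#' teams a pair of artists share). The mode-2 projection is `t(B) %*% B`. The
#' diagonal of these products counts each node's own memberships, not ties
#' between nodes, and is dropped.
#'
#' Projections are kept weighted (shared-neighbor counts), not dichotomized:
#' the weights are what carries community signal into one-mode detection.
#'
#' @param graph a `bipartite_graph`.
#' @param mode which mode to project onto: `1` or `2`.
#' @return A `weighted_graph` of size `n1` (mode 1) or `n2` (mode 2) with
#'   integer weights and tag `"mode1-projection"` / `"mode2-projection"`.
#' @examples
#' g <- bipartite_graph(cbind(c(1, 1, 2), c(1, 2, 2)), 2, 2)
#' project(g, 1)
#' @export
project <- function(graph, mode = 1L) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (!(length(mode) == 1L && mode %in% c(1, 2))) {
    stop("mode must be 1 or 2")
  }
  B <- biadjacency(graph)
  W <- if (mode == 1L) Matrix::tcrossprod(B) else Matrix::crossprod(B)
  W <- methods::as(methods::as(W, "dMatrix"), "generalMatrix")
  Matrix::diag(W) <- 0
  weighted_graph(Matrix::drop0(W),
                 mode_tag = if (mode == 1L) "mode1-projection" else "mode2-projection")
}

#' Block off-diagonal meta-matrix of a bipartite graph
#'
#' Stacks both modes into one `(n1 + n2)`-node graph whose adjacency holds `B`
#' in the upper-right block and `t(B)` in the lower-left, with zero
#' within-mode blocks. One-mode community detection on this graph partitions
#' both modes simultaneously (the "combined" strategy). Node order: mode-1
#' nodes first, then mode-2 nodes.
#'
#' @param graph a `bipartite_graph`.
#' @return A `weighted_graph` of size `n1 + n2` tagged `"meta"`.
#' @export
meta_matrix <- function(graph) {
  stopifnot(inherits(graph, "bipartite_graph"))
  B <- biadjacency(graph)
  Z1 <- Matrix::Matrix(0, graph$n1, graph$n1, sparse = TRUE)
  Z2 <- Matrix::Matrix(0, graph$n2, graph$n2, sparse = TRUE)
  M <- rbind(cbind(Z1, B), cbind(Matrix::t(B), Z2))
  dimnames(M) <- list(c(graph$names1, graph$names2),
                      c(graph$names1, graph$names2))
  weighted_graph(M, mode_tag = "meta")
}
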