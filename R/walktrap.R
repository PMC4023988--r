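#' Convert a weighted graph to an igraph object
#'
#' @param wg a `weighted_graph`.
#' @return An undirected `igraph` graph with edge attribute `weight`.
#' @export
as_igraph <- function(wg) {
  stopifnot(inherits(wg, "weighted_graph"))
  igraph::graph_from_adjacency_matrix(wg$weights, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Random-walk (walktrap) community detection
#'
#' Detects communities on a weighted one-mode graph with the walktrap
#' algorithm of Pons and Latapy: nodes are agglomeratively merged by the
#' similarity of their t-step random-walk distributions (transition
#' probabilities proportional to edge weights), and the dendrogram is cut at
#' the level of maximum Newman modularity. This is the single detection
#' backend used by both bipartite pipelines; `steps = 4` (short walks)
#' throughout unless overridden.
#'
#' Isolated nodes, which a random walk can never leave, become singleton
#' communities. The result is deterministic for a fixed input graph.
#'
#' @param wg a `weighted_graph` with at least one node.
#' @param steps random-walk length t; default 4.
#' @return A `bicomm_partition` over the nodes of `wg`, labels canonicalized
#'   by first appearance.
#' @examples
#' tri2 <- matrix(0, 6, 6)
#' tri2[cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))] <- 1
#' tri2 <- tri2 + t(tri2); tri2[tri2 > 0] <- 1
#' walktrap_communities(weighted_graph(tri2))  # the two triangles
#' @export
walktrap_communities <- function(wg, steps = 4L) {
  stopifnot(inherits(wg, "weighted_graph"))
  if (wg$n < 1L) stop("graph must have at least one node")
  steps <- as.integer(steps)
  if (is.na(steps) || steps < 1L) stop("steps must be a positive integer")
  if (Matrix::nnzero(wg$weights) == 0L) {
    return(partition(seq_len(wg$n)))
  }
  ig <- as_igraph(wg)
  cl <- igraph::cluster_walktrap(ig, weights = igraph::E(ig)$weight,
                                 steps = steps)
  partition(igraph::membership(cl))
}

#' Newman modularity of a partition on a weighted graph
#'
#' `Q = sum_c (w_c / W - (s_c / 2W)^2)` where, for community c, `w_c` is the
#' within-community edge weight, `s_c` the summed weighted degree and `W` the
#' total edge weight. Q is 0 for the all-in-one partition and at most 1;
#' larger is better.
#'
#' @param wg a `weighted_graph`.
#' @param p partition covering all nodes of `wg`.
#' @return Modularity score in `[-1, 1]`.
#' @export
modularity_score <- function(wg, p) {
  stopifnot(inherits(wg, "weighted_graph"))
  if (length(p) != wg$n) stop("partition must cover all nodes of the graph")
  ig <- as_igraph(wg)
  igraph::modularity(ig, as.integer(partition(p)),
                     weights = igraph::E(ig)$weight)
}
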