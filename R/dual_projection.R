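#' @keywords internal
new_joint_partition <- function(graph, p1, p2, joint1, joint2, method) {
  jall <- partition(c(joint1, joint2))
  joint1 <- as.integer(jall[seq_len(graph$n1)])
  joint2 <- as.integer(jall[graph$n1 + seq_len(graph$n2)])
  matching <- unique(rbind(
    data.frame(mode = 1L, community = as.integer(p1), joint = joint1),
    data.frame(mode = 2L, community = as.integer(p2), joint = joint2)
  ))
  matching <- matching[order(matching$mode, matching$community), ]
  rownames(matching) <- NULL
  structure(
    list(partition1 = p1, partition2 = p2,
         joint1 = joint1, joint2 = joint2,
         matching = matching,
         barber_q = barber_modularity(graph, joint1, joint2),
         method = method),
    class = "joint_partition"
  )
}

#' @export
print.joint_partition <- function(x, ...) {
  cat(sprintf(
    "Joint bipartite partition (%s): %d mode-1 x %d mode-2 communities, %d joint; Q_B = %.4f\n",
    x$method, n_communities(x$partition1), n_communities(x$partition2),
    length(unique(c(x$joint1, x$joint2))), x$barber_q))
  invisible(x)
}

#' Barber bipartite modularity
#'
#' The bipartite analogue of Newman's Q:
#' `Q_B = (1/m) * sum_{i,j} (B_ij - k_i d_j / m) * delta(c_i, c_j)`
#' over all mode-1 x mode-2 node pairs, where `m` is the edge count, `k_i`
#' and `d_j` the mode-1 and mode-2 degrees, and `c` the joint community
#' labels. The null term `k_i d_j / m` is the expected tie weight under a
#' degree-preserving random bipartite graph, so Q_B measures the excess of
#' within-community ties over chance; it is 0 for the all-in-one assignment
#' and lies in `[-1, 1]`.
#'
#' @param graph a `bipartite_graph` with at least one edge.
#' @param joint1 joint community labels of the mode-1 nodes.
#' @param joint2 joint community labels of the mode-2 nodes (same label space;
#'   the delta only fires when labels agree across modes).
#' @return Barber modularity `Q_B` in `[-1, 1]`.
#' @examples
#' # two complete 2x2 blocks on the diagonal, matched block-wise: Q_B = 0.5
#' B <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
#' g <- as_bipartite(B)
#' barber_modularity(g, c(1, 1, 2, 2), c(1, 1, 2, 2))
#' @export
barber_modularity <- function(graph, joint1, joint2) {
  stopifnot(inherits(graph, "bipartite_graph"))
  m <- nrow(graph$edges)
  if (m == 0L) stop("Barber modularity is undefined for an edgeless graph")
  if (length(joint1) != graph$n1 || length(joint2) != graph$n2) {
    stop("joint labels must cover all nodes of both modes")
  }
  lab <- match(c(joint1, joint2), unique(c(joint1, joint2)))
  c1 <- lab[seq_len(graph$n1)]
  c2 <- lab[graph$n1 + seq_len(graph$n2)]
  nc <- max(lab)
  k <- tabulate(graph$edges[, 1L], graph$n1)   # mode-1 degrees
  d <- tabulate(graph$edges[, 2L], graph$n2)   # mode-2 degrees
  within <- c1[graph$edges[, 1L]] == c2[graph$edges[, 2L]]
  E_c <- tabulate(c1[graph$edges[, 1L]][within], nc)
  K_c <- vapply(seq_len(nc), function(cc) sum(k[c1 == cc]), 0)
  D_c <- vapply(seq_len(nc), function(cc) sum(d[c2 == cc]), 0)
  sum(E_c - K_c * D_c / m) / m
}

#' Match per-mode community partitions across modes
#'
#' Given independent community partitions of the two modes, finds the
#' cross-mode matching that maximizes Barber modularity [barber_modularity()]
#' of the resulting joint labeling: each community of the mode with fewer
#' communities is either assigned the joint label of one community of the
#' other mode (many-to-one allowed) or left unmatched with its own joint
#' label.
#'
#' Over this search space Q_B decomposes into independent per-community
#' contributions (the delta in Q_B only fires across modes), so the optimum
#' is found exactly by taking, for each community of the smaller mode, the
#' partner with the largest non-negative Q_B gain
#' `(E_ab - K_a D_b / m) / m`, where `E_ab` is the edge count between the
#' two communities and `K_a`, `D_b` their degree sums.
#'
#' @param graph a `bipartite_graph` with at least one edge.
#' @param p1 partition of the mode-1 nodes.
#' @param p2 partition of the mode-2 nodes.
#' @return A `joint_partition` holding both per-mode partitions, the joint
#'   labels, the matching table and its Barber modularity.
#' @export
combine_partitions <- function(graph, p1, p2) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (length(p1) == 0L || length(p2) == 0L) stop("empty partition")
  if (length(p1) != graph$n1 || length(p2) != graph$n2) {
    stop("partitions must cover all nodes of their modes")
  }
  m <- nrow(graph$edges)
  if (m == 0L) stop("cannot combine partitions of an edgeless graph")
  p1 <- partition(p1)
  p2 <- partition(p2)
  k1 <- n_communities(p1)
  k2 <- n_communities(p2)
  k <- tabulate(graph$edges[, 1L], graph$n1)
  d <- tabulate(graph$edges[, 2L], graph$n2)
  # community-level sufficient statistics
  E <- matrix(0, k1, k2)
  tab <- table(factor(p1[graph$edges[, 1L]], levels = seq_len(k1)),
               factor(p2[graph$edges[, 2L]], levels = seq_len(k2)))
  E[] <- as.numeric(tab)
  K <- vapply(seq_len(k1), function(a) sum(k[p1 == a]), 0)
  D <- vapply(seq_len(k2), function(b) sum(d[p2 == b]), 0)
  gain <- (E - outer(K, D) / m) / m        # Q_B contribution of matching a with b
  if (k2 <= k1) {
    # map mode-2 communities onto mode-1 joint labels
    joint1 <- as.integer(p1)
    best <- apply(gain, 2L, which.max)
    matched <- gain[cbind(best, seq_len(k2))] >= 0
    lab2 <- ifelse(matched, best, k1 + seq_len(k2))
    joint2 <- lab2[as.integer(p2)]
  } else {
    joint2 <- as.integer(p2)
    best <- apply(gain, 1L, which.max)
    matched <- gain[cbind(seq_len(k1), best)] >= 0
    lab1 <- ifelse(matched, best, k2 + seq_len(k1))
    joint1 <- lab1[as.integer(p1)]
  }
  new_joint_partition(graph, p1, p2, joint1, joint2, method = "dual")
}

#' Dual-projection community detection
#'
#' The two-mode pipeline advocated by this package: run walktrap on the
#' weighted projection of each mode separately, then match the two community
#' solutions across modes so as to maximize Barber modularity. Detection in
#' one mode is thereby never distorted by the structure of the other.
#'
#' @param graph a `bipartite_graph` with at least one edge.
#' @param steps walktrap random-walk length; default 4.
#' @return A `joint_partition` (method `"dual"`).
#' @seealso [detect_combined()] for the baseline meta-matrix strategy.
#' @export
detect_dual <- function(graph, steps = 4L) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (nrow(graph$edges) == 0L) stop("graph has no edges")
  p1 <- walktrap_communities(project(graph, 1L), steps = steps)
  p2 <- walktrap_communities(project(graph, 2L), steps = steps)
  combine_partitions(graph, p1, p2)
}

#' Combined (meta-matrix) community detection
#'
#' The baseline strategy: run walktrap once on the block off-diagonal
#' meta-matrix stacking both modes, then split the single partition by mode.
#' Communities spanning both modes keep a shared joint label, so the
#' cross-mode matching is induced by the one-mode solution rather than
#' searched.
#'
#' @param graph a `bipartite_graph` with at least one edge.
#' @param steps walktrap random-walk length; default 4.
#' @return A `joint_partition` (method `"combined"`).
#' @export
detect_combined <- function(graph, steps = 4L) {
  stopifnot(inherits(graph, "bipartite_graph"))
  if (nrow(graph$edges) == 0L) stop("graph has no edges")
  memb <- walktrap_communities(meta_matrix(graph), steps = steps)
  joint1 <- as.integer(memb[seq_len(graph$n1)])
  joint2 <- as.integer(memb[graph$n1 + seq_len(graph$n2)])
  new_joint_partition(graph, partition(joint1), partition(joint2),
                      joint1, joint2, method = "combined")
}
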