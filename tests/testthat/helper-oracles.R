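# Independent oracles used across the test files. These deliberately avoid
# the package's own code paths (and igraph) so they can serve as a second
# route to the same quantities.

# All set partitions of n items as a list of label vectors (restricted
# growth strings). Bell(8) = 4140, so exhaustive checks up to n = 8 are cheap.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(labels, next_label) {
    i <- length(labels) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(next_label)) {
      recurse(c(labels, lab), max(next_label, lab + 1L))
    }
  }
  recurse(integer(0), 1L)
  out
}

# Newman modularity straight from the formula, from a dense weight matrix.
modularity_oracle <- function(W, labels) {
  W <- as.matrix(W)
  tw <- sum(W)                 # 2 * total edge weight
  if (tw == 0) return(0)
  deg <- rowSums(W)
  q <- 0
  for (cc in unique(labels)) {
    idx <- labels == cc
    q <- q + sum(W[idx, idx]) / tw - (sum(deg[idx]) / tw)^2
  }
  q
}

# Global modularity optimum by brute-force enumeration (n <= 8).
brute_force_best_partition <- function(W) {
  parts <- enumerate_partitions(nrow(as.matrix(W)))
  qs <- vapply(parts, function(p) modularity_oracle(W, p), 0)
  best <- which.max(qs)
  list(labels = parts[[best]], q = qs[best])
}

# Barber bipartite modularity as a literal double loop over all cross-mode
# node pairs.
barber_oracle <- function(graph, joint1, joint2) {
  B <- unname(as.matrix(biadjacency(graph)))
  m <- sum(B)
  k <- rowSums(B)
  d <- colSums(B)
  q <- 0
  for (i in seq_len(nrow(B))) {
    for (j in seq_len(ncol(B))) {
      if (joint1[i] == joint2[j]) {
        q <- q + B[i, j] - k[i] * d[j] / m
      }
    }
  }
  q / m
}

# Best cross-mode matching by brute force: every map from the smaller mode's
# community labels to (larger mode's labels + "unmatched"), scored with the
# double-loop oracle.
combine_oracle <- function(graph, p1, p2) {
  p1 <- partition(p1)
  p2 <- partition(p2)
  k1 <- n_communities(p1)
  k2 <- n_communities(p2)
  small_is_2 <- k2 <= k1
  ks <- min(k1, k2)
  kl <- max(k1, k2)
  options <- c(seq_len(kl), 0L)   # 0 = unmatched
  grids <- do.call(expand.grid, rep(list(options), ks))
  best_q <- -Inf
  for (r in seq_len(nrow(grids))) {
    map <- as.integer(grids[r, ])
    map[map == 0L] <- kl + which(map == 0L)   # own joint label
    if (small_is_2) {
      j1 <- as.integer(p1)
      j2 <- map[as.integer(p2)]
    } else {
      j2 <- as.integer(p2)
      j1 <- map[as.integer(p1)]
    }
    q <- barber_oracle(graph, j1, j2)
    if (q > best_q) best_q <- q
  }
  best_q
}

# NMI via the entropy identity I = H(a) + H(b) - H(a, b), a different route
# than the package's direct sum over contingency cells.
nmi_oracle <- function(a, b) {
  n <- length(a)
  ent <- function(x) {
    p <- table(x) / n
    -sum(p * log(p))
  }
  Ha <- ent(a)
  Hb <- ent(b)
  if (Ha == 0 && Hb == 0) return(1)
  if (Ha == 0 || Hb == 0) return(0)
  Hab <- ent(paste(a, b, sep = "\r"))
  (Ha + Hb - Hab) / sqrt(Ha * Hb)
}

# Random Bernoulli bipartite graph (possibly with isolated nodes).
random_bipartite <- function(n1, n2, p = 0.3) {
  B <- matrix(stats::rbinom(n1 * n2, 1, p), n1, n2)
  bipartite_graph(which(B == 1, arr.ind = TRUE), n1, n2)
}

# Random symmetric non-negative integer weight matrix with zero diagonal.
random_weighted <- function(n, p = 0.5, max_w = 3L) {
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (stats::runif(1) < p) {
        W[i, j] <- W[j, i] <- sample.int(max_w, 1L)
      }
    }
  }
  W
}
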