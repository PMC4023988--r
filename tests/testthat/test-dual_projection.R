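# block-diagonal bipartite graph: two complete 2x2 blocks
two_block_graph <- function() {
  as_bipartite(rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1)))
}

test_that("Barber modularity matches hand-computed block values", {
  g <- two_block_graph()
  # m = 8; each of the 8 within pairs contributes (1 - 2*2/8)/8
  expect_equal(barber_modularity(g, c(1, 1, 2, 2), c(1, 1, 2, 2)), 0.5)
  expect_equal(barber_modularity(g, rep(1, 4), rep(1, 4)), 0)
  expect_error(barber_modularity(g, c(1, 1), c(1, 1, 2, 2)), "cover")
  empty <- bipartite_graph(matrix(integer(0), ncol = 2), 2, 2)
  expect_error(barber_modularity(empty, 1:2, 1:2), "edgeless")
})

test_that("Barber modularity equals the double-loop oracle on random graphs", {
  set.seed(41)
  for (i in 1:20) {
    g <- random_bipartite(sample(3:12, 1), sample(3:12, 1), 0.4)
    if (n_edges(g) == 0) next
    j1 <- sample.int(3, g$n1, replace = TRUE)
    j2 <- sample.int(3, g$n2, replace = TRUE)
    q <- barber_modularity(g, j1, j2)
    expect_equal(q, barber_oracle(g, j1, j2), tolerance = 1e-12)
    expect_gte(q, -1)
    expect_lte(q, 1)
  }
})

test_that("combine_partitions pairs block-aligned communities", {
  g <- two_block_graph()
  jp <- combine_partitions(g, c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(jp$barber_q, 0.5)
  expect_equal(jp$joint1, jp$joint2)          # blocks matched across modes
  expect_equal(length(unique(jp$joint1)), 2L)
  # trivial case: one community per mode collapses to one joint community
  jp1 <- combine_partitions(g, rep(1, 4), rep(1, 4))
  expect_equal(jp1$barber_q, 0)
  expect_equal(length(unique(c(jp1$joint1, jp1$joint2))), 1L)
  expect_error(combine_partitions(g, numeric(0), rep(1, 4)), "empty|cover")
})

test_that("matching is optimal against brute-force enumeration", {
  set.seed(53)
  for (i in 1:12) {
    g <- random_bipartite(sample(4:8, 1), sample(4:8, 1), 0.5)
    if (n_edges(g) == 0) next
    p1 <- sample.int(sample(2:4, 1), g$n1, replace = TRUE)
    p2 <- sample.int(sample(2:4, 1), g$n2, replace = TRUE)
    jp <- combine_partitions(g, p1, p2)
    expect_equal(jp$barber_q, combine_oracle(g, p1, p2), tolerance = 1e-12)
    # never below the no-matching baseline
    n1 <- g$n1
    baseline <- barber_modularity(g, partition(p1),
                                  max(partition(p1)) + as.integer(partition(p2)))
    expect_gte(jp$barber_q, baseline - 1e-12)
  }
})

test_that("the 3/2 overlap structure matches a mode-2 half under the optimum", {
  # three mode-1 communities, two mode-2 halves: the middle community must
  # share a joint label with whichever half scores higher; joint label count
  # is max(k1, k2) = 3
  set.seed(61)
  cfg <- scenario_config("unequal_3_2", "small", seed = 61)
  gen <- generate_bipartite(cfg)
  jp <- combine_partitions(gen$graph, gen$truth$labels1, gen$truth$labels2)
  expect_equal(length(unique(c(jp$joint1, jp$joint2))), 3L)
  expect_equal(jp$barber_q,
               combine_oracle(gen$graph, gen$truth$labels1, gen$truth$labels2),
               tolerance = 1e-12)
})

test_that("both pipelines recover a planted block-diagonal structure", {
  g <- two_block_graph()
  jd <- detect_dual(g)
  expect_equal(nmi(c(1, 1, 2, 2), jd$partition1), 1)
  expect_equal(nmi(c(1, 1, 2, 2), jd$partition2), 1)
  expect_equal(jd$barber_q, 0.5)
  jc <- detect_combined(g)
  expect_equal(nmi(c(1, 1, 2, 2), jc$partition1), 1)
  expect_equal(nmi(c(1, 1, 2, 2), jc$partition2), 1)
  # combined solution attains the brute-force optimum of the 8-node meta graph
  M <- as.matrix(meta_matrix(g)$weights)
  best <- brute_force_best_partition(M)
  expect_equal(modularity_score(meta_matrix(g), c(jc$joint1, jc$joint2)),
               best$q, tolerance = 1e-12)
})

test_that("degenerate and invalid graphs are handled", {
  single <- bipartite_graph(cbind(1, 1), 1, 1)
  jd <- detect_dual(single)
  expect_equal(length(unique(c(jd$joint1, jd$joint2))), 1L)
  empty <- bipartite_graph(matrix(integer(0), ncol = 2), 2, 2)
  expect_error(detect_dual(empty), "no edges")
  expect_error(detect_combined(empty), "no edges")
})

test_that("detection is deterministic for a fixed graph", {
  set.seed(71)
  g <- random_bipartite(12, 18, 0.3)
  expect_identical(detect_dual(g)$joint1, detect_dual(g)$joint1)
  expect_identical(detect_combined(g)$joint2, detect_combined(g)$joint2)
})
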