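test_that("fixed mode-1 degrees give the exact configured density", {
  cfg <- scenario_config("equal_3_3", "small", seed = 2)
  gen <- generate_bipartite(cfg)
  B <- as.matrix(biadjacency(gen$graph))
  expect_true(all(rowSums(B) == 15))     # round(0.125 * 120)
  expect_equal(n_edges(gen$graph), 900L)
  expect_equal(graph_density(gen$graph), 0.125)
})

test_that("generation is reproducible from the seed", {
  cfg <- scenario_config("unequal_3_2", "small", seed = 99)
  g1 <- generate_bipartite(cfg)$graph
  g2 <- generate_bipartite(cfg)$graph
  expect_identical(g1$edges, g2$edges)
  cfg$seed <- 100
  g3 <- generate_bipartite(cfg)$graph
  expect_false(identical(g1$edges, g3$edges))
})

test_that("scenario configs validate divisibility and degree bounds", {
  expect_error(scenario_config("equal_3_3", n1 = 61, n2 = 120, density = 0.125),
               "divisible by 3")
  expect_error(scenario_config("equal_3_3", n1 = 60, n2 = 121, density = 0.125),
               "divisible by 6")
  expect_error(scenario_config("unequal_2_10", n1 = 61, n2 = 120, density = 0.125),
               "divisible by 20")
  expect_error(scenario_config("unequal_2_10", n1 = 60, n2 = 121, density = 0.125),
               "divisible by 30")
  expect_error(scenario_config("equal_3_3", n1 = 60, n2 = 120, density = 0.00001),
               "degree")
})

test_that("planted community counts follow the scenario", {
  for (sc in c("equal_3_3", "unequal_3_2", "unequal_2_10")) {
    lay <- scenario_regions(scenario_config(sc, "small"))
    k1 <- n_communities(lay$labels1)
    k2 <- n_communities(lay$labels2)
    expect_equal(c(k1, k2), switch(sc,
      equal_3_3 = c(3L, 3L), unequal_3_2 = c(3L, 2L), unequal_2_10 = c(2L, 10L)))
  }
})

test_that("the 2/10 layout never bridges the two mode-2 halves", {
  for (size in c("small", "large")) {
    cfg <- scenario_config("unequal_2_10", size)
    lay <- scenario_regions(cfg)
    half1 <- seq_len(cfg$n2 %/% 2L)
    for (s in seq_along(lay$regions)) {
      r <- lay$regions[[s]]
      crosses <- any(r %in% half1) && any(!(r %in% half1))
      expect_false(crosses)
      # mode-1 halves only touch their own mode-2 half
      expect_equal(all(r %in% half1), s <= 10L)
    }
  }
})

test_that("within-region ties occur with probability 0.9 (binomial check)", {
  # pooled over replicates; only scenarios whose regions never saturate
  for (sc in c("equal_3_3", "unequal_3_2")) {
    within <- 0
    total <- 0
    for (r in 1:5) {
      cfg <- scenario_config(sc, "small", seed = 300 + r)
      gen <- generate_bipartite(cfg)
      lay <- scenario_regions(cfg)
      e <- gen$graph$edges
      inside <- vapply(seq_len(nrow(e)), function(i) {
        e[i, 2] %in% lay$regions[[lay$subsection[e[i, 1]]]]
      }, TRUE)
      within <- within + sum(inside)
      total <- total + nrow(e)
    }
    frac <- within / total
    tol <- 3 * sqrt(0.9 * 0.1 / total)
    expect_lt(abs(frac - 0.9), tol)
  }
})

test_that("saturated regions spill with a classed warning", {
  cfg <- scenario_config("unequal_2_10", "small", seed = 4)
  expect_warning(generate_bipartite(cfg), class = "bicomm_spill")
  # degrees stay exact despite the spill
  gen <- suppressWarnings(generate_bipartite(cfg))
  expect_true(all(rowSums(as.matrix(biadjacency(gen$graph))) == 15))
})

test_that("the pure limit p_within = 1 is recovered exactly by both pipelines", {
  cfg <- scenario_config("equal_3_3", "small", p_within = 1, seed = 8)
  gen <- generate_bipartite(cfg)
  lay <- scenario_regions(cfg)
  e <- gen$graph$edges
  inside <- vapply(seq_len(nrow(e)), function(i) {
    e[i, 2] %in% lay$regions[[lay$subsection[e[i, 1]]]]
  }, TRUE)
  expect_true(all(inside))
  expect_equal(score_joint(gen$truth, detect_dual(gen$graph)), 1)
  expect_equal(score_joint(gen$truth, detect_combined(gen$graph)), 1)
})

test_that("the 3/2 design's efficient mode-2 description is the half-split", {
  # the three designated regions (first half, middle third, second half)
  # overlap; the non-overlapping partition of mode 2 that one-mode detection
  # on the projection settles on is the two halves, which is exactly the
  # planted labels2
  for (r in 1:3) {
    cfg <- scenario_config("unequal_3_2", "small", seed = 400 + r)
    gen <- generate_bipartite(cfg)
    p2 <- walktrap_communities(project(gen$graph, 2))
    expect_equal(n_communities(p2), 2L)
    n2 <- cfg$n2
    halves <- rep(1:2, each = n2 / 2)
    thirds <- rep(1:3, each = n2 / 3)
    expect_gt(nmi(halves, p2), nmi(thirds, p2))
  }
})
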