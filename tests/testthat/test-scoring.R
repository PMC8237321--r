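test_that("Table-style cluster scores match hand evaluation on the unit triangle", {
  g <- make_fixture("triangle", weights = c(1, 1, 1))
  agg <- cluster_aggregates(g, c(a = 1, b = 1, c = 2))
  expect_equal(score_cluster(g, agg, 1, "conductance"), 0.5)
  expect_equal(score_cluster(g, agg, 1, "expansion"), 1)
  expect_equal(score_cluster(g, agg, 1, "cut_ratio"), 1)
  expect_equal(score_cluster(g, agg, 1, "internal_density"), 1)
  expect_equal(score_cluster(g, agg, 1, "average_degree"), 1)
  # singleton cluster: internal density undefined
  expect_true(is.nan(score_cluster(g, agg, 2, "internal_density")))
})

test_that("the whole-graph cluster has zero external-connectivity scores", {
  set.seed(31)
  g <- random_weighted_graph(10)
  agg <- cluster_aggregates(g, rep(1, 10))
  for (sc in c("conductance", "expansion", "cut_ratio", "normalized_cut",
               "max_odf", "avg_odf")) {
    expect_equal(score_cluster(g, agg, 1, sc), 0, info = sc)
  }
})

test_that("scores on binary graphs equal their unweighted formulas", {
  set.seed(32)
  g <- make_fixture("binary_random", n = 16, p = 0.35)
  p <- random_partition(16, 3)
  agg <- cluster_aggregates(g, p)
  cl <- agg$clusters
  for (S in cl$cluster) {
    r <- cl[S, ]
    expect_equal(score_cluster(g, agg, S, "edges_inside"), r$m_S)
    if (r$n_S > 1) {
      expect_equal(score_cluster(g, agg, S, "internal_density"),
                   r$m_S / (r$n_S * (r$n_S - 1) / 2))
    }
    if (2 * r$m_S + r$c_S > 0) {
      expect_equal(score_cluster(g, agg, S, "conductance"),
                   r$c_S / (2 * r$m_S + r$c_S))
    }
  }
})

test_that("uniform weight scaling leaves invariant scores fixed and scales linear ones", {
  set.seed(33)
  specs <- score_specs()
  for (i in 1:8) {
    g <- random_weighted_graph(12, p = 0.5)
    p <- random_partition(12, 3)
    phi <- runif(1, 0.1, 10)
    g2 <- scale_graph_weights(g, phi)
    for (j in seq_len(nrow(specs))) {
      v1 <- score_partition(g, p, specs$score[j])$value
      v2 <- score_partition(g2, p, specs$score[j])$value
      if (is.nan(v1)) next
      if (specs$scale_class[j] == "invariant") {
        expect_equal(v2, v1, tolerance = 1e-9, info = specs$score[j])
      } else {
        expect_equal(v2, phi * v1, tolerance = 1e-9, info = specs$score[j])
      }
    }
  }
})

test_that("modularity matches the direct formula, igraph, and scale invariance", {
  gu <- make_fixture("triangle", weights = c(1, 1, 1))
  expect_equal(modularity_q(gu, c(a = 1, b = 1, c = 2)), -2 / 9)
  expect_equal(modularity_q(gu, c(a = 1, b = 1, c = 1)), 0)
  g7 <- scale_graph_weights(gu, 7)
  expect_equal(modularity_q(g7, c(a = 1, b = 1, c = 2)), -2 / 9)
  set.seed(34)
  for (i in 1:5) {
    g <- random_weighted_graph(14, p = 0.4)
    p <- random_partition(14, 4)
    expect_equal(modularity_q(g, p),
                 igraph::modularity(g, p, weights = igraph::E(g)$weight))
  }
})

test_that("partition-level aggregation averages defined clusters and counts NaNs", {
  g <- make_fixture("triangle", weights = c(1, 1, 1))
  res <- score_partition(g, c(a = 1, b = 1, c = 2), "internal_density")
  expect_equal(res$n_undefined, 1)  # the singleton cluster
  expect_equal(res$value, 1)        # mean over the one defined cluster
  # two symmetric cliques: both clusters share the same conductance
  g2 <- make_fixture("two_cliques", k = 4)
  truth <- igraph::graph_attr(g2, "truth")
  agg <- cluster_aggregates(g2, truth)
  c1 <- score_cluster(g2, agg, 1, "conductance")
  c2 <- score_cluster(g2, agg, 2, "conductance")
  expect_equal(c1, c2)
  expect_equal(score_partition(g2, truth, "conductance")$value, c1)
})

test_that("weighted clustering coefficient integrates the threshold sweep exactly", {
  g <- make_fixture("triangle")           # weights 1, 2, 3
  expect_equal(weighted_clustering_coefficient(g), 1 / 3)
  # complete graph with equal weights: C_t identically 1
  gc <- make_fixture("complete", n = 6)
  expect_equal(weighted_clustering_coefficient(gc), 1)
  # binary graph: classical transitivity
  set.seed(35)
  gb <- make_fixture("binary_random", n = 15, p = 0.35)
  expect_equal(weighted_clustering_coefficient(gb),
               igraph::transitivity(gb, type = "global"))
  # no triplets anywhere: undefined
  g2 <- weighted_graph_from_edges(c("a", "c"), c("b", "d"), c(1, 2))
  expect_true(is.nan(weighted_clustering_coefficient(g2)))
})

test_that("sweep equals brute-force grid integration on random graphs", {
  set.seed(36)
  for (i in 1:4) {
    g <- random_weighted_graph(10, p = 0.5, maxw = 3)
    got <- weighted_clustering_coefficient(g)
    grid <- oracle_wcc_grid(g, npts = 1e4)
    # grid error is bounded by (#thresholds + 1) / npts
    k <- length(unique(igraph::E(g)$weight))
    expect_equal(got, grid, tolerance = (k + 2) / 1e4)
  }
})

test_that("Barrat's coefficient is degenerate on complete graphs and matches igraph", {
  g <- make_fixture("complete", n = 7, seed = 41)
  for (v in c("v1", "v4")) {
    expect_equal(barrat_local_coefficient(g, v), 1)
  }
  gu <- make_fixture("triangle", weights = c(1, 1, 1))
  expect_equal(barrat_local_coefficient(gu, "a"), 1)
  star <- weighted_graph_from_edges(rep("hub", 3), c("l1", "l2", "l3"),
                                    c(1, 2, 3))
  expect_equal(barrat_local_coefficient(star, "hub"), 0)
  expect_true(is.nan(barrat_local_coefficient(star, "l1")))
  set.seed(42)
  g2 <- random_weighted_graph(12, p = 0.5)
  ig <- igraph::transitivity(g2, type = "barrat",
                             weights = igraph::E(g2)$weight)
  for (v in c(1, 5, 9)) {
    mine <- barrat_local_coefficient(g2, v)
    if (!is.nan(mine)) expect_equal(mine, unname(ig[v]))
  }
})
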