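test_that("transfer rules reproduce the worked quadruples", {
  # constant variance: w_bar = (0.9 + 0.5 - 0.1 - 0.3) / 2 = 0.5
  tr <- transfer_weight(0.9, 0.5, 0.1, 0.3, method = "constant_variance")
  expect_equal(tr$w_bar, 0.5)
  expect_equal(unname(tr$weights), c(0.4, 0.0, 0.6, 0.8))
  # the sample variance of the four touched weights is preserved
  expect_equal(var(c(0.9, 0.5, 0.1, 0.3)), var(tr$weights))
  # bounded maximum-weight transfer: componentwise minimum
  tr2 <- transfer_weight(0.6, 0.9, 0.7, 0.2, method = "max_weight",
                         upper_bound = 1)
  expect_equal(tr2$w_bar, 0.3)
  # binary case: the classic switch
  tr3 <- transfer_weight(1, 1, 0, 0, method = "max_weight")
  expect_equal(tr3$w_bar, 1)
  expect_equal(unname(tr3$weights), c(0, 0, 1, 1))
  tr4 <- transfer_weight(1, 1, 0, 0, method = "constant_variance")
  expect_equal(tr4$w_bar, 1)
  # out-of-bound constant-variance step is discarded whole
  tr5 <- transfer_weight(0.5, 2, 0, 0, method = "constant_variance",
                         upper_bound = 1)
  expect_true(tr5$discarded)
})

test_that("proposals accept disjoint heavy-over-weak pairs and reject shared vertices", {
  # two disjoint unit edges, no AD/BC edges: always accepted
  g <- weighted_graph_from_edges(c("A", "B"), c("C", "D"), c(1, 1))
  set.seed(51)
  for (i in 1:20) {
    pr <- propose_switch(g)
    expect_true(pr$accepted)
    expect_equal(pr$w_AD, 0)
    expect_equal(pr$w_BC, 0)
  }
  # two edges sharing a vertex: never accepted
  g2 <- weighted_graph_from_edges(c("A", "A"), c("C", "D"), c(1, 1))
  for (i in 1:20) expect_false(propose_switch(g2)$accepted)
  # strict inequality: equal-weight complete triangle plus pendant can
  # only be accepted when the weak edges are strictly lighter
  g3 <- make_fixture("complete", n = 4)   # all weights equal
  for (i in 1:40) expect_false(propose_switch(g3)$accepted)
})

test_that("rewiring conserves strengths and total weight for both methods", {
  set.seed(52)
  for (i in 1:6) {
    g <- random_weighted_graph(sample(10:20, 1), p = 0.4)
    for (method in c("max_weight", "constant_variance")) {
      gr <- rewire_weighted(g, method = method, T = 30)
      expect_equal(strengths(gr)[names(strengths(g))], strengths(g),
                   tolerance = 1e-9)
      expect_equal(sum(igraph::E(gr)$weight), sum(igraph::E(g)$weight),
                   tolerance = 1e-12)
      expect_true(all(igraph::E(gr)$weight > 0))
      expect_false(igraph::any_loop(gr))
      expect_false(igraph::any_multiple(gr))
    }
  }
})

test_that("constant variance preserves the all-pairs weight variance", {
  set.seed(53)
  g <- make_fixture("complete", n = 14, seed = 8)   # bounded in (0, 1]
  gr <- rewire_weighted(g, method = "constant_variance", T = 50)
  expect_equal(oracle_allpairs_variance(gr), oracle_allpairs_variance(g),
               tolerance = 1e-9)
  expect_true(all(igraph::E(gr)$weight <= 1 + 1e-12))
  expect_true(all(igraph::E(gr)$weight >= 0))
})

test_that("binary graphs stay binary with the same degree sequence", {
  set.seed(54)
  g <- make_fixture("binary_random", n = 18, p = 0.3)
  for (method in c("max_weight", "constant_variance")) {
    gr <- rewire_weighted(g, method = method, T = 50)
    expect_true(all(igraph::E(gr)$weight == 1))
    expect_false(igraph::any_multiple(gr))
    d0 <- igraph::degree(g)
    expect_equal(igraph::degree(gr)[names(d0)], d0)
  }
})

test_that("rewiring is reproducible under a seed and T = 0 is the identity", {
  set.seed(55)
  g <- random_weighted_graph(15, p = 0.4)
  g1 <- rewire_weighted(g, method = "max_weight", T = 20, seed = 99)
  g2 <- rewire_weighted(g, method = "max_weight", T = 20, seed = 99)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(igraph::E(g1)$weight, igraph::E(g2)$weight)
  g0 <- rewire_weighted(g, T = 0)
  expect_equal(igraph::graph_attr(g0, "proposals"), 0)
  expect_equal(sort(igraph::E(g0)$weight), sort(igraph::E(g)$weight))
})

test_that("the mixing diagnostic starts at the identity point", {
  g <- make_fixture("wsbm_small", sizes = c(12, 12), lambda = 8, seed = 6)
  md <- mixing_diagnostic(g, "louvain", T_grid = c(0, 1),
                          method = "max_weight", seed = 7)
  expect_equal(md$vi[1], 0)
  expect_equal(md$size_ratio[1], 1)
  expect_equal(md$variance_ratio[1], 1)
  expect_true(md$vi[2] > 0)
})

test_that("constant-variance mixing keeps the variance ratio at one", {
  g <- make_fixture("complete", n = 12, seed = 9)
  md <- mixing_diagnostic(g, "walktrap", T_grid = c(0, 0.5, 2, 10),
                          method = "constant_variance", seed = 10)
  expect_equal(md$variance_ratio, rep(1, 4), tolerance = 1e-9)
  expect_equal(md$size_ratio, rep(1, 4))   # no edge ever leaves (0, 1)
})
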