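test_that("contingency tables cross-tabulate with verified margins", {
  ct <- partition_contingency(c(1, 1, 2, 2), c(1, 1, 1, 2))
  expect_equal(ct$counts, matrix(c(2, 1, 0, 1), 2, 2))
  expect_equal(ct$a, c(2, 2))
  expect_equal(ct$b, c(3, 1))
  expect_equal(ct$n, 4)
  # identical partitions give a diagonal table
  p <- c(1, 2, 1, 3, 2)
  ctd <- partition_contingency(p, p)
  expect_equal(ctd$counts, diag(c(2, 2, 1)))
  # singletons vs one cluster: a column of ones
  cts <- partition_contingency(1:4, rep(1, 4))
  expect_equal(cts$counts, matrix(1L, 4, 1))
  # named vectors align by vertex, and disjoint vertex sets fail
  m1 <- c(a = 1, b = 1, c = 2); m2 <- c(c = 5, a = 5, b = 9)
  expect_equal(partition_contingency(m1, m2)$counts, matrix(c(1, 1, 1, 0), 2))
  expect_error(partition_contingency(m1, c(x = 1, y = 1, z = 2)),
               "different vertex sets")
})

test_that("entropy and mutual information match their closed forms", {
  expect_equal(partition_entropy(rep(1, 6)), 0)
  expect_equal(partition_entropy(rep(1:3, each = 4)), log(3))
  expect_equal(partition_entropy(c(1, 1, 1, 2)), 0.562335, tolerance = 1e-6)
  p1 <- c(1, 1, 2, 2); p2 <- c(1, 1, 1, 2)
  expect_equal(mutual_information(p1, p2), 0.215761, tolerance = 1e-5)
  expect_equal(mutual_information(p1, p1), partition_entropy(p1))
  # independent uniform table
  expect_equal(mutual_information(matrix(1, 2, 2)), 0)
})

test_that("variation of information matches the worked value and is symmetric", {
  p1 <- c(1, 1, 2, 2); p2 <- c(1, 1, 1, 2)
  expect_equal(variation_of_information(p1, p2), 0.823959, tolerance = 1e-6)
  expect_equal(variation_of_information(p1, p2),
               variation_of_information(p2, p1))
  expect_equal(variation_of_information(p1, c(2, 2, 1, 1)), 0)
})

test_that("Rand and adjusted Rand match the worked tables", {
  p1 <- c(1, 1, 2, 2); p2 <- c(1, 1, 1, 2)
  expect_equal(rand_index(p1, p2), 0.5)
  expect_equal(adjusted_rand_index(p1, p2), 0)
  expect_equal(rand_index(p1, p1), 1)
  expect_equal(adjusted_rand_index(p1, c(2, 2, 1, 1)), 1)
  expect_equal(rand_index(1:4, rep(1, 4)), 0)
})

test_that("all measures agree with pair-counting and direct-formula oracles", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(5:25, 1)
    p1 <- random_partition(n, sample(2:5, 1))
    p2 <- random_partition(n, sample(2:5, 1))
    pc <- oracle_pair_indices(p1, p2)
    oi <- oracle_information(p1, p2)
    expect_equal(rand_index(p1, p2), pc$ri)
    expect_equal(adjusted_rand_index(p1, p2), pc$ari)
    expect_equal(mutual_information(p1, p2), oi$mi)
    expect_equal(variation_of_information(p1, p2), oi$vi)
    # igraph as an independent cross-check
    expect_equal(variation_of_information(p1, p2),
                 igraph::compare(p1, p2, method = "vi"))
    expect_equal(adjusted_rand_index(p1, p2),
                 igraph::compare(p1, p2, method = "adjusted.rand"))
  }
})

test_that("measures are invariant under label permutation", {
  set.seed(72)
  for (i in 1:10) {
    n <- 20
    p1 <- random_partition(n, 4); p2 <- random_partition(n, 4)
    perm <- sample(max(p2))
    p2b <- perm[p2]
    expect_equal(variation_of_information(p1, p2b),
                 variation_of_information(p1, p2))
    expect_equal(adjusted_rand_index(p1, p2b), adjusted_rand_index(p1, p2))
    expect_equal(as.numeric(reduced_mutual_information(p1, p2b)),
                 as.numeric(reduced_mutual_information(p1, p2)))
  }
})

test_that("VI satisfies the metric axioms on random partition triples", {
  set.seed(73)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    p <- random_partition(n, 4); q <- random_partition(n, 4)
    r <- random_partition(n, 4)
    expect_equal(variation_of_information(p, p), 0)
    expect_equal(variation_of_information(p, q),
                 variation_of_information(q, p))
    expect_gte(variation_of_information(p, r) + 1e-12,
               variation_of_information(p, q) -
                 variation_of_information(q, r))
  }
})

test_that("table counting: exact enumeration matches closed forms and the oracle", {
  expect_equal(exp(count_contingency_tables(c(2, 2), c(3, 1),
                                            method = "exact")$log_omega), 2)
  expect_equal(exp(count_contingency_tables(c(1, 1, 1, 1), c(2, 2),
                                            method = "exact")$log_omega), 6)
  expect_equal(exp(count_contingency_tables(rep(1, 4), rep(1, 4),
                                            method = "exact")$log_omega), 24)
  set.seed(74)
  for (i in 1:10) {
    n <- sample(6:14, 1)
    a <- tabulate(random_partition(n, 3))
    b <- tabulate(random_partition(n, 3))
    expect_equal(exp(count_contingency_tables(a, b,
                                              method = "exact")$log_omega),
                 oracle_omega(a, b))
  }
  expect_error(count_contingency_tables(c(2, 2), c(3, 2)), "disagree")
})

test_that("the analytic estimate tracks exact enumeration on random tables", {
  set.seed(75)
  checked <- 0
  while (checked < 25) {
    n <- sample(15:40, 1)
    a <- tabulate(random_partition(n, sample(2:4, 1)))
    b <- tabulate(random_partition(n, sample(2:4, 1)))
    if (length(a) < 2 || length(b) < 2) next
    ex <- count_contingency_tables(a, b, method = "exact")$log_omega
    an <- count_contingency_tables(a, b, method = "analytic")$log_omega
    expect_lt(abs(an - ex) / ex, 0.02)
    checked <- checked + 1
  }
})

test_that("the hybrid MC estimator brackets exact counts on unit-heavy margins", {
  cases <- list(list(a = c(1, 1, 1, 1, 1, 5), b = c(2, 2, 2, 2, 2)),
                list(a = c(1, 1, 1, 1, 4, 4), b = c(1, 1, 2, 8)))
  set.seed(76)
  for (cs in cases) {
    ex <- count_contingency_tables(cs$a, cs$b, method = "exact")$log_omega
    hy <- count_contingency_tables(cs$a, cs$b, method = "mc",
                                   mc_samples = 3000)
    expect_lt(abs(hy$log_omega - ex), 3 * hy$mc_error)
    expect_gt(hy$mc_error, 0)
  }
})

test_that("reduced mutual information matches worked values and fixes the NMI pathology", {
  # singletons vs halves on four elements: I = log 2, Omega = 6
  rmi <- reduced_mutual_information(1:4, c(1, 1, 2, 2))
  expect_equal(as.numeric(rmi), log(2) - log(6) / 4)
  expect_equal(as.numeric(rmi), 0.245207, tolerance = 1e-5)
  # equal partitions normalize to one
  p <- c(1, 1, 2, 2, 3)
  expect_equal(as.numeric(reduced_mutual_information(p, p,
                                                     normalized = TRUE)), 1)
  # singletons vs the one-cluster partition: NRMI is 0, yet the
  # min-normalized mutual information would be maximal (I = H = 0 case)
  expect_equal(as.numeric(reduced_mutual_information(
    1:4, rep(1, 4), normalized = TRUE)), 0)
  # both trivial one-cluster labelings: degenerate denominator
  expect_true(is.nan(as.numeric(reduced_mutual_information(
    rep(1, 4), rep(1, 4), normalized = TRUE))))
})
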