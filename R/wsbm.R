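# Weighted stochastic block model benchmark generator.
#
# A multigraph sampler: unit-weight edges are added one pair at a time with
# probability proportional to a block expectation matrix, and the edge
# weight is the accumulated count.  The total network weight is therefore
# fixed across samples, and each edge weight is marginally binomial.

#' Specification of a weighted stochastic block model benchmark
#'
#' The expectation matrix gives the expected total weight between a vertex
#' of block `i` and a vertex of block `j`; the `lambda` parameter scales
#' its diagonal, tuning the planted-community strength from near-uniform
#' (`lambda = 1`) to very strong.
#'
#' @param block_sizes positive integer vector of community sizes.
#' @param expectation symmetric nonnegative base expectation matrix (its
#'   diagonal is the `lambda = 1` value).
#' @param lambda positive diagonal scaling factor.
#' @return an object of class `wsbm_spec`.
#' @export
wsbm_spec <- function(block_sizes, expectation, lambda = 1) {
  block_sizes <- as.integer(block_sizes)
  stopifnot(length(block_sizes) >= 1, all(block_sizes > 0),
            is.matrix(expectation),
            nrow(expectation) == length(block_sizes),
            isTRUE(all.equal(expectation, t(expectation))),
            all(expectation >= 0), lambda > 0)
  E <- expectation
  diag(E) <- diag(E) * lambda
  structure(list(block_sizes = block_sizes, expectation = E,
                 lambda = lambda), class = "wsbm_spec")
}

#' The built-in four-block benchmark specification
#'
#' Block sizes (40, 25, 25, 10) with base expectation matrix
#' ```
#'   0.03l 0.01  0.01  0.03
#'   0.01  0.02l 0.05  0.02
#'   0.01  0.05  0.02l 0.01
#'   0.03  0.02  0.01  0.03l
#' ```
#' where `l` is the `lambda` diagonal scaling.
#'
#' @param lambda diagonal scaling factor.
#' @return a [wsbm_spec()].
#' @export
wsbm_benchmark_spec <- function(lambda = 1) {
  E <- matrix(c(0.03, 0.01, 0.01, 0.03,
                0.01, 0.02, 0.05, 0.02,
                0.01, 0.05, 0.02, 0.01,
                0.03, 0.02, 0.01, 0.03), 4, 4)
  wsbm_spec(c(40, 25, 25, 10), E, lambda = lambda)
}

#' Number of sampling steps (= total network weight)
#'
#' The sum of the pair expectations over all unordered pairs of distinct
#' vertices, rounded half-up:
#' `sum_i C(n_i, 2) E_ii + sum_{i<j} n_i n_j E_ij`.  Self-pairs are
#' excluded so that the per-step pair probabilities sum to one over
#' admissible pairs; `self_pairs = TRUE` reproduces instead the plain
#' half-sum `0.5 * sum_ij n_i n_j E_ij` over all ordered block pairs,
#' which counts diagonal self-pairs (compatibility reading).
#'
#' @param spec a [wsbm_spec()].
#' @param self_pairs compatibility flag, see above.
#' @return integer number of steps.
#' @export
wsbm_n_steps <- function(spec, self_pairs = FALSE) {
  stopifnot(inherits(spec, "wsbm_spec"))
  ns <- spec$block_sizes; E <- spec$expectation
  if (self_pairs) {
    tot <- sum(outer(ns, ns) * E) / 2
  } else {
    pairs <- outer(ns, ns)
    diag(pairs) <- ns * (ns - 1)
    tot <- sum(pairs * E) / 2
  }
  if (tot <= 0) stop("zero total expectation: nothing to sample")
  as.integer(floor(tot + 0.5))
}

#' Sample a weighted graph with planted communities
#'
#' Performs [wsbm_n_steps()] independent draws; each draw selects one
#' unordered pair of distinct vertices with probability proportional to
#' the expectation between their blocks and increments that pair's weight
#' by one.  The total sampled weight equals the number of steps exactly.
#'
#' @param spec a [wsbm_spec()].
#' @param seed optional integer seed.
#' @return a list with `graph` (weighted graph, vertices `v1..vn`) and
#'   `membership` (named planted block labels).
#' @export
sample_wsbm <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "wsbm_spec"))
  if (!is.null(seed)) set.seed(seed)
  ns <- spec$block_sizes
  n <- sum(ns)
  block <- rep(seq_along(ns), ns)
  # all unordered pairs of distinct vertices
  iu <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  iv <- sequence((n - 1L):1L) + iu
  p <- spec$expectation[cbind(block[iu], block[iv])]
  steps <- wsbm_n_steps(spec)
  draws <- sample.int(length(p), steps, replace = TRUE, prob = p)
  cnt <- tabulate(draws, nbins = length(p))
  keep <- cnt > 0
  vn <- paste0("v", seq_len(n))
  g <- weighted_graph_from_edges(vn[iu[keep]], vn[iv[keep]], cnt[keep],
                                 vertices = vn)
  membership <- block
  names(membership) <- vn
  list(graph = g, membership = membership)
}

#' Sweep the planted-community strength parameter
#'
#' For each `lambda` and replicate, samples a benchmark graph, clusters it
#' with each algorithm, and records the similarity of the found partition
#' to the planted one (variation of information and adjusted Rand index).
#'
#' @param lambdas numeric vector of diagonal scalings.
#' @param algorithms character vector of adapter names (or a named list of
#'   functions), see [cluster_adapter()].
#' @param n_reps replicates per `lambda`.
#' @param spec_fn function `lambda -> wsbm_spec`; defaults to
#'   [wsbm_benchmark_spec()].
#' @param seed optional integer seed for the whole sweep.
#' @return a data frame with columns `lambda`, `rep`, `algorithm`, `vi`,
#'   `ari`, `n_clusters`.
#' @export
lambda_sweep <- function(lambdas, algorithms = "louvain", n_reps = 20,
                         spec_fn = wsbm_benchmark_spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  algos <- adapter_list(algorithms)
  rows <- list()
  for (lam in lambdas) {
    spec <- spec_fn(lam)
    for (r in seq_len(n_reps)) {
      smp <- sample_wsbm(spec)
      for (nm in names(algos)) {
        mem <- algos[[nm]](smp$graph)
        rows[[length(rows) + 1L]] <- data.frame(
          lambda = lam, rep = r, algorithm = nm,
          vi = variation_of_information(smp$membership, mem),
          ari = adjusted_rand_index(smp$membership, mem),
          n_clusters = max(mem))
      }
    }
  }
  do.call(rbind, rows)
}
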