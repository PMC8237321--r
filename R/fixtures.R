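# Deterministic toy graphs used across examples and tests.

#' Toy weighted graphs
#'
#' Deterministic (or seeded) fixture graphs:
#' * `triangle` — three vertices `a, b, c` with weights `weights`
#'   (default `c(1, 2, 3)` on edges ab, bc, ac).
#' * `two_cliques` — two `k`-cliques of unit weights joined by one bridge
#'   edge of weight `bridge_weight`; carries a `truth` attribute with the
#'   planted 2-partition.
#' * `complete` — complete graph on `n` vertices; unit weights, or
#'   uniform weights in (0, 1] with upper bound 1 when `seed` is given.
#' * `binary_random` — Erdos-Renyi `G(n, p)` with unit weights.
#' * `wsbm_small` — a small two-block benchmark sample; carries `truth`.
#'
#' @param kind fixture name.
#' @param weights,k,bridge_weight,n,p,sizes,lambda,seed shape parameters.
#' @return a weighted graph; planted partitions are attached as the graph
#'   attribute `truth`.
#' @export
make_fixture <- function(kind = c("triangle", "two_cliques", "complete",
                                  "binary_random", "wsbm_small"),
                         weights = c(1, 2, 3), k = 5, bridge_weight = 1,
                         n = 13, p = 0.3, sizes = c(10, 10), lambda = 10,
                         seed = NULL) {
  kind <- match.arg(kind)
  switch(kind,
    triangle = weighted_graph_from_edges(c("a", "b", "a"), c("b", "c", "c"),
                                         weights),
    two_cliques = {
      vn <- c(paste0("l", seq_len(k)), paste0("r", seq_len(k)))
      pairs <- t(utils::combn(seq_len(k), 2))
      u <- c(vn[pairs[, 1]], vn[k + pairs[, 1]], vn[1])
      v <- c(vn[pairs[, 2]], vn[k + pairs[, 2]], vn[k + 1])
      w <- c(rep(1, 2 * nrow(pairs)), bridge_weight)
      g <- weighted_graph_from_edges(u, v, w, vertices = vn)
      truth <- stats::setNames(rep(1:2, each = k), vn)
      igraph::set_graph_attr(g, "truth", truth)
    },
    complete = {
      vn <- paste0("v", seq_len(n))
      pairs <- t(utils::combn(seq_len(n), 2))
      if (is.null(seed)) {
        w <- rep(1, nrow(pairs)); ub <- NULL
      } else {
        set.seed(seed)
        w <- runif(nrow(pairs)); ub <- 1
      }
      weighted_graph_from_edges(vn[pairs[, 1]], vn[pairs[, 2]], w,
                                vertices = vn, upper_bound = ub)
    },
    binary_random = {
      if (!is.null(seed)) set.seed(seed)
      vn <- paste0("v", seq_len(n))
      pairs <- t(utils::combn(seq_len(n), 2))
      keep <- runif(nrow(pairs)) < p
      weighted_graph_from_edges(vn[pairs[keep, 1]], vn[pairs[keep, 2]], 1,
                                vertices = vn)
    },
    wsbm_small = {
      E <- matrix(c(0.2, 0.05, 0.05, 0.2), 2, 2)
      spec <- wsbm_spec(sizes, E, lambda = lambda)
      smp <- sample_wsbm(spec, seed = seed)
      igraph::set_graph_attr(smp$graph, "truth", smp$membership)
    })
}
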