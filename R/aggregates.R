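# O(m) aggregate quantities consumed by every scoring function.

#' Per-cluster and per-vertex aggregates of a partitioned weighted graph
#'
#' Computes, in a single pass over the edge list, every aggregate the
#' community scoring functions need: per cluster `S` the vertex count
#' `n_S`, internal edge count `m_S`, internal weight `m_tilde_S`, boundary
#' edge count `c_S` and boundary weight `c_tilde_S`; per vertex its
#' unweighted and weighted degree, total and restricted to its own cluster.
#' Median degrees are exposed as well (no bundled scoring function consumes
#' them, but they belong to the same one-pass sweep).
#'
#' @param g a weighted graph.
#' @param membership partition of the vertices of `g`: a vector with one
#'   label per vertex, optionally named by vertex.
#' @return an object of class `cluster_aggregates`: a list with elements
#'   `clusters` (data frame, one row per cluster), `vertices` (data frame,
#'   one row per vertex), `membership`, and graph totals `n`, `m`,
#'   `m_tilde`, `d_median`, `d_tilde_median`.
#' @examples
#' g <- make_fixture("triangle")
#' cluster_aggregates(g, c(a = 1, b = 1, c = 2))
#' @export
cluster_aggregates <- function(g, membership) {
  membership <- align_membership(g, membership)
  n <- igraph::vcount(g)
  k <- max(membership)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- edge_weights(g)
  cu <- membership[el[, 1]]
  cv <- membership[el[, 2]]
  internal <- cu == cv

  n_S <- tabulate(membership, nbins = k)
  m_S <- tabulate(cu[internal], nbins = k)
  mt_S <- as.numeric(rowsum_safe(w[internal], cu[internal], k))
  # each boundary edge contributes to both endpoint clusters
  c_S <- tabulate(cu[!internal], nbins = k) + tabulate(cv[!internal], nbins = k)
  ct_S <- as.numeric(rowsum_safe(w[!internal], cu[!internal], k) +
                       rowsum_safe(w[!internal], cv[!internal], k))

  deg <- tabulate(el, nbins = n)
  str_tot <- as.numeric(rowsum_safe(w, el[, 1], n) + rowsum_safe(w, el[, 2], n))
  deg_own <- tabulate(c(el[internal, 1], el[internal, 2]), nbins = n)
  str_own <- as.numeric(rowsum_safe(w[internal], el[internal, 1], n) +
                          rowsum_safe(w[internal], el[internal, 2], n))

  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(n))
  structure(list(
    clusters = data.frame(cluster = seq_len(k), n_S = n_S, m_S = m_S,
                          m_tilde_S = mt_S, c_S = c_S, c_tilde_S = ct_S),
    vertices = data.frame(vertex = vn, cluster = as.integer(membership),
                          degree = deg, strength = str_tot,
                          degree_in_cluster = deg_own,
                          strength_in_cluster = str_own,
                          stringsAsFactors = FALSE),
    membership = membership,
    n = n, m = igraph::ecount(g), m_tilde = sum(w),
    d_median = stats::median(deg), d_tilde_median = stats::median(str_tot)
  ), class = "cluster_aggregates")
}

# rowsum over integer groups 1..k returning a dense length-k vector
rowsum_safe <- function(x, group, k) {
  out <- numeric(k)
  if (length(x) > 0) {
    rs <- rowsum(x, group)
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

#' @export
print.cluster_aggregates <- function(x, ...) {
  cat("Cluster aggregates: n =", x$n, ", m =", x$m,
      ", total weight =", format(x$m_tilde), "\n")
  print(x$clusters, ...)
  invisible(x)
}
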