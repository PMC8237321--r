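# Independent oracles and graph builders used across the suite.

# random weighted graph on n vertices: G(n, p) topology, weights ~ U(0, maxw]
random_weighted_graph <- function(n, p = 0.4, maxw = 5) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  if (sum(keep) < 2) keep[1:2] <- TRUE
  vn <- paste0("v", seq_len(n))
  weighted_graph_from_edges(vn[pairs[keep, 1]], vn[pairs[keep, 2]],
                            runif(sum(keep), 1e-3, maxw), vertices = vn)
}

scale_graph_weights <- function(g, phi) {
  igraph::set_edge_attr(g, "weight", value = igraph::E(g)$weight * phi)
}

random_partition <- function(n, kmax = 4) {
  canonicalize_membership(sample.int(kmax, n, replace = TRUE))
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_set_partitions <- function(n) {
  out <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(max(prefix) + 1L)) grow(c(prefix, lab))
  }
  grow(1L)
  out
}

# pair-counting oracle: classify every vertex pair as agreeing/disagreeing
oracle_pair_indices <- function(p1, p2) {
  n <- length(p1)
  same1 <- outer(p1, p1, "==")[upper.tri(diag(n))]
  same2 <- outer(p2, p2, "==")[upper.tri(diag(n))]
  agree <- sum(same1 == same2)
  total <- n * (n - 1) / 2
  ri <- agree / total
  # ARI from pair counts (Hubert-Arabie form)
  n11 <- sum(same1 & same2); n00 <- sum(!same1 & !same2)
  n10 <- sum(same1 & !same2); n01 <- sum(!same1 & same2)
  expected <- (n11 + n10) * (n11 + n01) / total
  maximum <- ((n11 + n10) + (n11 + n01)) / 2
  ari <- if (maximum == expected) 1 else (n11 - expected) / (maximum - expected)
  list(ri = ri, ari = ari)
}

# direct-formula oracle for entropy, mutual information and VI
oracle_information <- function(p1, p2) {
  n <- length(p1)
  tab <- unname(unclass(table(p1, p2))) / n
  pr <- rowSums(tab); ps <- colSums(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  I <- 0
  for (r in seq_along(pr)) for (s in seq_along(ps)) {
    if (tab[r, s] > 0) I <- I + tab[r, s] * log(tab[r, s] / (pr[r] * ps[s]))
  }
  list(h1 = H(pr), h2 = H(ps), mi = I, vi = H(pr) + H(ps) - 2 * I)
}

# plain unmemoized recursion counting tables with the given margins
oracle_omega <- function(a, b) {
  a <- a[a > 0]; b <- b[b > 0]
  if (length(a) == 0) return(1)
  if (length(a) == 1) return(1)
  total <- 0
  first <- a[1]
  fill <- function(row_left, s, row) {
    if (s > length(b)) {
      if (row_left == 0) total <<- total + oracle_omega_rest(a[-1], b - row)
      return(invisible())
    }
    for (x in 0:min(row_left, b[s])) {
      row[s] <- x
      fill(row_left - x, s + 1L, row)
    }
  }
  oracle_omega_rest <- function(a2, b2) oracle_omega(a2, b2)
  fill(first, 1L, integer(length(b)))
  total
}

# Riemann-grid integration of the thresholded clustering coefficient,
# C_t computed by igraph's transitivity on the binary graph at threshold t
oracle_wcc_grid <- function(g, w_bar = NULL, npts = 1e4) {
  w <- igraph::E(g)$weight
  if (is.null(w_bar)) w_bar <- max(w)
  ts <- (seq_len(npts) - 0.5) / npts * w_bar
  vals <- vapply(ts, function(t) {
    gt <- igraph::subgraph_from_edges(g, which(w >= t),
                                      delete.vertices = FALSE)
    ct <- igraph::transitivity(gt, type = "global")
    if (is.nan(ct)) 0 else ct
  }, numeric(1))
  mean(vals)
}

# all-pairs sample variance of a weight assignment (absent edges = 0)
oracle_allpairs_variance <- function(g) {
  n <- igraph::vcount(g)
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  var(W[upper.tri(W)])
}

strengths <- function(g) {
  igraph::strength(g, weights = igraph::E(g)$weight)
}
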