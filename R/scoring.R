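# Community scoring functions for weighted networks, modularity and the
# threshold-integral weighted clustering coefficient.

#' Catalogue of the community scoring functions
#'
#' One row per score with its optimization direction (whether higher or
#' lower values indicate a stronger clustering) and its behaviour under
#' uniform weight scaling `w -> phi * w`: scores combining internal and
#' external connectivity (and modularity and the clustering coefficient)
#' are invariant, the rest scale linearly with `phi`.
#'
#' @param names optional character vector to subset/validate.
#' @return a data frame with columns `score`, `direction`
#'   (`"higher_better"` / `"lower_better"`) and `scale_class`
#'   (`"linear"` / `"invariant"`).
#' @export
score_specs <- function(names = NULL) {
  specs <- data.frame(
    score = c("internal_density", "edges_inside", "average_degree",
              "expansion", "cut_ratio", "conductance", "normalized_cut",
              "max_odf", "avg_odf", "clustering_coefficient", "modularity"),
    direction = c("higher_better", "higher_better", "higher_better",
                  "lower_better", "lower_better", "lower_better",
                  "lower_better", "lower_better", "lower_better",
                  "higher_better", "higher_better"),
    scale_class = c("linear", "linear", "linear", "linear", "linear",
                    "invariant", "invariant", "invariant", "invariant",
                    "invariant", "invariant"),
    stringsAsFactors = FALSE)
  if (is.null(names) || identical(names, "all")) return(specs)
  bad <- setdiff(names, specs$score)
  if (length(bad) > 0) stop("unknown score(s): ", paste(bad, collapse = ", "))
  specs[match(names, specs$score), , drop = FALSE]
}

# scores defined per cluster (modularity is partition-level)
cluster_score_names <- function() {
  setdiff(score_specs()$score, "modularity")
}

#' Score a single cluster
#'
#' Evaluates one community scoring function on cluster `cluster` of the
#' partition summarised in `agg`.  On a binary graph every weighted score
#' equals its unweighted counterpart exactly.  Undefined cases return
#' `NaN`: internal density of a singleton cluster, and conductance /
#' normalized cut of a cluster with no internal weight and no boundary
#' weight (a division by zero).
#'
#' @param g the weighted graph.
#' @param agg aggregates from [cluster_aggregates()].
#' @param cluster integer cluster id (label in the canonicalized partition).
#' @param score one of the names in [score_specs()], except `"modularity"`.
#' @return a single numeric value (possibly `NaN` when undefined).
#' @export
score_cluster <- function(g, agg, cluster, score) {
  stopifnot(inherits(agg, "cluster_aggregates"))
  score <- match.arg(score, cluster_score_names())
  cl <- agg$clusters
  if (!cluster %in% cl$cluster) stop("no such cluster: ", cluster)
  row <- cl[cl$cluster == cluster, ]
  n_S <- row$n_S; mt <- row$m_tilde_S; ct <- row$c_tilde_S
  n <- agg$n; m_tilde <- agg$m_tilde
  switch(score,
    internal_density = if (n_S < 2) NaN else mt / (n_S * (n_S - 1) / 2),
    edges_inside = mt,
    average_degree = 2 * mt / n_S,
    expansion = ct / n_S,
    cut_ratio = if (n_S == n) 0 else ct / (n_S * (n - n_S)),
    conductance = if (2 * mt + ct == 0) NaN else ct / (2 * mt + ct),
    normalized_cut = {
      if (ct == 0) {
        if (2 * mt == 0) NaN else 0
      } else {
        t1 <- ct / (2 * mt + ct)
        d2 <- 2 * (m_tilde - mt) + ct
        if (d2 == 0) NaN else t1 + ct / d2
      }
    },
    max_odf = odf_values(agg, cluster, max),
    avg_odf = odf_values(agg, cluster, mean),
    clustering_coefficient = {
      vs <- which(agg$membership == cluster)
      sub <- igraph::induced_subgraph(g, vs)
      weighted_clustering_coefficient(sub, w_bar = weight_upper_bound(g))
    }
  )
}

# out-degree fractions of the vertices of one cluster; a vertex with zero
# weighted degree contributes 0 (no outgoing fraction definable)
odf_values <- function(agg, cluster, aggregate_fn) {
  vx <- agg$vertices[agg$vertices$cluster == cluster, ]
  frac <- ifelse(vx$strength == 0, 0,
                 (vx$strength - vx$strength_in_cluster) / vx$strength)
  aggregate_fn(frac)
}

#' Score a whole partition
#'
#' Cluster-level scores are aggregated as the unweighted mean over the
#' clusters on which they are defined; the number of undefined (NaN)
#' clusters is reported alongside.  `score = "modularity"` returns the
#' partition-level modularity.
#'
#' @param g the weighted graph.
#' @param membership a partition of the vertices of `g`.
#' @param score a score name from [score_specs()].
#' @param agg optional precomputed [cluster_aggregates()].
#' @return a list with `value` (mean over defined clusters, `NaN` when all
#'   clusters are undefined) and `n_undefined`.
#' @export
score_partition <- function(g, membership, score, agg = NULL) {
  if (is.null(agg)) agg <- cluster_aggregates(g, membership)
  if (score == "modularity") {
    return(list(value = modularity_q(g, membership, agg = agg),
                n_undefined = 0L))
  }
  vals <- vapply(agg$clusters$cluster,
                 function(S) score_cluster(g, agg, S, score), numeric(1))
  nan <- is.nan(vals)
  list(value = if (all(nan)) NaN else mean(vals[!nan]),
       n_undefined = sum(nan))
}

#' Weighted modularity of a partition
#'
#' `Q = (1/2m) * sum_ij [w_ij - d(i) d(j) / (2m)] delta(c_i, c_j)` with
#' weighted degrees `d` and total weight `m`.  Invariant under uniform
#' scaling of the weights.  Computed from the cluster aggregates as
#' `sum_S [ m_S / m - (D_S / 2m)^2 ]` where `D_S` is the total weighted
#' degree of cluster `S`.
#'
#' @inheritParams score_partition
#' @return the modularity value.
#' @export
modularity_q <- function(g, membership, agg = NULL) {
  if (is.null(agg)) agg <- cluster_aggregates(g, membership)
  if (agg$m_tilde <= 0) stop("modularity needs a graph with positive weight")
  D_S <- rowsum_safe(agg$vertices$strength, agg$vertices$cluster,
                     nrow(agg$clusters))
  sum(agg$clusters$m_tilde_S / agg$m_tilde - (D_S / (2 * agg$m_tilde))^2)
}

#' Threshold-integral weighted clustering coefficient
#'
#' For threshold `t` let `C_t` be the (global) clustering coefficient of
#' the binary graph keeping the edges of weight `>= t`.  The weighted
#' clustering coefficient is `(1/w_bar) * integral_0^w_bar C_t dt`, with
#' `w_bar` the graph's declared weight upper bound or, failing that, its
#' maximum edge weight.  The integral of the step function is computed
#' exactly as a finite sum over the sorted critical thresholds (the
#' distinct minimum edge weights of the connected triplets); thresholds at
#' which no connected triplet survives contribute 0, which keeps the value
#' within `[0, 1]`.  On a binary graph this equals the classical
#' transitivity.  Complexity `O(m + G log G)` for `G` connected triplets.
#'
#' @param g a weighted graph.
#' @param w_bar integration bound override; default as described above.
#' @return the coefficient, or `NaN` when the graph has no connected
#'   triplet at any threshold.
#' @export
weighted_clustering_coefficient <- function(g, w_bar = NULL) {
  sweep <- triplet_sweep(g)
  if (is.null(sweep)) return(NaN)
  if (is.null(w_bar)) w_bar <- weight_upper_bound(g)
  if (is.null(w_bar)) w_bar <- max(edge_weights(g))
  stopifnot(w_bar > 0)
  v <- sweep$thresholds
  v_cap <- pmin(v, w_bar)            # thresholds above w_bar add no length
  seg <- diff(c(0, v_cap))
  sum(seg * sweep$closed / sweep$total) / w_bar
}

# Enumerate connected triplets and triangles with their critical thresholds.
# A triplet centred at u over neighbours (j, h) survives at t iff
# min(w_uj, w_uh) >= t; it is closed iff additionally w_jh >= t, so its
# closed critical value is the minimum over the triangle's three weights.
# Returns, per distinct triplet critical value t: total = Gamma(t),
# closed = gamma(t) (counts of triplets/closed triplets with critical
# value >= t), or NULL when the graph has no connected triplet.
triplet_sweep <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- edge_weights(g)
  if (nrow(el) < 2) return(NULL)
  # weight lookup by pair key
  key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  ekeys <- key(el[, 1], el[, 2])
  # stacked incidence list sorted by owning vertex
  su <- c(el[, 1], el[, 2]); sv <- c(el[, 2], el[, 1]); sw <- c(w, w)
  ord <- order(su)
  sv <- sv[ord]; sw <- sw[ord]
  deg <- tabulate(su, nbins = n)
  starts <- cumsum(c(0L, deg))
  tl <- list(); cl <- list()
  for (u in which(deg >= 2L)) {
    rng <- (starts[u] + 1L):starts[u + 1L]
    nbv <- sv[rng]; nbw <- sw[rng]
    k <- deg[u]
    i1 <- rep.int(seq_len(k - 1L), (k - 1L):1L)
    i2 <- sequence((k - 1L):1L) + i1
    tmin <- pmin(nbw[i1], nbw[i2])
    pos <- match(key(nbv[i1], nbv[i2]), ekeys)
    closed <- !is.na(pos)
    tl[[length(tl) + 1L]] <- tmin
    if (any(closed)) {
      cl[[length(cl) + 1L]] <- pmin(tmin[closed], w[pos[closed]])
    }
  }
  trip_min <- unlist(tl, use.names = FALSE)
  closed_min <- unlist(cl, use.names = FALSE)
  if (length(trip_min) == 0) return(NULL)
  v <- sort(unique(trip_min))
  # counts with critical value >= v_j
  total <- length(trip_min) -
    findInterval(v, sort(trip_min), left.open = TRUE)
  closed <- length(closed_min) -
    findInterval(v, sort(closed_min), left.open = TRUE)
  list(thresholds = v, total = total, closed = closed)
}

#' Barrat's local weighted clustering coefficient
#'
#' `c_i = 1 / (s(i) (d(i) - 1)) * sum over triangles (i, j, h) of
#' (w_ij + w_ih) / 2` (ordered neighbour pairs), with `s` the weighted and
#' `d` the unweighted degree.  On any complete weighted graph this is
#' identically 1 regardless of the weights, which is why it is provided
#' only as a comparison baseline for the threshold-integral coefficient.
#'
#' @param g a weighted graph.
#' @param i a vertex id or name.
#' @return the local coefficient; `NaN` when `d(i) < 2`.
#' @export
barrat_local_coefficient <- function(g, i) {
  vid <- if (is.character(i)) match(i, igraph::V(g)$name) else as.integer(i)
  if (is.na(vid)) stop("no such vertex: ", i)
  nbv <- as.integer(igraph::neighbors(g, vid))
  if (length(nbv) < 2) return(NaN)
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  w <- edge_weights(g)
  key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  ekeys <- key(el[, 1], el[, 2])
  wi <- w[match(key(vid, nbv), ekeys)]
  k <- length(nbv)
  i1 <- rep.int(seq_len(k - 1L), (k - 1L):1L)
  i2 <- sequence((k - 1L):1L) + i1
  closed <- !is.na(match(key(nbv[i1], nbv[i2]), ekeys))
  num <- sum((wi[i1] + wi[i2])[closed])
  num / (sum(wi) * (k - 1))
}
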