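# Cluster significance: scores on the original graph vs. a switching-model
# null ensemble, summarised as relative scores and percentile ranks.

#' Percentile rank with mid-rank ties
#'
#' Position of `x` within the empirical distribution `null_scores`:
#' `(#{y < x} + 0.5 #{y = x}) / N`.
#'
#' @param x observed value.
#' @param null_scores numeric vector of null values (NaN entries dropped).
#' @return a value in `[0, 1]` (`NaN` when no defined null values).
#' @export
percentile_rank <- function(x, null_scores) {
  y <- null_scores[!is.na(null_scores)]
  if (length(y) == 0 || is.na(x)) return(NaN)
  (sum(y < x) + 0.5 * sum(y == x)) / length(y)
}

#' Significance of clusterings against the switching null model
#'
#' For each algorithm: clusters the original graph once and scores the
#' partition; then, for each of `n_null` switching-model randomizations of
#' the graph, re-clusters and re-scores.  Reports, per (algorithm, score),
#' the original value, the null-ensemble mean over defined values, the
#' relative score (original / null mean) and the percentile rank of the
#' original within the null distribution.  A significant community
#' structure shows percentile ranks close to 1 for higher-is-better scores
#' and close to 0 for lower-is-better ones.
#'
#' Degenerate partitions (a single cluster, or all singletons) are still
#' scored but flagged: external-connectivity scores are trivially optimal
#' for the one-cluster partition and carry no information.
#'
#' @param g a weighted graph.
#' @param algorithms character vector of adapter names, or a named list of
#'   functions `graph -> membership`.
#' @param scores score names from [score_specs()], or `"all"`.
#' @param n_null null-ensemble size (100 gives percentile resolution 0.01).
#' @param method switching method, see [rewire_weighted()].
#' @param T switching proposals per edge.
#' @param seed optional integer seed for the whole evaluation.
#' @return a data frame of class `score_report` with columns `algorithm`,
#'   `score`, `direction`, `original`, `null_mean`, `relative`,
#'   `percentile`, `n_null_defined`, `n_clusters`, `degenerate`.
#' @export
evaluate_significance <- function(g, algorithms = "louvain", scores = "all",
                                  n_null = 100,
                                  method = c("auto", "max_weight",
                                             "constant_variance"),
                                  T = 100, seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_null >= 1)
  specs <- score_specs(scores)
  algos <- adapter_list(algorithms)

  originals <- lapply(algos, function(f) f(g))
  null_scores <- rep(list(lapply(algos, function(.) {
    matrix(NA_real_, n_null, nrow(specs))
  })), 1)[[1]]
  for (b in seq_len(n_null)) {
    gr <- rewire_weighted(g, method = method, T = T)
    for (nm in names(algos)) {
      mem <- algos[[nm]](gr)
      agg <- cluster_aggregates(gr, mem)
      null_scores[[nm]][b, ] <- vapply(specs$score, function(sc) {
        score_partition(gr, mem, sc, agg = agg)$value
      }, numeric(1))
    }
  }

  rows <- list()
  for (nm in names(algos)) {
    mem <- originals[[nm]]
    agg <- cluster_aggregates(g, mem)
    k <- max(mem)
    degen <- k == 1 || k == igraph::vcount(g)
    for (i in seq_len(nrow(specs))) {
      sc <- specs$score[i]
      orig <- score_partition(g, mem, sc, agg = agg)$value
      nv <- null_scores[[nm]][, i]
      nv_def <- nv[!is.na(nv)]
      null_mean <- if (length(nv_def) == 0) NaN else mean(nv_def)
      rows[[length(rows) + 1L]] <- data.frame(
        algorithm = nm, score = sc, direction = specs$direction[i],
        original = orig, null_mean = null_mean,
        relative = if (!is.na(null_mean) && null_mean != 0)
          orig / null_mean else NaN,
        percentile = percentile_rank(orig, nv),
        n_null_defined = length(nv_def), n_clusters = k,
        degenerate = degen, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("score_report", "data.frame")
  out
}
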