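# Cluster stability: nonparametric vertex bootstrap with edge-weight
# perturbation.

#' Bootstrap resample of a weighted graph
#'
#' Draws `n` vertices with replacement and builds the induced graph: two
#' resampled vertices are joined iff their source vertices were adjacent,
#' with the same weight.  Copies of the same source vertex are joined into
#' a clique of heavy edges — weight equal to the graph's upper bound when
#' it has one (`duplicate_policy = "upper_bound"`), otherwise values drawn
#' uniformly from the top-quantile weights of the original edge set
#' (`"top_quantile"`) — so that clusterings are not pushed to separate a
#' vertex from its own copies.  Finally every edge weight receives
#' truncated-normal noise (mean 0, sd `noise_sd`, truncated so weights
#' stay within `[0, upper_bound]`, or `[0, Inf)` for unbounded graphs).
#'
#' @param g a weighted graph.
#' @param noise_sd perturbation scale; `"auto"` uses 0.1 times the
#'   standard deviation of the original edge weights.
#' @param duplicate_policy `"auto"` (upper bound when the graph has one,
#'   else top quantile), `"upper_bound"` or `"top_quantile"`.
#' @param top_quantile the top fraction of weights sampled for duplicate
#'   edges under the `"top_quantile"` policy.
#' @param idx optional resample index vector (defaults to a uniform draw
#'   with replacement); exposed so diagnostics can fix the resample.
#' @return a list with `graph` (vertices named `<source>.<copy>`) and
#'   `idx` (the index map replicate vertex -> source vertex).
#' @export
bootstrap_graph <- function(g, noise_sd = "auto",
                            duplicate_policy = c("auto", "upper_bound",
                                                 "top_quantile"),
                            top_quantile = 0.05, idx = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  n <- igraph::vcount(g)
  ub <- weight_upper_bound(g)
  if (duplicate_policy == "auto") {
    duplicate_policy <- if (is.null(ub)) "top_quantile" else "upper_bound"
  }
  if (duplicate_policy == "upper_bound" && is.null(ub)) {
    stop("duplicate_policy = 'upper_bound' needs a graph upper bound")
  }
  if (identical(noise_sd, "auto")) {
    w0 <- edge_weights(g)
    noise_sd <- if (length(w0) > 1) 0.1 * sd(w0) else 0
    if (is.na(noise_sd)) noise_sd <- 0
  }
  if (is.null(idx)) idx <- sample.int(n, n, replace = TRUE)

  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight",
                                             sparse = TRUE))
  B <- W[idx, idx, drop = FALSE]
  diag(B) <- 0
  # clique of heavy edges between copies of the same source vertex
  dup_sources <- unique(idx[duplicated(idx)])
  for (src in dup_sources) {
    copies <- which(idx == src)
    pairs <- t(utils::combn(copies, 2))
    wdup <- if (duplicate_policy == "upper_bound") {
      rep(ub, nrow(pairs))
    } else {
      w0 <- edge_weights(g)
      top <- w0[w0 >= stats::quantile(w0, 1 - top_quantile)]
      top[sample.int(length(top), nrow(pairs), replace = TRUE)]
    }
    B[pairs] <- wdup
    B[pairs[, c(2, 1), drop = FALSE]] <- wdup
  }
  if (noise_sd > 0) {
    ut <- which(upper.tri(B) & B > 0)
    B[ut] <- rtruncnorm_at(B[ut], noise_sd, lo = 0,
                           hi = if (is.null(ub)) Inf else ub)
    B[lower.tri(B)] <- t(B)[lower.tri(B)]
  }
  bg <- igraph::graph_from_adjacency_matrix(B, mode = "undirected",
                                            weighted = TRUE)
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(n))
  igraph::V(bg)$name <- make.unique(vn[idx], sep = ".")
  if (!is.null(ub)) bg <- igraph::set_graph_attr(bg, "upper_bound", ub)
  list(graph = bg, idx = idx)
}

# truncated-normal jitter around each mean, by inverse-CDF sampling
rtruncnorm_at <- function(mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  u <- runif(length(mean), plo, phi)
  pmin(pmax(mean + sd * qnorm(u), lo), hi)
}

#' Bootstrap stability of clusterings
#'
#' Clusters the original graph once per algorithm; then, for each of `R`
#' bootstrap-with-perturbation replicates, re-clusters and compares the
#' replicate partition to the original partition pulled back through the
#' resample map (each copy inherits its source vertex's original label).
#' Stable clusterings give small variation of information and similarity
#' indices close to 1 across replicates.  With
#' `include_null_baseline = TRUE` the same procedure runs on a
#' switching-randomized version of the graph, providing reference values
#' for networks without community structure.
#'
#' Replicates where an algorithm fails are recorded as missing; degenerate
#' replicate partitions (one cluster or all singletons) are kept in the
#' distributions but counted in the summary's `n_degenerate`.
#'
#' @param g a weighted graph.
#' @param algorithms adapter names or a named list of functions.
#' @param R number of bootstrap replicates.
#' @param measures subset of `c("vi", "ari", "nrmi")`.
#' @param include_null_baseline also run on a rewired copy of `g`.
#' @param rewire_T proposals per edge for the baseline rewiring.
#' @param omega_method table-counting method for the NRMI.
#' @param seed optional integer seed.
#' @inheritParams bootstrap_graph
#' @return a list of class `stability_report`: `replicates` (long data
#'   frame of per-replicate measure values, `baseline` flag included) and
#'   `summary` (mean per algorithm x measure x baseline, with degenerate
#'   and failed replicate counts).
#' @export
boot_stability <- function(g, algorithms = "louvain", R = 999,
                           measures = c("vi", "ari", "nrmi"),
                           noise_sd = "auto",
                           duplicate_policy = c("auto", "upper_bound",
                                                "top_quantile"),
                           top_quantile = 0.05,
                           include_null_baseline = FALSE, rewire_T = 100,
                           omega_method = "analytic", seed = NULL,
                           resample = NULL) {
  duplicate_policy <- match.arg(duplicate_policy)
  measures <- match.arg(measures, several.ok = TRUE)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(R >= 1)
  algos <- adapter_list(algorithms)

  run_one <- function(graph, baseline) {
    originals <- lapply(algos, function(f) f(graph))
    rows <- list()
    n <- igraph::vcount(graph)
    for (r in seq_len(R)) {
      idx <- if (is.null(resample)) NULL else resample(n)
      bs <- bootstrap_graph(graph, noise_sd = noise_sd,
                            duplicate_policy = duplicate_policy,
                            top_quantile = top_quantile, idx = idx)
      for (nm in names(algos)) {
        ref <- canonicalize_membership(originals[[nm]][bs$idx])
        mem <- tryCatch(unname(algos[[nm]](bs$graph)),
                        error = function(e) NULL)
        failed <- is.null(mem)
        k <- if (failed) NA_integer_ else max(mem)
        vals <- vapply(measures, function(ms) {
          if (failed) return(NA_real_)
          switch(ms,
                 vi = variation_of_information(ref, mem),
                 ari = adjusted_rand_index(ref, mem),
                 nrmi = as.numeric(reduced_mutual_information(
                   ref, mem, normalized = TRUE, method = omega_method)))
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          baseline = baseline, algorithm = nm, replicate = r,
          measure = measures, value = vals,
          degenerate = !failed && (k == 1 || k == length(mem)),
          failed = failed, stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  }

  reps <- run_one(g, baseline = FALSE)
  if (include_null_baseline) {
    reps <- rbind(reps, run_one(rewire_weighted(g, T = rewire_T),
                                baseline = TRUE))
  }
  summ <- do.call(rbind, lapply(
    split(reps, list(reps$baseline, reps$algorithm, reps$measure),
          drop = TRUE),
    function(d) data.frame(
      baseline = d$baseline[1], algorithm = d$algorithm[1],
      measure = d$measure[1], mean = mean(d$value, na.rm = TRUE),
      n = nrow(d), n_degenerate = sum(d$degenerate, na.rm = TRUE),
      n_failed = sum(d$failed), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  structure(list(replicates = reps, summary = summ),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Bootstrap stability over",
      max(x$replicates$replicate), "replicates\n")
  print(x$summary, ...)
  invisible(x)
}
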