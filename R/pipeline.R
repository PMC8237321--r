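# Config-driven analysis pipeline: one entry point tying together graph
# input, clustering adapters, significance, stability and the lambda sweep.

#' Run a configured assessment pipeline
#'
#' The configuration (a list, or a path to a JSON/YAML file) names a graph
#' source, the clustering algorithms, and which analyses to run; reports
#' are written as CSV files plus a run-metadata JSON next to them.
#'
#' Recognized fields:
#' * `graph`: path to an edge list / GraphML file, **or** a list
#'   `list(wsbm = list(sizes, lambda))` for a benchmark sample.
#' * `format`, `upper_bound`: graph input options.
#' * `algorithms`: character vector of adapter names (required).
#' * `tasks`: subset of `c("significance", "stability", "sweep")`.
#' * `seed`: integer seed (default 1).
#' * `significance`: list of overrides for [evaluate_significance()]
#'   (`n_null`, `method`, `T`).
#' * `stability`: list of overrides for [boot_stability()] (`R`,
#'   `noise_sd`, `duplicate_policy`, `include_null_baseline`).
#' * `sweep`: list of overrides for [lambda_sweep()] (`lambdas`, `n_reps`).
#' * `out_dir`: output directory (created if missing).
#'
#' @param config a list or a path to a JSON or YAML file.
#' @return (invisibly) a named list of the result data frames; CSV and
#'   metadata files are written to `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_pipeline_config(config)
  if (is.null(cfg$algorithms) || length(cfg$algorithms) == 0) {
    stop("pipeline config must name at least one clustering algorithm")
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  out_dir <- if (is.null(cfg$out_dir)) "." else cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tasks <- if (is.null(cfg$tasks)) "significance" else cfg$tasks
  stopifnot(all(tasks %in% c("significance", "stability", "sweep")))

  g <- NULL
  if (is.character(cfg$graph)) {
    fmt <- if (is.null(cfg$format)) "edgelist" else cfg$format
    g <- read_weighted_graph(cfg$graph, format = fmt,
                             upper_bound = cfg$upper_bound)
  } else if (is.list(cfg$graph) && !is.null(cfg$graph$wsbm)) {
    ws <- cfg$graph$wsbm
    spec <- if (is.null(ws$sizes)) {
      wsbm_benchmark_spec(lambda = ws$lambda)
    } else {
      wsbm_spec(unlist(ws$sizes), wsbm_benchmark_spec(1)$expectation,
                lambda = ws$lambda)
    }
    set.seed(seed)
    smp <- sample_wsbm(spec)
    g <- smp$graph
  } else if (any(tasks != "sweep")) {
    stop("pipeline config must provide a readable 'graph' source")
  }

  results <- list()
  if ("significance" %in% tasks) {
    ov <- cfg$significance
    results$significance <- evaluate_significance(
      g, algorithms = cfg$algorithms,
      n_null = ov$n_null %||% 100, method = ov$method %||% "auto",
      T = ov$T %||% 100, seed = seed)
  }
  if ("stability" %in% tasks) {
    ov <- cfg$stability
    st <- boot_stability(
      g, algorithms = cfg$algorithms, R = ov$R %||% 999,
      noise_sd = ov$noise_sd %||% "auto",
      duplicate_policy = ov$duplicate_policy %||% "auto",
      include_null_baseline = isTRUE(ov$include_null_baseline),
      seed = seed)
    results$stability <- st$summary
    results$stability_replicates <- st$replicates
  }
  if ("sweep" %in% tasks) {
    ov <- cfg$sweep
    results$sweep <- lambda_sweep(
      lambdas = unlist(ov$lambdas) %||% c(1, 5, 15, 50),
      algorithms = cfg$algorithms, n_reps = ov$n_reps %||% 20, seed = seed)
  }

  for (nm in names(results)) {
    utils::write.csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  meta <- list(seed = seed, algorithms = cfg$algorithms, tasks = tasks,
               package_version = as.character(utils::packageVersion("clustvalid")),
               written = names(results))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

load_pipeline_config <- function(config) {
  if (is.list(config)) return(config)
  stopifnot(is.character(config), length(config) == 1, file.exists(config))
  if (grepl("\\.ya?ml$", config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs needs the 'yaml' package")
    }
    yaml::read_yaml(config)
  } else {
    jsonlite::read_json(config, simplifyVector = TRUE)
  }
}
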