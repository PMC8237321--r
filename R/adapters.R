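# Clustering-algorithm adapters.  The community-detection algorithms
# themselves are igraph's implementations; adapters wrap them behind a
# uniform graph -> membership interface with canonicalized labels, so the
# assessment machinery is backend-agnostic.

adapter_registry <- local({
  reg <- list(
    louvain = list(
      fn = function(g) igraph::membership(
        igraph::cluster_louvain(g, weights = igraph::E(g)$weight)),
      stochastic = TRUE),
    leading_eigenvector = list(
      fn = function(g) igraph::membership(
        igraph::cluster_leading_eigen(g, weights = igraph::E(g)$weight)),
      stochastic = FALSE),
    label_propagation = list(
      fn = function(g) igraph::membership(
        igraph::cluster_label_prop(g, weights = igraph::E(g)$weight)),
      stochastic = TRUE),
    walktrap = list(
      fn = function(g) igraph::membership(
        igraph::cluster_walktrap(g, weights = igraph::E(g)$weight)),
      stochastic = FALSE),
    spinglass = list(
      fn = function(g) {
        if (!igraph::is_connected(g)) {
          stop("spinglass is not applicable: the graph is disconnected")
        }
        igraph::membership(
          igraph::cluster_spinglass(g, weights = igraph::E(g)$weight))
      },
      stochastic = TRUE)
  )
  function() reg
})

#' Clustering-algorithm adapter
#'
#' Returns a function `graph -> membership` with labels canonicalized to
#' `1..k` by first appearance and named by vertex.  Registered backends:
#' `louvain`, `leading_eigenvector`, `label_propagation`, `walktrap`,
#' `spinglass` (the latter requires a connected graph and reports
#' inapplicability otherwise).  A function passed in is wrapped as a
#' custom adapter.
#'
#' @param algorithm a registered name or a function `graph -> labeling`.
#' @return the adapter function, with attributes `name` and `stochastic`.
#' @export
cluster_adapter <- function(algorithm) {
  if (is.function(algorithm)) {
    fn <- algorithm
    name <- "custom"; stochastic <- NA
  } else {
    reg <- adapter_registry()
    if (!algorithm %in% names(reg)) {
      stop("unknown clustering algorithm '", algorithm, "'; registered: ",
           paste(names(reg), collapse = ", "))
    }
    fn <- reg[[algorithm]]$fn
    name <- algorithm; stochastic <- reg[[algorithm]]$stochastic
  }
  out <- function(g) {
    mem <- fn(g)
    if (length(mem) != igraph::vcount(g)) {
      stop("adapter '", name, "' did not label every vertex")
    }
    mem <- canonicalize_membership(mem)
    if (is.null(names(mem))) {
      vn <- igraph::V(g)$name
      if (!is.null(vn)) names(mem) <- vn
    }
    mem
  }
  structure(out, name = name, stochastic = stochastic)
}

#' Names of the registered clustering backends
#' @return character vector.
#' @export
registered_algorithms <- function() names(adapter_registry())

# normalize `algorithms` (names, functions, or mix) to a named adapter list
adapter_list <- function(algorithms) {
  if (is.function(algorithms)) algorithms <- list(custom = algorithms)
  if (is.character(algorithms)) {
    algorithms <- stats::setNames(as.list(algorithms), algorithms)
  }
  if (length(algorithms) == 0) stop("no clustering algorithms given")
  if (is.null(names(algorithms)) || any(!nzchar(names(algorithms)))) {
    stop("algorithm list entries must be named")
  }
  lapply(algorithms, cluster_adapter)
}
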