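# Weighted-graph data model and file I/O.
#
# Graphs are igraph objects: undirected, simple (no loops, no multi-edges),
# strictly positive edge weights in E(g)$weight (weight 0 <=> edge absent).
# An optional natural cap on weights (e.g. 1 for correlation graphs) is kept
# in the graph attribute "upper_bound".

#' Read an undirected weighted graph from a file
#'
#' Edge lists are whitespace- or comma-separated `u v [w]` lines; lines
#' starting with `#` are ignored.  A missing weight column yields a binary
#' graph (all weights 1).  Duplicate edge lines are collapsed by summing
#' their weights.  GraphML files are read through igraph and must carry a
#' real-valued `weight` edge attribute (absent attribute means weight 1).
#'
#' Self-loops and negative weights are rejected: the methods in this package
#' are defined for simple graphs with nonnegative weights only.
#'
#' @param path path to the file.
#' @param format `"edgelist"` or `"graphml"`.
#' @param upper_bound optional positive number: natural upper bound of the
#'   edge weights (stored as the graph attribute `upper_bound`).
#' @return an undirected weighted [igraph::graph] with vertex names.
#' @export
read_weighted_graph <- function(path, format = c("edgelist", "graphml"),
                                upper_bound = NULL) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum", "ignore"))
    if (is.null(igraph::E(g)$weight)) igraph::E(g)$weight <- 1
    if (is.null(igraph::V(g)$name)) {
      igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    }
    el <- igraph::as_edgelist(g, names = TRUE)
    df <- data.frame(u = el[, 1], v = el[, 2], w = igraph::E(g)$weight,
                     stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0) stop("empty edge list in '", path, "'")
    parts <- strsplit(lines, "[,[:space:]]+")
    nf <- lengths(parts)
    if (any(nf < 2 | nf > 3)) {
      stop("malformed edge list line(s): ",
           paste(utils::head(lines[nf < 2 | nf > 3], 3), collapse = " | "))
    }
    u <- vapply(parts, `[[`, "", 1L)
    v <- vapply(parts, `[[`, "", 2L)
    w <- vapply(parts, function(p) {
      if (length(p) >= 3) as.numeric(p[[3]]) else 1
    }, numeric(1))
    if (anyNA(w)) stop("non-numeric weight in edge list")
    df <- data.frame(u = u, v = v, w = w, stringsAsFactors = FALSE)
  }
  weighted_graph_from_edges(df$u, df$v, df$w, upper_bound = upper_bound)
}

#' Build a weighted graph from edge vectors
#'
#' Core constructor enforcing the package's graph invariants: undirected,
#' no self-loops, strictly positive weights, duplicate edges summed.
#'
#' @param u,v vertex names (coerced to character) of the edge endpoints.
#' @param w nonnegative edge weights; zero-weight rows are dropped.
#' @param vertices optional character vector of vertex names to include
#'   (allows isolated vertices and fixes vertex order).
#' @param upper_bound optional positive number, see [read_weighted_graph()].
#' @return an undirected weighted [igraph::graph].
#' @export
weighted_graph_from_edges <- function(u, v, w = 1, vertices = NULL,
                                      upper_bound = NULL) {
  u <- as.character(u); v <- as.character(v)
  w <- rep_len(as.numeric(w), length(u))
  if (any(w < 0)) stop("negative edge weights are not supported")
  if (any(u == v)) {
    stop("self-loop on vertex '", u[u == v][1], "' is not allowed")
  }
  keep <- w > 0
  u <- u[keep]; v <- v[keep]; w <- w[keep]
  # collapse duplicates (in either orientation) by summing weights
  a <- pmin(u, v); b <- pmax(u, v)
  key <- paste(a, b, sep = "\r")
  agg <- rowsum(w, key)
  ab <- strsplit(rownames(agg), "\r", fixed = TRUE)
  a <- vapply(ab, `[[`, "", 1L); b <- vapply(ab, `[[`, "", 2L)
  w <- as.numeric(agg)
  verts <- if (is.null(vertices)) unique(c(u, v)) else as.character(vertices)
  if (!all(c(a, b) %in% verts)) stop("edge endpoint missing from 'vertices'")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, weight = w, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  if (!is.null(upper_bound)) {
    stopifnot(is.numeric(upper_bound), upper_bound > 0)
    if (any(w > upper_bound)) {
      stop("edge weight exceeds the declared upper bound")
    }
    g <- igraph::set_graph_attr(g, "upper_bound", upper_bound)
  }
  g
}

#' Upper bound of a graph's edge weights
#'
#' Returns the graph's declared natural upper bound, or `NULL` if none.
#' @param g a weighted graph.
#' @return a positive number or `NULL`.
#' @export
weight_upper_bound <- function(g) {
  ub <- igraph::graph_attr(g, "upper_bound")
  if (is.null(ub) || is.na(ub)) NULL else ub
}

#' Is the graph binary (all weights equal 1)?
#'
#' Binary graphs trigger the unweighted-equivalence code paths: every
#' weighted score equals its unweighted counterpart exactly on them.
#' @param g a weighted graph.
#' @return logical.
#' @export
is_binary_graph <- function(g) {
  w <- edge_weights(g)
  length(w) == 0 || all(w == 1)
}

# weights with a default of 1 for unweighted igraph objects
edge_weights <- function(g) {
  w <- igraph::E(g)$weight
  if (is.null(w)) rep(1, igraph::ecount(g)) else w
}

#' Write a weighted graph as an edge list
#'
#' One `u v w` line per edge, whitespace separated.  Reading the file back
#' with [read_weighted_graph()] reproduces the same multiset of weighted
#' edges.
#'
#' @param g a weighted graph.
#' @param path output file path.
#' @export
write_weighted_graph <- function(g, path) {
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(el[, 1], el[, 2], edge_weights(g))
  write.table(df, path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a membership file
#'
#' One `vertex label` pair per line.  Labels are canonicalized to the
#' contiguous range `1..k` in order of first appearance.
#'
#' @param path path to the membership file.
#' @return a named integer vector (names = vertex names).
#' @export
read_membership <- function(path) {
  df <- read.table(path, header = FALSE, col.names = c("vertex", "label"),
                   colClasses = c("character", "character"))
  if (anyDuplicated(df$vertex)) stop("duplicate vertex in membership file")
  m <- canonicalize_membership(df$label)
  names(m) <- df$vertex
  m
}

#' Write a membership vector
#'
#' @param membership a named (vertex names) or unnamed labeling.
#' @param path output file path.
#' @param vertices vertex names, required when `membership` is unnamed.
#' @export
write_membership <- function(membership, path, vertices = names(membership)) {
  if (is.null(vertices)) vertices <- seq_along(membership)
  write.table(data.frame(vertices, as.integer(membership)), path,
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Canonicalize a partition labeling
#'
#' Relabels clusters as `1..k` by order of first appearance, so that any
#' two labelings of the same partition map to the same vector.
#'
#' @param membership any vector of cluster labels.
#' @return an integer vector with labels forming a contiguous range.
#' @export
canonicalize_membership <- function(membership) {
  if (anyNA(membership)) stop("membership contains missing labels")
  out <- match(membership, unique(membership))
  names(out) <- names(membership)
  out
}

# Align a membership vector with a graph's vertices; errors name the
# offending vertex, per the aggregate contract.
align_membership <- function(g, membership) {
  vn <- igraph::V(g)$name
  if (is.null(vn)) vn <- as.character(seq_len(igraph::vcount(g)))
  if (!is.null(names(membership))) {
    miss <- setdiff(vn, names(membership))
    if (length(miss) > 0) {
      stop("vertex '", miss[1], "' is missing from the partition")
    }
    membership <- membership[vn]
  } else if (length(membership) != igraph::vcount(g)) {
    stop("membership length ", length(membership),
         " does not match the number of vertices ", igraph::vcount(g))
  }
  canonicalize_membership(membership)
}
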