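# Partition comparison: entropy, mutual information, variation of
# information, Rand / adjusted Rand indices, reduced mutual information.
# All information measures are in nats (natural logarithm), which keeps
# the (1/n) log Omega penalty of the reduced mutual information in the
# same units as the entropies.

#' Contingency table of two partitions
#'
#' Cross-tabulates two labelings of the same vertex set.  Named vectors
#' are aligned by name; unnamed vectors are matched by position and must
#' have equal length.
#'
#' @param p1,p2 membership vectors (any label types).
#' @return an object of class `contingency_table`: list with the count
#'   matrix `counts`, row margins `a`, column margins `b`, and total `n`.
#' @export
partition_contingency <- function(p1, p2) {
  al <- align_partitions(p1, p2)
  counts <- unclass(table(al$p1, al$p2))
  dimnames(counts) <- NULL
  structure(list(counts = counts, a = rowSums(counts), b = colSums(counts),
                 n = sum(counts)), class = "contingency_table")
}

align_partitions <- function(p1, p2) {
  if (!is.null(names(p1)) && !is.null(names(p2))) {
    if (!setequal(names(p1), names(p2))) {
      stop("the two partitions label different vertex sets")
    }
    p2 <- p2[names(p1)]
  } else if (length(p1) != length(p2)) {
    stop("partitions have different lengths (", length(p1), " vs ",
         length(p2), ")")
  }
  list(p1 = canonicalize_membership(p1), p2 = canonicalize_membership(p2))
}

as_contingency <- function(x, y = NULL) {
  if (inherits(x, "contingency_table")) return(x)
  if (is.matrix(x) && is.null(y)) {
    return(structure(list(counts = x, a = rowSums(x), b = colSums(x),
                          n = sum(x)), class = "contingency_table"))
  }
  if (is.null(y)) stop("need either a contingency table or two partitions")
  partition_contingency(x, y)
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- rbind(cbind(x$counts, sum = x$a), sum = c(x$b, x$n))
  print(m, ...)
  invisible(x)
}

#' Entropy of a partition (nats)
#'
#' `H = -sum_r P(r) log P(r)` with `P(r)` the fraction of elements in
#' cluster `r`.
#'
#' @param p a membership vector.
#' @return entropy in nats.
#' @export
partition_entropy <- function(p) {
  a <- tabulate(canonicalize_membership(p))
  entropy_from_margins(a)
}

entropy_from_margins <- function(a) {
  pr <- a[a > 0] / sum(a)
  -sum(pr * log(pr))
}

#' Mutual information of two partitions (nats)
#'
#' `I = sum_rs P(r,s) log( P(r,s) / (P(r) P(s)) )` with the convention
#' `0 log 0 = 0`.  Bounded between 0 and the smaller of the two partition
#' entropies.
#'
#' @param x a `contingency_table`, a count matrix, or a membership vector.
#' @param y second membership vector when `x` is one.
#' @return mutual information in nats.
#' @export
mutual_information <- function(x, y = NULL) {
  ct <- as_contingency(x, y)
  n <- ct$n
  c_rs <- ct$counts
  pos <- c_rs > 0
  sum((c_rs[pos] / n) *
        log(c_rs[pos] * n / outer(ct$a, ct$b)[pos]))
}

#' Variation of information between two partitions (nats)
#'
#' `VI = H(p1) + H(p2) - 2 I(p1; p2)`.  A metric on the space of
#' partitions: zero iff the partitions are equal up to relabeling,
#' symmetric, and satisfying the triangle inequality.
#'
#' @param p1,p2 membership vectors (or a `contingency_table` as `p1`).
#' @return the variation of information in nats.
#' @export
variation_of_information <- function(p1, p2 = NULL) {
  ct <- as_contingency(p1, p2)
  h1 <- entropy_from_margins(ct$a)
  h2 <- entropy_from_margins(ct$b)
  max(0, h1 + h2 - 2 * mutual_information(ct))
}

#' Rand index of two partitions
#'
#' The fraction of vertex pairs classified consistently by the two
#' partitions (together in both, or separate in both), in `[0, 1]`:
#' the raw agreement count divided by `choose(n, 2)`.
#'
#' @inheritParams mutual_information
#' @return the Rand index in `[0, 1]`.
#' @export
rand_index <- function(x, y = NULL) {
  ct <- as_contingency(x, y)
  n <- ct$n
  total <- choose(n, 2)
  agreements <- total + 2 * sum(choose(ct$counts, 2)) -
    (sum(choose(ct$a, 2)) + sum(choose(ct$b, 2)))
  agreements / total
}

#' Adjusted Rand index of two partitions
#'
#' The Rand index corrected for the agreements expected between random
#' labelings with the observed margins; 1 iff the partitions are equal up
#' to relabeling, about 0 for independent labelings.
#'
#' @inheritParams mutual_information
#' @return the adjusted Rand index (at most 1).
#' @export
adjusted_rand_index <- function(x, y = NULL) {
  ct <- as_contingency(x, y)
  sum_c <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$a, 2))
  sum_b <- sum(choose(ct$b, 2))
  expected <- sum_a * sum_b / choose(ct$n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) {
    # both partitions trivial (all-one-cluster vs itself): define as 1
    return(1)
  }
  (sum_c - expected) / (maximum - expected)
}

#' Reduced mutual information of two partitions (nats)
#'
#' `RMI = I(p1; p2) - (1/n) log Omega(a, b)` where `Omega(a, b)` counts
#' the nonnegative integer matrices with the observed contingency-table
#' margins (see [count_contingency_tables()]).  The subtracted term is the
#' information needed to transmit the table itself, which deflates the
#' spuriously maximal mutual information that trivial partitions (e.g.
#' all-singletons) achieve against any partition.
#'
#' The normalized form divides by the average of `RMI(p1; p1)` and
#' `RMI(p2; p2)`, so equal partitions score 1.  It is `NaN` when both
#' partitions are the trivial one-cluster labeling (zero denominator).
#'
#' @param p1,p2 membership vectors.
#' @param normalized return NRMI instead of RMI.
#' @param method,... table-counting method and options passed to
#'   [count_contingency_tables()].
#' @return the (normalized) reduced mutual information; the `omega`
#'   attribute carries the counting details.
#' @export
reduced_mutual_information <- function(p1, p2, normalized = FALSE,
                                       method = "auto", ...) {
  ct <- partition_contingency(p1, p2)
  om <- count_contingency_tables(ct$a, ct$b, method = method, ...)
  rmi <- mutual_information(ct) - om$log_omega / ct$n
  if (!normalized) return(structure(rmi, omega = om))
  om_a <- count_contingency_tables(ct$a, ct$a, method = method, ...)
  om_b <- count_contingency_tables(ct$b, ct$b, method = method, ...)
  denom <- (entropy_from_margins(ct$a) + entropy_from_margins(ct$b) -
              (om_a$log_omega + om_b$log_omega) / ct$n) / 2
  val <- if (denom == 0) NaN else rmi / denom
  structure(val, omega = om)
}
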