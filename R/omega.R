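# Counting R x S nonnegative integer matrices with fixed margins:
# Omega(a, b) for the reduced mutual information.
#
# Three routes:
#   exact    — depth-first enumeration with memoization on the remaining
#              column margins (feasible while the enumeration bound stays
#              within ~1e7 states);
#   analytic — exact elementary closed forms when either partition has at
#              most two clusters (bounded-composition convolution), and
#              otherwise a maximum-entropy saddle-point estimate of
#              log Omega with a second-order (Edgeworth) correction;
#   mc       — hybrid estimator for tables with many unit margins: unit
#              rows/columns are pinned one at a time and each pinning
#              ratio is estimated by uniform sampling of tables with a
#              diamond-move Markov chain, the remaining core being counted
#              exactly or analytically.

#' Count contingency tables with fixed margins
#'
#' Computes or estimates `log Omega(a, b)`, the natural log of the number
#' of nonnegative integer matrices with row sums `a` and column sums `b`.
#'
#' `method = "auto"` picks `exact` when the enumeration bound permits,
#' `mc` when the margins contain many ones with a sizeable core (the
#' regime where the saddle-point estimate degrades), and `analytic`
#' otherwise.
#'
#' @param a,b nonnegative integer margin vectors with equal sums; zero
#'   margins are dropped.
#' @param method `"auto"`, `"exact"`, `"analytic"` or `"mc"`.
#' @param mc_samples Monte-Carlo samples per pinning ratio.
#' @param exact_bound state bound for `auto` to choose exact enumeration.
#' @return a list of class `omega_estimate` with `log_omega`, `method`,
#'   and `mc_error` (standard error of `log_omega`, 0 unless `mc`).
#' @examples
#' exp(count_contingency_tables(c(2, 2), c(3, 1))$log_omega)  # 2
#' @export
count_contingency_tables <- function(a, b,
                                     method = c("auto", "exact", "analytic",
                                                "mc"),
                                     mc_samples = 1e4, exact_bound = 1e7) {
  method <- match.arg(method)
  a <- as.integer(a[a > 0]); b <- as.integer(b[b > 0])
  if (sum(a) != sum(b)) stop("margins disagree: sum(a) != sum(b)")
  if (length(a) <= 1 || length(b) <= 1) {
    return(omega_result(0, "exact"))
  }
  if (method == "auto") {
    if (omega_enum_bound(a, b) <= exact_bound) {
      method <- "exact"
    } else if (mean(c(a, b) == 1) > 0.3 &&
               (sum(a > 1) >= 2 && sum(b > 1) >= 2)) {
      method <- "mc"
    } else {
      method <- "analytic"
    }
  }
  switch(method,
         exact = omega_result(omega_exact_log(a, b), "exact"),
         analytic = omega_result(omega_analytic_log(a, b), "analytic"),
         mc = omega_hybrid_mc(a, b, mc_samples = mc_samples))
}

omega_result <- function(log_omega, method, mc_error = 0) {
  structure(list(log_omega = log_omega, method = method,
                 mc_error = mc_error), class = "omega_estimate")
}

#' @export
print.omega_estimate <- function(x, ...) {
  cat("log Omega =", format(x$log_omega), "(", x$method, ")")
  if (x$mc_error > 0) cat(" +/-", format(x$mc_error))
  cat("\n")
  invisible(x)
}

# worst-case number of enumeration states: rows filled independently
omega_enum_bound <- function(a, b) {
  prod(choose(pmin(a, sum(a)) + length(b) - 1, length(b) - 1))
}

## ---- exact enumeration -------------------------------------------------

omega_exact_log <- function(a, b) {
  # orient so the recursion depth (rows) is the longer dimension and sort
  # rows descending for earlier pruning
  if (length(a) < length(b)) { tmp <- a; a <- b; b <- tmp }
  a <- sort(a, decreasing = TRUE)
  b <- sort(b, decreasing = TRUE)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  S <- length(b)
  count_rows <- function(r, rem) {
    if (r > length(a)) return(1)
    k <- paste0(r, ":", paste(rem, collapse = ","))
    hit <- memo[[k]]
    if (!is.null(hit)) return(hit)
    total <- 0
    for (comp in bounded_compositions(a[r], rem)) {
      total <- total + count_rows(r + 1L, rem - comp)
    }
    memo[[k]] <- total
    total
  }
  log(count_rows(1L, b))
}

# all vectors x >= 0 with sum(x) = total and x <= caps, as a list
bounded_compositions <- function(total, caps) {
  S <- length(caps)
  if (total > sum(caps)) return(list())
  if (S == 1) return(list(total))
  out <- list()
  lo <- max(0, total - sum(caps[-1]))
  hi <- min(total, caps[1])
  if (lo > hi) return(out)
  for (x in lo:hi) {
    for (rest in bounded_compositions(total - x, caps[-1])) {
      out[[length(out) + 1L]] <- c(x, rest)
    }
  }
  out
}

## ---- analytic ----------------------------------------------------------

omega_analytic_log <- function(a, b) {
  if (length(a) == 2 || length(b) == 2) return(omega_twomargin_log(a, b))
  omega_saddlepoint_log(a, b)
}

# S = 2 (or R = 2, by transposition symmetry): Omega equals the number of
# integer vectors 0 <= x_r <= a_r with sum x_r = b_1, an exact polynomial
# convolution.
omega_twomargin_log <- function(a, b) {
  if (length(b) != 2) { tmp <- a; a <- b; b <- tmp }
  target <- b[1]
  poly <- c(1, numeric(target))            # coefficients 0..target
  for (ar in a) {
    upto <- min(ar, target)
    # multiply by (1 + t + ... + t^upto), truncated at degree `target`
    cs <- cumsum(poly)
    shifted <- c(numeric(upto + 1), cs)[seq_len(target + 1)]
    poly <- cs - shifted
  }
  log(poly[target + 1])
}

# Maximum-entropy saddle point with Edgeworth correction.  Fit the
# geometric mean-parametrization mu_rs = z_r y_s / (1 - z_r y_s) to the
# margins, evaluate the tilted generating function, and correct the
# Gaussian fluctuation integral with the third/fourth cumulant terms.
omega_saddlepoint_log <- function(a, b) {
  R <- length(a); S <- length(b)
  z <- rep(0.5, R); y <- rep(0.5, S)
  margin_gap <- function(t, other, target) {
    sum(t * other / (1 - t * other)) - target
  }
  for (iter in 1:200) {
    for (r in seq_len(R)) {
      hi <- (1 - 1e-12) / max(y)
      z[r] <- uniroot(margin_gap, c(1e-14, hi), other = y, target = a[r],
                      tol = 1e-13)$root
    }
    for (s in seq_len(S)) {
      hi <- (1 - 1e-12) / max(z)
      y[s] <- uniroot(margin_gap, c(1e-14, hi), other = z, target = b[s],
                      tol = 1e-13)$root
    }
    q <- outer(z, y)
    mu <- q / (1 - q)
    if (max(abs(rowSums(mu) - a)) < 1e-10 &&
        max(abs(colSums(mu) - b)) < 1e-10) break
  }
  F0 <- -sum(log(1 - q)) - sum(a * log(z)) - sum(b * log(y))
  V <- mu * (1 + mu)                       # cell variances (kappa_2)
  k3 <- V * (1 + 2 * mu)                   # kappa_3
  k4 <- V * (1 + 6 * mu + 6 * mu^2)        # kappa_4
  H <- rbind(cbind(diag(rowSums(V), R), V),
             cbind(t(V), diag(colSums(V), S)))
  eg <- eigen(H, symmetric = TRUE)
  ord <- order(eg$values)
  keep <- ord[-1]                          # drop the scale-redundancy mode
  logdet <- sum(log(eg$values[keep]))
  G <- eg$vectors[, keep] %*% (t(eg$vectors[, keep]) / eg$values[keep])
  # cell directions e_r + e_s; contract cumulant tensors through G
  cells <- cbind(rep(seq_len(R), S), rep(seq_len(S), each = R))
  U <- matrix(0, nrow(cells), R + S)
  U[cbind(seq_len(nrow(cells)), cells[, 1])] <- 1
  U[cbind(seq_len(nrow(cells)), R + cells[, 2])] <- 1
  Gc <- U %*% G %*% t(U)
  gcc <- diag(Gc)
  k3v <- k3[cells]; k4v <- k4[cells]
  t4 <- sum(k4v * gcc^2)
  t3a <- as.numeric(t(k3v * gcc) %*% Gc %*% (k3v * gcc))
  t3b <- sum(outer(k3v, k3v) * Gc^3)
  corr <- 1 + t4 / 8 - t3a / 8 - t3b / 12
  F0 + 0.5 * log(R + S) - ((R + S - 1) / 2) * log(2 * pi) - 0.5 * logdet +
    log(max(corr, 1e-8))
}

## ---- hybrid Monte Carlo ------------------------------------------------

# Nested-subset estimator: rows and columns are sorted ascending; each
# unit margin is pinned to a designated heavy column (row), the pinning
# probability being estimated by uniform sampling of tables with the
# diamond-move chain; the core with margins > 1 is counted exactly or by
# the saddle point.
omega_hybrid_mc <- function(a, b, mc_samples = 1e4) {
  a <- sort(a); b <- sort(b)
  log_omega <- 0
  var_log <- 0
  repeat {
    a <- a[a > 0]; b <- b[b > 0]
    if (length(a) <= 1 || length(b) <= 1) {
      return(omega_result(log_omega, "hybrid_mc", sqrt(var_log)))
    }
    if (all(a > 1) && all(b > 1)) break
    transposed <- FALSE
    if (!any(a == 1)) { tmp <- a; a <- b; b <- tmp; transposed <- TRUE }
    ur <- which(a == 1)[1]
    target_col <- which.max(b)
    p_hat <- pin_probability(a, b, ur, target_col, mc_samples)
    log_omega <- log_omega - log(p_hat$p)
    var_log <- var_log + p_hat$var_log
    a <- a[-ur]
    b[target_col] <- b[target_col] - 1L
    if (transposed) { tmp <- a; a <- b; b <- tmp }
  }
  core <- count_contingency_tables(a, b, method = "auto",
                                   exact_bound = 1e6)
  if (identical(core$method, "mc")) {  # cannot happen: core has no units
    core <- omega_result(omega_analytic_log(a, b), "analytic")
  }
  omega_result(log_omega + core$log_omega, "hybrid_mc",
               sqrt(var_log + core$mc_error^2))
}

# P(the single unit of row `ur` lies in column `col`) under the uniform
# distribution on tables with margins (a, b), estimated by a Metropolis
# chain over diamond moves (+1/-1 on a 2x2 minor), which is uniform on
# the table polytope lattice.
pin_probability <- function(a, b, ur, col, mc_samples) {
  tab <- northwest_table(a, b)
  R <- length(a); S <- length(b)
  burn <- 20L * R * S
  thin <- max(1L, R * S %/% 2L)
  hits <- 0L
  total_steps <- burn + mc_samples * thin
  rows2 <- function() sample.int(R, 2)
  taken <- 0L
  for (step in seq_len(total_steps)) {
    rr <- rows2(); ss <- sample.int(S, 2)
    d <- if (runif(1) < 0.5) 1L else -1L
    t11 <- tab[rr[1], ss[1]] + d; t22 <- tab[rr[2], ss[2]] + d
    t12 <- tab[rr[1], ss[2]] - d; t21 <- tab[rr[2], ss[1]] - d
    if (t11 >= 0 && t22 >= 0 && t12 >= 0 && t21 >= 0) {
      tab[rr[1], ss[1]] <- t11; tab[rr[2], ss[2]] <- t22
      tab[rr[1], ss[2]] <- t12; tab[rr[2], ss[1]] <- t21
    }
    if (step > burn && (step - burn) %% thin == 0L) {
      taken <- taken + 1L
      if (tab[ur, col] == 1L) hits <- hits + 1L
    }
  }
  p <- max(hits, 1L) / taken      # guard against a zero estimate
  # effective-sample-size-naive binomial SE on log scale
  list(p = p, var_log = (1 - p) / (p * taken))
}

# greedy north-west-corner feasible table for given margins
northwest_table <- function(a, b) {
  R <- length(a); S <- length(b)
  tab <- matrix(0L, R, S)
  ra <- as.integer(a); rb <- as.integer(b)
  r <- 1L; s <- 1L
  while (r <= R && s <= S) {
    x <- min(ra[r], rb[s])
    tab[r, s] <- x
    ra[r] <- ra[r] - x; rb[s] <- rb[s] - x
    if (ra[r] == 0L) r <- r + 1L else s <- s + 1L
  }
  tab
}
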