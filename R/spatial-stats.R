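#' Global Moran's I with permutation or normal-approximation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centred
#' values and binary symmetric weights from the adjacency (optionally
#' row-standardized). The default inference is a randomization
#' (permutation) test; the alternative is the normal approximation under
#' the randomization assumption. The null expectation is `-1 / (n - 1)`.
#'
#' @param values numeric vector per unit, in adjacency id order (or named
#'   by unit id).
#' @param adj a `suburb_adjacency` (>= 3 units).
#' @param inference `"permutation"` or `"normal"`.
#' @param n_permutations number of random permutations (default 9999).
#' @param seed optional integer seed for the permutations.
#' @param row_standardize divide each unit's weights by its neighbour
#'   count.
#' @param alternative `"greater"` (clustering), `"less"` or `"two.sided"`.
#' @return a `spatial_test` list: `statistic`, `expectation`, `p_value`,
#'   `method`, and for permutation inference `n_permutations` and `seed`.
#' @export
morans_i <- function(values, adj, inference = c("permutation", "normal"),
                     n_permutations = 9999, seed = NULL,
                     row_standardize = FALSE,
                     alternative = c("greater", "less", "two.sided")) {
  inference <- match.arg(inference)
  alternative <- match.arg(alternative)
  n <- length(adj$ids)
  if (n < 3) stop("Moran's I needs at least 3 units")
  x <- if (!is.null(names(values))) as.numeric(values[adj$ids]) else as.numeric(values)
  if (length(x) != n) stop("values do not align with the adjacency")
  if (stats::var(x) == 0) stop("constant values: Moran's I is undefined")

  idx <- match(unlist(adj$nbr), adj$ids)
  from <- rep(seq_len(n), lengths(adj$nbr))
  w <- if (row_standardize) 1 / lengths(adj$nbr)[from] else rep(1, length(from))
  S0 <- sum(w)
  if (S0 == 0) stop("adjacency has no edges")

  stat_fun <- function(z) {
    zc <- z - mean(z)
    (n / S0) * sum(w * zc[from] * zc[idx]) / sum(zc^2)
  }
  I <- stat_fun(x)
  E <- -1 / (n - 1)

  if (inference == "normal") {
    # randomization variance (binary or row-standardized weights)
    zc <- x - mean(x)
    b2 <- n * sum(zc^4) / (sum(zc^2)^2)
    Wm <- matrix(0, n, n)
    Wm[cbind(from, idx)] <- w
    S1 <- 0.5 * sum((Wm + t(Wm))^2)
    S2 <- sum((rowSums(Wm) + colSums(Wm))^2)
    v <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
            b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - E^2
    z <- (I - E) / sqrt(v)
    p <- switch(alternative,
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z),
                two.sided = 2 * stats::pnorm(abs(z), lower.tail = FALSE))
    return(structure(list(statistic = I, expectation = E, p_value = p,
                          method = "normal", z = z, variance = v),
                     class = "spatial_test"))
  }

  if (!is.null(seed)) set.seed(seed)
  perm <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) perm[b] <- stat_fun(sample(x))
  p <- permutation_p(I, perm, alternative)
  structure(list(statistic = I, expectation = E, p_value = p,
                 method = "permutation", n_permutations = n_permutations,
                 seed = seed),
            class = "spatial_test")
}

permutation_p <- function(obs, perm, alternative) {
  B <- length(perm)
  pg <- (1 + sum(perm >= obs)) / (B + 1)
  pl <- (1 + sum(perm <= obs)) / (B + 1)
  switch(alternative,
         greater = pg, less = pl, two.sided = min(1, 2 * min(pg, pl)))
}

#' @export
print.spatial_test <- function(x, ...) {
  cat(sprintf("spatial test: statistic = %.4f (null expectation %.4f), p = %.4g [%s]\n",
              x$statistic, x$expectation, x$p_value, x$method))
  invisible(x)
}

#' Oden's population-adjusted spatial association statistic I_pop
#'
#' The population-adjusted Moran statistic of Oden (1995) for case counts
#' with heterogeneous area populations. It equals Moran's I computed on
#' individual-level case indicators where individuals in the same area have
#' weight 1 and individuals in adjacent areas have the areas' binary weight
#' — evaluated here in its area-level closed form. With `b` the overall
#' case rate, `d_i = x_i - b n_i` the area case excess, the statistic is
#' `[sum_(i != j) w_ij d_i d_j + sum_i (d_i^2 - x_i (1 - 2b) - n_i b^2)] /
#' (S0 b (1 - b))` with `S0 = sum_(i != j) w_ij n_i n_j + sum_i n_i (n_i - 1)`.
#' Inference is by conditional randomization: the total case count is
#' redistributed among areas multinomially with probabilities proportional
#' to population.
#'
#' @param cases non-negative integer case counts per unit (adjacency
#'   order, total >= 1).
#' @param populations positive populations per unit.
#' @param adj a `suburb_adjacency`.
#' @param n_permutations randomization replicates (default 999).
#' @param seed optional integer seed.
#' @param alternative as in [morans_i()].
#' @return a `spatial_test`.
#' @export
oden_ipop <- function(cases, populations, adj, n_permutations = 999,
                      seed = NULL,
                      alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  n <- length(adj$ids)
  stopifnot(length(cases) == n, length(populations) == n)
  if (any(populations <= 0)) stop("populations must be positive")
  if (sum(cases) < 1) stop("at least one case is required")
  idx <- match(unlist(adj$nbr), adj$ids)
  from <- rep(seq_len(n), lengths(adj$nbr))

  stat_fun <- function(x) {
    Ntot <- sum(populations)
    b <- sum(x) / Ntot
    d <- x - b * populations
    cross <- sum(d[from] * d[idx])                 # binary between-area weights
    within <- sum(d^2 - x * (1 - 2 * b) - populations * b^2)
    S0 <- sum(populations[from] * populations[idx]) +
      sum(populations * (populations - 1))
    (cross + within) / (S0 * b * (1 - b))
  }
  I <- stat_fun(cases)
  if (!is.null(seed)) set.seed(seed)
  pr <- populations / sum(populations)
  perm <- numeric(n_permutations)
  for (bb in seq_len(n_permutations)) {
    perm[bb] <- stat_fun(as.numeric(stats::rmultinom(1, sum(cases), pr)))
  }
  p <- permutation_p(I, perm, alternative)
  structure(list(statistic = I, expectation = mean(perm), p_value = p,
                 method = "conditional randomization",
                 n_permutations = n_permutations, seed = seed),
            class = "spatial_test")
}

#' Brute-force oracle for Oden's I_pop
#'
#' Literally expands every person into a binary case indicator and computes
#' the individual-level Moran statistic with the implied weight matrix
#' (same-area pairs weight 1, adjacent-area pairs the areas' weight). Only
#' feasible for small total populations; used to validate [oden_ipop()].
#'
#' @inheritParams oden_ipop
#' @return the statistic (a scalar).
#' @export
oden_ipop_direct <- function(cases, populations, adj) {
  n <- length(adj$ids)
  stopifnot(length(cases) == n, length(populations) == n)
  area <- rep(seq_len(n), populations)
  y <- unlist(lapply(seq_len(n), function(i) {
    c(rep(1, cases[i]), rep(0, populations[i] - cases[i]))
  }))
  Ntot <- length(y)
  W <- adjacency_matrix(adj)
  A <- matrix(0, Ntot, Ntot)
  for (k in seq_len(Ntot)) {
    for (l in seq_len(Ntot)) {
      if (k == l) next
      A[k, l] <- if (area[k] == area[l]) 1 else W[area[k], area[l]]
    }
  }
  z <- y - mean(y)
  (Ntot / sum(A)) * as.numeric(t(z) %*% A %*% z) / sum(z^2)
}

#' Pearson product-moment correlation
#'
#' @param x,y paired numeric vectors (>= 3 pairs, both non-constant).
#' @return the correlation coefficient.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3) stop("at least 3 paired values are required")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant vector")
  stats::cor(x, y)
}
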