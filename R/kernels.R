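# Kernel and distance machinery behind HSIC, distance covariance, and the
# kernel-based conditional-independence tests.

# Squared Euclidean distance matrix between rows of x (vector = 1 column).
sq_dist_matrix <- function(x) {
  x <- as.matrix(x)
  sq <- rowSums(x^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

#' Median-heuristic kernel bandwidth
#'
#' The median of the pairwise Euclidean distances between observations,
#' estimated on at most `max_pairs` seeded sampled pairs for large n. A zero
#' median (e.g. constant input) falls back to bandwidth 1.
#'
#' @param x numeric vector or matrix (rows = observations).
#' @param max_pairs cap on the number of pairs examined.
#' @param seed seed for the pair subsample.
#' @return A positive scalar bandwidth.
#' @export
median_bandwidth <- function(x, max_pairs = 1000L, seed = 1L) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 2L) return(1)
  npairs <- n * (n - 1) / 2
  if (npairs <= max_pairs) {
    d <- stats::dist(x)
    med <- stats::median(d)
  } else {
    ij <- with_seed(seed, {
      i <- sample.int(n, max_pairs, replace = TRUE)
      j <- sample.int(n - 1L, max_pairs, replace = TRUE)
      j <- ifelse(j >= i, j + 1L, j)
      cbind(i, j)
    })
    d <- sqrt(rowSums((x[ij[, 1L], , drop = FALSE] -
                       x[ij[, 2L], , drop = FALSE])^2))
    med <- stats::median(d)
  }
  if (!is.finite(med) || med <= 0) 1 else med
}

gaussian_kernel <- function(x, bandwidth) {
  exp(-sq_dist_matrix(x) / (2 * bandwidth^2))
}

# Double-centering: HMH with H = I - (1/n) 11'.
double_center <- function(m) {
  rm <- rowMeans(m)
  cm <- colMeans(m)
  sweep(sweep(m, 1L, rm), 2L, cm) + mean(m)
}

#' Hilbert-Schmidt independence criterion (biased V-statistic)
#'
#' `trace(K H L H) / n^2` with Gaussian kernels K on `x` and L on `y` and the
#' centering matrix `H = I - 11'/n`. Zero iff empirical independence in the
#' RKHS sense; bandwidths default to the median pairwise-distance heuristic.
#'
#' @param x,y numeric vectors or matrices with `n` rows each.
#' @param bandwidth_x,bandwidth_y optional positive kernel bandwidths.
#' @return Non-negative scalar HSIC estimate.
#' @export
hsic_statistic <- function(x, y, bandwidth_x = NULL, bandwidth_y = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 2L || nrow(y) != n)
    validation_error("hsic_statistic needs matching n >= 2 observations")
  bx <- bandwidth_x %||% median_bandwidth(x)
  by <- bandwidth_y %||% median_bandwidth(y)
  stopifnot_scalar_number(bx, "bandwidth_x", lower = 0, strict = TRUE)
  stopifnot_scalar_number(by, "bandwidth_y", lower = 0, strict = TRUE)
  Kc <- double_center(gaussian_kernel(x, bx))
  Lc <- double_center(gaussian_kernel(y, by))
  max(sum(Kc * Lc) / n^2, 0)
}

#' Squared sample distance covariance
#'
#' `V^2_n(x, y)`: the mean elementwise product of the double-centered
#' Euclidean distance matrices of `x` and `y`.
#'
#' @param x,y numeric vectors or matrices with `n` rows each.
#' @return Non-negative scalar.
#' @export
dcov_statistic <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  n <- nrow(x)
  if (n < 2L || nrow(y) != n)
    validation_error("dcov_statistic needs matching n >= 2 observations")
  Ac <- double_center(as.matrix(stats::dist(x)))
  Bc <- double_center(as.matrix(stats::dist(y)))
  max(sum(Ac * Bc) / n^2, 0)
}

#' Sample distance correlation
#' @param x,y numeric vectors or matrices with `n` rows each.
#' @return Scalar in `[0, 1]` (0 when either distance variance vanishes).
#' @export
dcor_statistic <- function(x, y) {
  vxy <- dcov_statistic(x, y)
  vx <- dcov_statistic(x, x)
  vy <- dcov_statistic(y, y)
  if (vx * vy <= 0) return(0)
  sqrt(vxy / sqrt(vx * vy))
}

# Two-moment gamma null for a statistic sum(Ac * Bc)/n^2 built from
# double-centered matrices Ac, Bc. The permutation-null mean is
# tr(Ac) tr(Bc) / (n^2 (n-1)); the variance uses the classic HSIC gamma-test
# approximation. Returns NULL when the fit is degenerate.
gamma_null_pvalue <- function(stat, Ac, Bc, n) {
  mean0 <- sum(diag(Ac)) * sum(diag(Bc)) / (n^2 * (n - 1))
  prod2 <- (Ac * Bc)^2
  off_sum <- sum(prod2) - sum(diag(prod2))
  var0 <- 2 * (n - 4) * (n - 5) / (n * (n - 1) * (n - 2) * (n - 3)) *
    off_sum / (n * (n - 1))
  var0 <- max(var0, 1e-12)
  if (!is.finite(mean0) || !is.finite(var0) || mean0 <= 0)
    return(NULL)
  shape <- mean0^2 / var0
  scale <- var0 / mean0
  stats::pgamma(stat, shape = shape, scale = scale, lower.tail = FALSE)
}

# Permutation p-value for the same statistic: permute the second block,
# add-one estimator (1 + #{perm >= obs}) / (1 + B).
perm_null_pvalue <- function(stat, Ac, Bc, n, B, seed) {
  perms <- with_seed(seed, replicate(B, sample.int(n), simplify = FALSE))
  count <- 0L
  for (p in perms) {
    s <- sum(Ac * Bc[p, p]) / n^2
    if (s >= stat - 1e-15) count <- count + 1L
  }
  (1 + count) / (1 + B)
}
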