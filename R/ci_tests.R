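#' Conditional-independence tester specification
#'
#' A named CI test plus its parameters, pluggable into [pc_skeleton()].
#' Available methods:
#' \describe{
#'   \item{gauss}{partial correlation + Fisher z under a joint-Gaussian
#'     assumption; fastest, linear relationships only.}
#'   \item{hsic.gamma / hsic.perm}{HSIC with a two-moment gamma null or a
#'     seeded permutation null; conditioning by kernel ridge residualization.}
#'   \item{dcc.gamma / dcc.perm}{distance covariance with the same two null
#'     options and the same conditioning scheme.}
#'   \item{rcit / rcot}{random-Fourier-feature approximations of the kernel
#'     conditional-independence test; p-values from a Hall-Buckley-Eagleson
#'     weighted-chi-square approximation.}
#'   \item{oracle}{d-separation on a known DAG (`dag` argument); for
#'     benchmarking only.}
#' }
#'
#' @param method test name (see above).
#' @param B permutation count for the `.perm` variants (at least 19).
#' @param f_xy,f_z random Fourier feature counts for rcit/rcot.
#' @param ridge ridge penalty of the kernel regression used to residualize on
#'   the conditioning set for hsic/dcc tests.
#' @param seed integer seed; every random ingredient (permutations, Fourier
#'   features) is derived deterministically from it and the tested indices.
#' @param dag adjacency matrix of the true DAG, `method = "oracle"` only.
#' @return A `ci_tester` object.
#' @export
ci_tester <- function(method = c("gauss", "hsic.gamma", "hsic.perm",
                                 "dcc.gamma", "dcc.perm", "rcit", "rcot",
                                 "oracle"),
                      B = 100L, f_xy = 5L, f_z = 25L, ridge = 1e-3,
                      seed = 1L, dag = NULL) {
  method <- match.arg(method)
  if (grepl("perm$", method) && B < 19L)
    validation_error("permutation tests require B >= 19")
  if (method %in% c("rcit", "rcot") && (f_xy < 1L || f_z < 1L))
    validation_error("rcit/rcot require at least one Fourier feature")
  if (method == "oracle" && is.null(dag))
    validation_error("oracle tester requires the true DAG adjacency")
  structure(list(method = method, B = as.integer(B), f_xy = as.integer(f_xy),
                 f_z = as.integer(f_z), ridge = ridge,
                 seed = as.integer(seed), dag = dag),
            class = "ci_tester")
}

ci_result <- function(statistic, p_value, method, cond_size, n_used,
                      warning = NULL) {
  list(statistic = statistic, p_value = min(max(p_value, 0), 1),
       method = method, cond_size = as.integer(cond_size),
       n_used = as.integer(n_used), warning = warning)
}

standardize_cols <- function(m) {
  m <- as.matrix(m)
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  sweep(sweep(m, 2L, mu), 2L, sdv, "/")
}

#' Run a conditional-independence test
#'
#' Tests `X_i` independent of `X_j` given the columns `S`, dispatching on the
#' tester's method. All statistics are computed after per-column
#' standardization.
#'
#' @param tester a [ci_tester()].
#' @param data numeric matrix, observations as rows, variables as columns.
#' @param i,j column indices of the tested pair.
#' @param S integer vector of conditioning column indices (possibly empty).
#' @return A list: `statistic`, `p_value`, `method`, `cond_size`, `n_used`,
#'   `warning`.
#' @export
ci_test <- function(tester, data, i, j, S = integer(0)) {
  stopifnot(inherits(tester, "ci_tester"))
  S <- setdiff(as.integer(S), c(i, j))
  if (i == j) validation_error("i and j must differ")
  if (tester$method == "oracle")
    return(oracle_ci_test(tester$dag, i, j, S))
  n <- nrow(data)
  if (n <= length(S) + 3L)
    validation_error("need n > |S| + 3 observations")
  switch(tester$method,
    gauss = gauss_ci_test(data, i, j, S),
    rcit = ,
    rcot = rcot_test(data, i, j, S, variant = tester$method, params = tester),
    hsic.gamma = ,
    hsic.perm = hsic_test(data, i, j, S,
                          variant = sub("^hsic\\.", "", tester$method),
                          params = tester),
    dcc.gamma = ,
    dcc.perm = dcov_test(data, i, j, S,
                         variant = sub("^dcc\\.", "", tester$method),
                         params = tester)
  )
}

#' Partial-correlation (Fisher z) conditional-independence test
#'
#' Computes the partial correlation of columns `i` and `j` given `S` by
#' inverting the correlation matrix of the involved columns, then the Fisher
#' z statistic `sqrt(n - |S| - 3) * atanh(r)` with a two-sided standard
#' normal p-value.
#'
#' @inheritParams ci_test
#' @return A CI test result list.
#' @export
gauss_ci_test <- function(data, i, j, S = integer(0)) {
  S <- setdiff(as.integer(S), c(i, j))
  n <- nrow(data)
  if (n <= length(S) + 3L) validation_error("need n > |S| + 3 observations")
  cols <- c(i, j, S)
  cm <- stats::cor(data[, cols, drop = FALSE])
  cm[!is.finite(cm)] <- 0; diag(cm) <- 1
  warn <- NULL
  P <- tryCatch(solve(cm), error = function(e) NULL)
  if (is.null(P)) {
    P <- solve(cm + diag(1e-8, nrow(cm)))
    warn <- "singular conditioning correlation matrix; regularized inverse"
  }
  r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  r <- min(max(r, -1 + 1e-12), 1 - 1e-12)
  z <- sqrt(n - length(S) - 3) * atanh(r)
  p <- 2 * stats::pnorm(-abs(z))
  ci_result(z, p, "gauss", length(S), n, warn)
}

# Kernel ridge regression residuals of v on the conditioning block S
# (Gaussian kernel, median-heuristic bandwidth). Deterministic.
krr_residuals <- function(v, Sdata, ridge = 1e-3) {
  n <- length(v)
  Ks <- gaussian_kernel(Sdata, median_bandwidth(Sdata))
  fit <- Ks %*% solve(Ks + diag(n * ridge, n), v)
  as.numeric(v - fit)
}

# Shared body of the HSIC and distance-covariance CI tests: residualize on S
# when needed, build double-centered kernel/distance matrices, then apply the
# gamma or permutation null.
kernel_ci_test <- function(data, i, j, S, variant, params, centered_fn,
                           method_tag) {
  n <- nrow(data)
  if (grepl("perm", variant) && params$B < 19L)
    validation_error("permutation tests require B >= 19")
  x <- standardize_cols(data[, i, drop = FALSE])[, 1L]
  y <- standardize_cols(data[, j, drop = FALSE])[, 1L]
  warn <- NULL
  if (length(S) > 0L) {
    Sdata <- standardize_cols(data[, S, drop = FALSE])
    x <- krr_residuals(x, Sdata, params$ridge)
    y <- krr_residuals(y, Sdata, params$ridge)
    x <- as.numeric(scale(x)); x[!is.finite(x)] <- 0
    y <- as.numeric(scale(y)); y[!is.finite(y)] <- 0
  }
  Ac <- centered_fn(x)
  Bc <- centered_fn(y)
  stat <- max(sum(Ac * Bc) / n^2, 0)
  seed <- derive_seed(params$seed, i, j, sum(S))
  if (variant == "gamma") {
    p <- gamma_null_pvalue(stat, Ac, Bc, n)
    if (is.null(p)) {
      warn <- "degenerate gamma fit; fell back to permutation null"
      p <- perm_null_pvalue(stat, Ac, Bc, n, params$B, seed)
    }
  } else {
    p <- perm_null_pvalue(stat, Ac, Bc, n, params$B, seed)
  }
  ci_result(stat, p, paste0(method_tag, ".", variant), length(S), n, warn)
}

#' HSIC conditional-independence test (gamma or permutation null)
#'
#' Unconditionally, the statistic is [hsic_statistic()] of the two columns.
#' With a non-empty conditioning set, each tested column is first replaced by
#' its residual from a kernel ridge regression on the `S` columns. The gamma
#' variant fits a two-moment gamma to the permutation null; the perm variant
#' permutes one argument `B` times with the add-one p-value estimator.
#'
#' @inheritParams ci_test
#' @param variant `"gamma"` or `"perm"`.
#' @param params a [ci_tester()] carrying `B`, `ridge`, and `seed`.
#' @return A CI test result list.
#' @export
hsic_test <- function(data, i, j, S = integer(0), variant = c("gamma", "perm"),
                      params = ci_tester("hsic.gamma")) {
  variant <- match.arg(variant)
  centered <- function(v) {
    double_center(gaussian_kernel(v, median_bandwidth(as.matrix(v))))
  }
  kernel_ci_test(data, i, j, setdiff(as.integer(S), c(i, j)), variant, params,
                 centered, "hsic")
}

#' Distance-covariance conditional-independence test
#'
#' As [hsic_test()] but with the squared sample distance covariance (double-
#' centered Euclidean distance matrices) as the statistic.
#'
#' @inheritParams hsic_test
#' @return A CI test result list.
#' @export
dcov_test <- function(data, i, j, S = integer(0), variant = c("gamma", "perm"),
                      params = ci_tester("dcc.gamma")) {
  variant <- match.arg(variant)
  centered <- function(v) double_center(as.matrix(stats::dist(v)))
  kernel_ci_test(data, i, j, setdiff(as.integer(S), c(i, j)), variant, params,
                 centered, "dcc")
}

# Random Fourier features of a Gaussian kernel with median-heuristic
# bandwidth; seeded, so identical calls give identical features.
fourier_features <- function(x, num_f, seed) {
  x <- standardize_cols(x)
  d <- ncol(x)
  bw <- median_bandwidth(x)
  with_seed(seed, {
    W <- matrix(stats::rnorm(d * num_f), d, num_f) / bw
    b <- stats::runif(num_f, 0, 2 * pi)
    sqrt(2 / num_f) * cos(sweep(x %*% W, 2L, b, "+"))
  })
}

# OLS residuals of each feature column on the conditioning features.
linear_residuals <- function(F, Z) {
  qrz <- qr(cbind(1, Z))
  F - qr.fitted(qrz, F)
}

# Hall-Buckley-Eagleson tail probability for a positively weighted sum of
# independent chi-square(1) variables.
hbe_pvalue <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0L) return(1)
  k1 <- sum(lambda); k2 <- 2 * sum(lambda^2); k3 <- 8 * sum(lambda^3)
  if (k3 <= 0 || k2 <= 0)
    return(stats::pchisq(q / (k1 / length(lambda)), df = length(lambda),
                         lower.tail = FALSE))
  a <- k3 / (4 * k2)
  nu <- 8 * k2^3 / k3^2
  stats::pchisq((q - k1) / a + nu, df = nu, lower.tail = FALSE)
}

#' Random-Fourier-feature conditional-independence test (RCIT / RCoT)
#'
#' Maps the tested columns (and the conditioning set) to random Fourier
#' features of Gaussian kernels, removes the conditioning features from the
#' tested features by linear regression, and tests the residual
#' cross-covariance: statistic `n * ||cov||_F^2`, p-value from the
#' Hall-Buckley-Eagleson weighted-chi-square approximation. RCoT
#' residualizes the features of both tested variables on the `S` features;
#' RCIT instead builds the second variable's features on the concatenation
#' `(X_j, S)` before residualizing (the published asymmetric scheme). With an
#' empty `S` both variants coincide.
#'
#' @inheritParams ci_test
#' @param variant `"rcit"` or `"rcot"`.
#' @param params a [ci_tester()] carrying `f_xy`, `f_z`, and `seed`.
#' @return A CI test result list.
#' @export
rcot_test <- function(data, i, j, S = integer(0), variant = c("rcot", "rcit"),
                      params = ci_tester("rcot")) {
  variant <- match.arg(variant)
  S <- setdiff(as.integer(S), c(i, j))
  n <- nrow(data)
  if (params$f_xy < 1L || params$f_z < 1L)
    validation_error("rcit/rcot require at least one Fourier feature")
  seed <- derive_seed(params$seed, i, j, sum(S))
  fx <- fourier_features(data[, i, drop = FALSE], params$f_xy, seed + 1L)
  ycols <- if (variant == "rcit" && length(S) > 0L) c(j, S) else j
  fy <- fourier_features(data[, ycols, drop = FALSE], params$f_xy, seed + 2L)
  if (length(S) > 0L) {
    fz <- fourier_features(data[, S, drop = FALSE], params$f_z, seed + 3L)
    fx <- linear_residuals(fx, fz)
    fy <- linear_residuals(fy, fz)
  }
  fx <- sweep(fx, 2L, colMeans(fx))
  fy <- sweep(fy, 2L, colMeans(fy))
  Cxy <- crossprod(fx, fy) / n
  stat <- n * sum(Cxy^2)
  # Null: n * vec(Cxy) is asymptotically a weighted sum of chi-square(1);
  # the weights are eigenvalues of the covariance of the feature products.
  prods <- matrix(0, n, ncol(fx) * ncol(fy))
  k <- 1L
  for (a in seq_len(ncol(fx))) {
    for (b in seq_len(ncol(fy))) {
      prods[, k] <- fx[, a] * fy[, b]
      k <- k + 1L
    }
  }
  lambda <- eigen(stats::cov(prods), symmetric = TRUE,
                  only.values = TRUE)$values
  p <- hbe_pvalue(stat, lambda)
  ci_result(stat, p, variant, length(S), n, NULL)
}
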