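#' Random DAG model for benchmarking
#'
#' Samples a random topological order of `p` nodes and includes each forward
#' pair independently with probability `expected_degree / (p - 1)`, so the
#' expected number of edges is `p * expected_degree / 2` and the graph is
#' acyclic by construction. Edge coefficients have magnitude in
#' `[0.5, 2]` with random sign; nonlinear mechanisms draw an edge function
#' from tanh, square, and sine.
#'
#' @param p number of nodes.
#' @param expected_degree expected total degree per node, `< p - 1`.
#' @param mechanism `"linear"` or `"nonlinear"` structural equations.
#' @param noise_sd standard deviation of the additive Gaussian noise at
#'   non-root nodes; root nodes are unit-variance Gaussian sources.
#' @param dropout_rate Bernoulli zeroing probability in `[0, 1)`.
#' @param seed integer seed.
#' @return A `synthetic_model`: `dag` (0/1 adjacency, `dag[a,b]=1` for
#'   `a -> b`), `weights`, `functions`, `mechanism`, `noise_sd`,
#'   `dropout_rate`, `nodes`, `seed`.
#' @export
random_dag <- function(p, expected_degree, mechanism = c("linear", "nonlinear"),
                       noise_sd = 0.5, dropout_rate = 0, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (p < 2L) validation_error("need at least two nodes")
  stopifnot_scalar_number(expected_degree, "expected_degree", lower = 0,
                          strict = TRUE)
  if (expected_degree >= p - 1)
    validation_error("expected_degree must be below p - 1")
  stopifnot_scalar_number(dropout_rate, "dropout_rate", lower = 0, upper = 1)
  if (dropout_rate >= 1) validation_error("dropout_rate must be below 1")
  nodes <- sprintf("G%02d", seq_len(p))
  prob <- expected_degree / (p - 1)
  with_seed(seed, {
    ord <- sample.int(p)
    dag <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    weights <- matrix(0, p, p)
    funs <- matrix("", p, p)
    for (a in seq_len(p - 1L)) {
      for (b in seq(a + 1L, p)) {
        if (stats::runif(1) < prob) {
          src <- ord[a]; dst <- ord[b]
          dag[src, dst] <- 1L
          weights[src, dst] <- sample(c(-1, 1), 1L) * stats::runif(1, 0.5, 2)
          funs[src, dst] <- sample(c("tanh", "square", "sine"), 1L)
        }
      }
    }
    structure(list(dag = dag, weights = weights, functions = funs,
                   mechanism = mechanism, noise_sd = noise_sd,
                   dropout_rate = dropout_rate, nodes = nodes,
                   seed = as.integer(seed)),
              class = "synthetic_model")
  })
}

#' @export
print.synthetic_model <- function(x, ...) {
  cat(sprintf("<synthetic_model> %d nodes, %d edges, %s mechanism\n",
              length(x$nodes), sum(x$dag), x$mechanism))
  invisible(x)
}

edge_function <- function(name) {
  switch(name,
         tanh = tanh,
         square = function(v) v^2,
         sine = function(v) sin(v),
         identity)
}

#' Simulate observations from a structural-equation model
#'
#' Generates `n` samples in topological order: each node is the sum of its
#' parents' contributions (`w * x` for linear models, `w * g(x)` with the
#' edge's sampled nonlinearity otherwise) plus Gaussian noise. Columns are
#' standardized to zero mean and unit variance.
#'
#' @param model a [random_dag()] model.
#' @param n number of samples (>= 2).
#' @param seed integer seed (default: the model's).
#' @return Numeric matrix `n x p` with the model's node ids as column names.
#' @export
simulate_sem <- function(model, n, seed = model$seed) {
  stopifnot(inherits(model, "synthetic_model"))
  if (n < 2L) validation_error("need n >= 2 samples")
  p <- length(model$nodes)
  ord <- topological_order(model$dag)
  with_seed(seed, {
    x <- matrix(0, n, p, dimnames = list(NULL, model$nodes))
    for (j in ord) {
      parents <- which(model$dag[, j] == 1L)
      # roots are unit-variance sources; children get the structural noise
      val <- stats::rnorm(n, sd = if (length(parents)) model$noise_sd else 1)
      for (a in parents) {
        contrib <- if (model$mechanism == "linear") x[, a]
                   else edge_function(model$functions[a, j])(x[, a])
        val <- val + model$weights[a, j] * contrib
      }
      x[, j] <- val
    }
    standardize_cols(x)
  })
}

topological_order <- function(dag) {
  p <- nrow(dag)
  indeg <- colSums(dag)
  order <- integer(0)
  remaining <- rep(TRUE, p)
  while (any(remaining)) {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0L) validation_error("adjacency is not acyclic")
    nxt <- src[1L]
    order <- c(order, nxt)
    remaining[nxt] <- FALSE
    indeg <- indeg - dag[nxt, ]
    indeg[!remaining] <- Inf
    indeg[nxt] <- Inf
  }
  order
}

#' Apply scRNA-seq-style dropout
#'
#' Sets each entry independently to zero with probability `rate` (uniform
#' Bernoulli zeroing). An expression-dependent variant zeroes low values
#' preferentially via a logistic function of the value.
#'
#' @param data numeric matrix.
#' @param rate dropout probability in `[0, 1)`.
#' @param seed integer seed.
#' @param dependent if `TRUE`, the zeroing probability decreases with the
#'   entry's magnitude (logistic), with mean rate calibrated near `rate`.
#' @return A list: `data` (with zeros) and logical `mask` of dropped entries.
#' @export
apply_dropout <- function(data, rate, seed = 1L, dependent = FALSE) {
  stopifnot_scalar_number(rate, "rate", lower = 0, upper = 1)
  if (rate >= 1) validation_error("rate must be below 1")
  if (rate == 0)
    return(list(data = data, mask = matrix(FALSE, nrow(data), ncol(data))))
  with_seed(seed, {
    if (!dependent) {
      mask <- matrix(stats::runif(length(data)) < rate, nrow(data))
    } else {
      pr <- stats::plogis(-abs(data))
      pr <- pr * rate / mean(pr)
      mask <- matrix(stats::runif(length(data)) < pr, nrow(data))
    }
    out <- data
    out[mask] <- 0
    list(data = out, mask = mask)
  })
}

#' Evaluate an inferred network against the generating model
#'
#' Adjacency precision/recall/F1 against the DAG's skeleton; directed
#' precision/recall computed only over edges the inferred CPDAG orients; and
#' the structural Hamming distance to the true CPDAG of the DAG.
#'
#' @param inferred a [causal_network()].
#' @param model a [random_dag()] model with the same node set.
#' @return A list: `precision`, `recall`, `f1`, `directed_precision`,
#'   `directed_recall`, `shd_to_truth`.
#' @export
evaluate_network <- function(inferred, model) {
  stopifnot(inherits(model, "synthetic_model"))
  if (!setequal(inferred$nodes, model$nodes))
    validation_error("node sets differ")
  truth_pairs <- which(model$dag == 1L, arr.ind = TRUE)
  truth_keys <- pair_key(model$nodes[truth_pairs[, 1L]],
                         model$nodes[truth_pairs[, 2L]])
  inf_keys <- adjacency_keys(inferred)
  overlap <- length(intersect(inf_keys, truth_keys))
  precision <- if (length(inf_keys) == 0L) {
    warning("empty inferred network; precision defined as 1")
    1
  } else overlap / length(inf_keys)
  recall <- if (length(truth_keys) == 0L) 1 else overlap / length(truth_keys)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  dir_e <- inferred$edges[inferred$edges$directed, , drop = FALSE]
  if (nrow(dir_e) > 0L) {
    correct <- mapply(function(f, t) model$dag[f, t] == 1L, dir_e$from,
                      dir_e$to)
    directed_precision <- mean(correct)
  } else directed_precision <- NA_real_
  true_dir <- sum(model$dag)
  directed_recall <- if (true_dir == 0L) NA_real_ else {
    if (nrow(dir_e) == 0L) 0 else sum(mapply(
      function(f, t) model$dag[f, t] == 1L, dir_e$from, dir_e$to)) / true_dir
  }
  list(precision = precision, recall = recall, f1 = f1,
       directed_precision = directed_precision,
       directed_recall = directed_recall,
       shd_to_truth = shd(inferred, true_cpdag(model$dag)))
}

#' Serialize a synthetic model as JSON
#' @param model a [random_dag()] model.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_synthetic_model <- function(model, path) {
  jsonlite::write_json(list(
    nodes = model$nodes, dag = model$dag, weights = model$weights,
    functions = model$functions, mechanism = model$mechanism,
    noise_sd = model$noise_sd, dropout_rate = model$dropout_rate,
    seed = model$seed), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Simulated data as an expression-style matrix
#'
#' Wraps [simulate_sem()] output (optionally after dropout) as a gene-by-cell
#' [expression_matrix()] so every pipeline stage can run on synthetic data.
#' The standardized values are tagged `zscore`.
#'
#' @param model a [random_dag()] model.
#' @param n number of cells.
#' @param seed integer seed.
#' @param dropout apply the model's dropout rate first.
#' @return An [expression_matrix()] (genes = model nodes, cells = samples).
#' @export
synthetic_expression <- function(model, n, seed = model$seed, dropout = TRUE) {
  x <- simulate_sem(model, n, seed = seed)
  if (dropout && model$dropout_rate > 0)
    x <- apply_dropout(x, model$dropout_rate, seed = derive_seed(seed, 77L))$data
  m <- t(x)
  colnames(m) <- sprintf("cell%04d", seq_len(n))
  expression_matrix(m, transform = "zscore")
}
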