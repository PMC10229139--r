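ranking_result <- function(genes, scores, method, response_genes) {
  structure(list(genes = genes,
                 scores = stats::setNames(scores, genes),
                 method = method, response_genes = response_genes),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, ...) {
  cat(sprintf("<feature_ranking> %s: %d genes for response {%s}\n",
              x$method, length(x$genes),
              paste(x$response_genes, collapse = ", ")))
  invisible(x)
}

# Cells-as-rows data for the response block and candidate columns.
fs_prepare <- function(m, response_genes, k) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!all(response_genes %in% gene_ids(m)))
    validation_error("response gene(s) absent from the matrix: ",
                     paste(setdiff(response_genes, gene_ids(m)), collapse = ", "))
  candidates <- setdiff(gene_ids(m), response_genes)
  if (length(candidates) < 2L) validation_error("need at least two candidates")
  if (k >= length(candidates))
    validation_error("k must be below the candidate count ", length(candidates))
  x <- t(m$values)  # cells x genes
  list(x = x, candidates = candidates,
       y = x[, response_genes, drop = FALSE])
}

#' BAHSIC feature selection (backward elimination on HSIC)
#'
#' Ranks candidate genes by their dependence on one or several response
#' genes. Each round scores every remaining gene by the HSIC between that
#' gene and the (possibly multivariate) response, then removes the
#' lowest-scoring `ceiling(elimination_fraction * remaining)` genes. The
#' final ranking is the reverse removal order; the top `k` genes are
#' returned. Per-gene kernel matrices and the response kernel are fixed per
#' run (median-heuristic bandwidths), so the procedure is deterministic
#' given the seed.
#'
#' @param m an [expression_matrix()].
#' @param response_genes gene ids used as the response block.
#' @param k number of features to return (below the candidate count);
#'   default 50, the usual size of a feature-gene set.
#' @param elimination_fraction fraction removed per round (default 0.1).
#' @param seed integer seed (bandwidth pair subsampling).
#' @return A `feature_ranking`: ordered `genes`, `scores`, `method`,
#'   `response_genes`.
#' @export
bahsic_select <- function(m, response_genes, k = 50L,
                          elimination_fraction = 0.1, seed = 1L) {
  stopifnot_scalar_number(elimination_fraction, "elimination_fraction",
                          lower = 0, upper = 1, strict = TRUE)
  prep <- fs_prepare(m, response_genes, k)
  n <- nrow(prep$x)
  Lc <- double_center(gaussian_kernel(
    prep$y, median_bandwidth(prep$y, seed = seed)))
  # Cache centered per-gene kernels; bandwidths fixed at the start.
  Kc <- lapply(prep$candidates, function(g) {
    v <- prep$x[, g, drop = FALSE]
    double_center(gaussian_kernel(v, median_bandwidth(v, seed = seed)))
  })
  names(Kc) <- prep$candidates
  remaining <- prep$candidates
  removal_order <- character(0)
  scores <- stats::setNames(numeric(length(prep$candidates)), prep$candidates)
  while (length(remaining) > 0L) {
    s <- vapply(remaining, function(g) sum(Kc[[g]] * Lc) / n^2, numeric(1L))
    scores[remaining] <- s
    drop_n <- min(length(remaining),
                  max(1L, ceiling(elimination_fraction * length(remaining))))
    # lowest HSIC first; ties broken by gene id for determinism
    ord <- order(s, remaining)
    dropped <- remaining[ord[seq_len(drop_n)]]
    removal_order <- c(removal_order, dropped)
    remaining <- setdiff(remaining, dropped)
  }
  ranking <- rev(removal_order)
  top <- ranking[seq_len(k)]
  ranking_result(top, unname(scores[top]), "bahsic", response_genes)
}

#' Ensemble-tree feature selection (random-forest impurity importance)
#'
#' Regresses each response gene on all candidate genes with a random forest
#' and ranks candidates by impurity importance (averaged over response genes
#' when several are given). Ties are broken lexicographically.
#'
#' @inheritParams bahsic_select
#' @param n_trees number of trees per forest (default 500).
#' @return A `feature_ranking`.
#' @export
tree_importance_select <- function(m, response_genes, k = 50L,
                                   n_trees = 500L, seed = 1L) {
  if (n_trees < 1L) validation_error("n_trees must be at least 1")
  prep <- fs_prepare(m, response_genes, k)
  imp <- stats::setNames(numeric(length(prep$candidates)), prep$candidates)
  df <- as.data.frame(prep$x[, prep$candidates, drop = FALSE])
  safe <- paste0("g", seq_along(prep$candidates))  # ranger-safe column names
  names(df) <- safe
  for (rg in response_genes) {
    df$.response <- prep$x[, rg]
    if (stats::sd(df$.response) == 0) next
    fit <- ranger::ranger(
      dependent.variable.name = ".response", data = df,
      num.trees = n_trees, importance = "impurity",
      seed = derive_seed(seed, match(rg, response_genes)),
      num.threads = 1L)
    vi <- fit$variable.importance
    imp <- imp + stats::setNames(as.numeric(vi[safe]), prep$candidates) /
      length(response_genes)
  }
  imp[!is.finite(imp)] <- 0
  ord <- order(-imp, names(imp))
  top <- names(imp)[ord][seq_len(k)]
  ranking_result(top, unname(imp[top]), "tree_importance", response_genes)
}

#' Combine two feature rankings (recommended joint use)
#'
#' Interleaves the two top lists (rank 1 of each, then rank 2, ...),
#' deduplicates, and caps the union at `k_total`. Manually curated genes can
#' be forced in (`add`) or excluded (`remove`) afterwards.
#'
#' @param ranking_a,ranking_b `feature_ranking` objects.
#' @param k_total cap on the combined list length.
#' @param add,remove optional gene-id vectors merged into / dropped from the
#'   result.
#' @return Character vector of gene ids.
#' @export
combine_rankings <- function(ranking_a, ranking_b, k_total = 50L,
                             add = character(0), remove = character(0)) {
  la <- ranking_a$genes; lb <- ranking_b$genes
  len <- max(length(la), length(lb))
  merged <- character(0)
  for (r in seq_len(len)) {
    if (r <= length(la)) merged <- c(merged, la[r])
    if (r <= length(lb)) merged <- c(merged, lb[r])
  }
  merged <- unique(merged)
  merged <- merged[seq_len(min(k_total, length(merged)))]
  unique(setdiff(c(merged, add), remove))
}

#' Write a feature ranking as TSV (rank, gene, score, method)
#' @param ranking a `feature_ranking`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_ranking <- function(ranking, path) {
  utils::write.table(
    data.frame(rank = seq_along(ranking$genes), gene = ranking$genes,
               score = unname(ranking$scores), method = ranking$method,
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
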