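#' Spike-in reliability set
#'
#' A small expression matrix of well-known genes with their expected
#' interactions, to be integrated into a case dataset as a quality control:
#' reliable inference should recover the spike-in block and keep it separate
#' from the case genes.
#'
#' @param expression an [expression_matrix()] over the spike-in genes.
#' @param expected_edges optional data.frame with columns `gene_a`, `gene_b`
#'   and optionally `directed` (0/1).
#' @param prefix label prefix guaranteeing id disjointness after
#'   integration (default `"SPIKE_"`).
#' @return A `spike_in_set`.
#' @export
spike_in_set <- function(expression, expected_edges = NULL,
                         prefix = "SPIKE_") {
  stopifnot(inherits(expression, "expression_matrix"))
  if (nrow(expression$values) < 1L)
    validation_error("spike-in set needs at least one gene")
  if (!is.null(expected_edges)) {
    expected_edges <- as.data.frame(expected_edges, stringsAsFactors = FALSE)
    if (!all(c("gene_a", "gene_b") %in% names(expected_edges)))
      validation_error("expected_edges needs gene_a and gene_b columns")
    bad <- setdiff(unique(c(expected_edges$gene_a, expected_edges$gene_b)),
                   gene_ids(expression))
    if (length(bad))
      validation_error("expected edge genes absent from spike-in matrix: ",
                       paste(bad, collapse = ", "))
  }
  structure(list(expression = expression, expected_edges = expected_edges,
                 prefix = prefix),
            class = "spike_in_set")
}

#' Integrate spike-in data into a case dataset
#'
#' Equalizes the cell counts of the two matrices to the smaller one by
#' seeded subsampling, pairs spike-in cells to case cells by a seeded random
#' permutation (so any true cross-block dependence is destroyed by
#' construction), prefixes the spike-in gene ids, and stacks the spike-in
#' rows under the case rows.
#'
#' @param case an [expression_matrix()].
#' @param spike a [spike_in_set()] whose matrix shares the case's transform.
#' @param seed integer seed.
#' @return An [expression_matrix()] with `case genes + spike genes` rows.
#' @export
integrate_spike_in <- function(case, spike, seed = 1L) {
  stopifnot(inherits(case, "expression_matrix"),
            inherits(spike, "spike_in_set"))
  sp <- spike$expression
  if (case$transform != sp$transform)
    validation_error("transform mismatch: case is ", case$transform,
                     ", spike-in is ", sp$transform)
  n <- min(ncol(case$values), ncol(sp$values))
  case_sub <- sample_cells(case, n, mode = "random",
                           seed = derive_seed(seed, 1L))
  sp_sub <- sample_cells(sp, n, mode = "random", seed = derive_seed(seed, 2L))
  pairing <- with_seed(derive_seed(seed, 3L), sample.int(n))
  sp_vals <- sp_sub$values[, pairing, drop = FALSE]
  rownames(sp_vals) <- paste0(spike$prefix, rownames(sp_vals))
  colnames(sp_vals) <- colnames(case_sub$values)
  out <- rbind(case_sub$values, sp_vals)
  expression_matrix(out, transform = case$transform)
}

#' Spike-in separation report
#'
#' Classifies every adjacency of an inferred network as within-spike,
#' within-case, or crossing, reports the fraction of expected spike-in
#' interactions recovered (adjacency level), and flags separation when the
#' crossing fraction is at most `threshold`.
#'
#' @param net a [causal_network()] inferred from an integrated matrix.
#' @param spike_genes spike-in gene ids as they appear in the network
#'   (i.e. prefixed).
#' @param expected_edges optional expected-interaction table (prefixed ids).
#' @param threshold maximum tolerated crossing fraction (default 0.05).
#' @return A list: `within_spike`, `within_case`, `cross`, `total`,
#'   `cross_fraction`, `expected_recovered`, `separated`.
#' @export
spike_separation_report <- function(net, spike_genes, expected_edges = NULL,
                                    threshold = 0.05) {
  stopifnot(inherits(net, "causal_network"))
  if (!all(spike_genes %in% net$nodes))
    validation_error("spike genes missing from the network nodes")
  e <- net$edges
  total <- nrow(e)
  in_spike <- e$from %in% spike_genes & e$to %in% spike_genes
  in_case <- !(e$from %in% spike_genes) & !(e$to %in% spike_genes)
  cross <- total - sum(in_spike) - sum(in_case)
  cross_fraction <- if (total == 0L) NA_real_ else cross / total
  recovered <- NA_real_
  if (!is.null(expected_edges) && nrow(expected_edges) > 0L) {
    want <- pair_key(expected_edges$gene_a, expected_edges$gene_b)
    have <- pair_key(e$from[in_spike], e$to[in_spike])
    recovered <- mean(want %in% have)
  }
  list(within_spike = sum(in_spike), within_case = sum(in_case),
       cross = as.integer(cross), total = total,
       cross_fraction = cross_fraction,
       expected_recovered = recovered,
       separated = if (total == 0L) NA else cross_fraction <= threshold)
}

#' Read a spike-in set from a matrix file and an expected-edges TSV
#'
#' @param matrix_path expression matrix file (CSV).
#' @param edges_path optional TSV with columns `gene_a`, `gene_b`,
#'   `directed`.
#' @param transform transform tag of the stored matrix.
#' @return A [spike_in_set()].
#' @export
read_spike_in <- function(matrix_path, edges_path = NULL, transform = "raw") {
  expr <- load_expression(matrix_path, format = "csv", transform = transform)
  edges <- NULL
  if (!is.null(edges_path)) {
    edges <- utils::read.table(edges_path, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  spike_in_set(expr, edges)
}
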