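#' Causal network (CPDAG with edge annotations)
#'
#' The product of constraint-based discovery: a partially directed graph over
#' gene ids. Directed edges are stored as ordered pairs, undirected edges as
#' unordered pairs (canonically `from < to`). Every edge carries a sign
#' (+1 activation, -1 repression, 0 unknown), a p-value (the weakest
#' surviving evidence from the CI tests on that pair), and a weight
#' `-log10(p)` used as edge thickness.
#'
#' @param nodes character vector of node ids.
#' @param edges data.frame with columns `from`, `to`, `directed` (logical),
#'   and optionally `sign`, `p_value`, `weight`, `conflict`.
#' @return A `causal_network` object.
#' @export
causal_network <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) validation_error("duplicate node ids")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        directed = logical(0), sign = integer(0),
                        p_value = numeric(0), weight = numeric(0),
                        conflict = logical(0), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    for (col in c("from", "to"))
      edges[[col]] <- as.character(edges[[col]])
    if (is.null(edges$sign)) edges$sign <- 0L
    if (is.null(edges$p_value)) edges$p_value <- NA_real_
    if (is.null(edges$weight))
      edges$weight <- -log10(pmax(edges$p_value, 1e-300))
    if (is.null(edges$conflict)) edges$conflict <- FALSE
    if (!all(c(edges$from, edges$to) %in% nodes))
      validation_error("edge endpoints outside the node set")
    if (any(edges$from == edges$to)) validation_error("self-loops not allowed")
    # canonicalize undirected edges
    und <- !edges$directed
    swap <- und & edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    keys <- pair_key(edges$from, edges$to)
    if (anyDuplicated(keys))
      validation_error("a node pair appears in more than one edge")
    rownames(edges) <- NULL
  }
  net <- structure(list(nodes = nodes, edges = edges),
                   class = "causal_network")
  if (has_directed_cycle(net))
    validation_error("directed subgraph contains a cycle")
  net
}

#' @export
print.causal_network <- function(x, ...) {
  cat(sprintf("<causal_network> %d nodes, %d directed / %d undirected edges\n",
              length(x$nodes), sum(x$edges$directed), sum(!x$edges$directed)))
  invisible(x)
}

# Unordered adjacency keys of a network.
adjacency_keys <- function(net) pair_key(net$edges$from, net$edges$to)

# Edge "mark" per unordered pair: "a>b", "b>a" (direction by canonical
# order), or "--". Used by SHD.
edge_marks <- function(net) {
  e <- net$edges
  keys <- pair_key(e$from, e$to)
  marks <- ifelse(!e$directed, "--", ifelse(e$from <= e$to, ">", "<"))
  stats::setNames(marks, keys)
}

has_directed_cycle <- function(net) {
  e <- net$edges[net$edges$directed, , drop = FALSE]
  if (nrow(e) == 0L) return(FALSE)
  p <- length(net$nodes)
  adj <- matrix(FALSE, p, p, dimnames = list(net$nodes, net$nodes))
  adj[cbind(e$from, e$to)] <- TRUE
  remaining <- rep(TRUE, p)
  repeat {
    indeg <- colSums(adj[remaining, remaining, drop = FALSE])
    src <- which(remaining)[indeg == 0]
    if (length(src) == 0L) break
    remaining[src] <- FALSE
    if (!any(remaining)) return(FALSE)
  }
  any(remaining)
}

#' Annotate edge signs from Pearson correlation
#'
#' For each edge (A, B), sets the sign to +1 ("activation") when the Pearson
#' correlation of the two columns is positive, -1 ("repression") when
#' negative, and 0 when zero or undefined (constant column).
#'
#' @param net a [causal_network()].
#' @param data numeric matrix with one column per network node (named).
#' @return The network with updated `sign` annotations.
#' @export
annotate_edge_signs <- function(net, data) {
  stopifnot(inherits(net, "causal_network"))
  if (!all(net$nodes %in% colnames(data)))
    validation_error("data lacks columns for some network nodes")
  e <- net$edges
  if (nrow(e) > 0L) {
    for (k in seq_len(nrow(e))) {
      a <- data[, e$from[k]]; b <- data[, e$to[k]]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("constant column for edge ", e$from[k], "-", e$to[k],
                "; sign set to 0")
        e$sign[k] <- 0L
      } else {
        r <- stats::cor(a, b)
        e$sign[k] <- if (!is.finite(r) || r == 0) 0L else as.integer(sign(r))
      }
    }
  }
  net$edges <- e
  net
}

#' Structural Hamming distance between two networks
#'
#' Counts one for every adjacency present in exactly one graph, and one for
#' every shared adjacency whose mark differs (directed vs undirected, or
#' opposite direction).
#'
#' @param g1,g2 [causal_network()] objects over identical node sets.
#' @return Non-negative integer distance.
#' @export
shd <- function(g1, g2) {
  if (!setequal(g1$nodes, g2$nodes))
    validation_error("networks have different node sets")
  m1 <- edge_marks(g1); m2 <- edge_marks(g2)
  shared <- intersect(names(m1), names(m2))
  only <- length(setdiff(names(m1), shared)) + length(setdiff(names(m2), shared))
  flipped <- sum(m1[shared] != m2[shared])
  as.integer(only + flipped)
}

#' Pairwise SHD and similarity matrices
#'
#' Computes all pairwise structural Hamming distances between the networks
#' and maps them to similarities `exp(-d / (2 sigma^2))` (so distance 0 gives
#' similarity 1, and with the default `sigma = 5` a distance of 50 gives
#' `exp(-1)`).
#'
#' @param networks named list of [causal_network()] objects (>= 2).
#' @param sigma positive similarity bandwidth, default 5.
#' @return A list with `labels`, integer matrix `shd`, and numeric matrix
#'   `similarity`.
#' @export
similarity_matrix <- function(networks, sigma = 5) {
  if (length(networks) < 2L) validation_error("need at least two networks")
  stopifnot_scalar_number(sigma, "sigma", lower = 0, strict = TRUE)
  labels <- names(networks) %||% paste0("net", seq_along(networks))
  m <- length(networks)
  D <- matrix(0L, m, m, dimnames = list(labels, labels))
  for (a in seq_len(m - 1L)) {
    for (b in seq(a + 1L, m)) {
      D[a, b] <- D[b, a] <- shd(networks[[a]], networks[[b]])
    }
  }
  S <- exp(-D / (2 * sigma^2))
  list(labels = labels, shd = D, similarity = S)
}

#' Consensus network by intersection
#'
#' Keeps an adjacency iff it is present in every member network; the
#' direction is kept iff all members agree on it (otherwise undirected), and
#' the sign iff unanimous (otherwise 0). The p-value annotation is the
#' weakest (largest) among members.
#'
#' @param networks named list of [causal_network()] objects.
#' @param members labels of the member subset (default: all networks).
#' @return A [causal_network()].
#' @export
consensus_network <- function(networks, members = NULL) {
  labels <- names(networks) %||% paste0("net", seq_along(networks))
  names(networks) <- labels
  members <- members %||% labels
  if (!all(members %in% labels))
    validation_error("unknown member label(s): ",
                     paste(setdiff(members, labels), collapse = ", "))
  if (length(members) < 2L) validation_error("need at least two members")
  nets <- networks[members]
  nodes <- nets[[1L]]$nodes
  for (nt in nets) if (!setequal(nt$nodes, nodes))
    validation_error("member networks have different node sets")
  keys <- Reduce(intersect, lapply(nets, adjacency_keys))
  if (length(keys) == 0L) return(causal_network(nodes))
  rows <- lapply(keys, function(k) {
    per <- lapply(nets, function(nt) {
      e <- nt$edges[pair_key(nt$edges$from, nt$edges$to) == k, , drop = FALSE]
      e[1L, ]
    })
    dirs <- vapply(per, function(e)
      if (!e$directed) "--" else paste0(e$from, ">", e$to), character(1L))
    signs <- vapply(per, function(e) e$sign, numeric(1L))
    pvals <- vapply(per, function(e) e$p_value, numeric(1L))
    first <- per[[1L]]
    directed <- length(unique(dirs)) == 1L && dirs[1L] != "--"
    data.frame(
      from = first$from, to = first$to, directed = directed,
      sign = if (length(unique(signs)) == 1L) as.integer(signs[1L]) else 0L,
      p_value = suppressWarnings(max(pvals)),
      stringsAsFactors = FALSE
    )
  })
  causal_network(nodes, do.call(rbind, rows))
}

#' True positive rate of a network against a consensus
#'
#' `overlap / (overlap + specific)` where `overlap` counts adjacencies the
#' network shares with the consensus and `specific` those only in the
#' network. A network without adjacencies has TPR 1 by convention (with a
#' warning).
#'
#' @param net,consensus [causal_network()] objects over identical node sets.
#' @return Scalar in `[0, 1]`.
#' @export
tpr_vs_consensus <- function(net, consensus) {
  if (!setequal(net$nodes, consensus$nodes))
    validation_error("networks have different node sets")
  k1 <- adjacency_keys(net)
  k2 <- adjacency_keys(consensus)
  if (length(k1) == 0L) {
    warning("network has no adjacencies; TPR defined as 1")
    return(1)
  }
  overlap <- length(intersect(k1, k2))
  overlap / length(k1)
}

#' Edge stability across repeated runs
#'
#' Counts, for every adjacency in the union of `m` networks, the number of
#' runs it appears in, and summarizes the fraction of union adjacencies
#' occurring in exactly `k` and in at least `k` runs.
#'
#' @param networks list of `m >= 2` [causal_network()] objects over identical
#'   node sets.
#' @return A list: `m`, `counts` (named integer vector per adjacency), and
#'   `summary` data.frame with `k`, `exact_fraction`, `cumulative_fraction`.
#' @export
edge_stability <- function(networks) {
  m <- length(networks)
  if (m < 2L) validation_error("need at least two networks")
  nodes <- networks[[1L]]$nodes
  for (nt in networks) if (!setequal(nt$nodes, nodes))
    validation_error("networks have different node sets")
  all_keys <- unlist(lapply(networks, adjacency_keys))
  counts <- table(all_keys)
  union_n <- length(counts)
  exact <- vapply(seq_len(m), function(k) sum(counts == k), numeric(1L))
  if (union_n > 0L) exact <- exact / union_n
  cum <- rev(cumsum(rev(exact)))
  list(m = m,
       counts = stats::setNames(as.integer(counts), names(counts)),
       summary = data.frame(k = seq_len(m), exact_fraction = exact,
                            cumulative_fraction = cum))
}

#' Pick consensus members by similarity clustering
#'
#' A reproducible stand-in for reading the cluster map by eye: average-
#' linkage hierarchical clustering on `1 - similarity`, cut at `height`, and
#' the largest cluster (ties: the one with the most similar pair) becomes the
#' member set.
#'
#' @param sim result of [similarity_matrix()].
#' @param height dissimilarity cut height in `(0, 1)`, default 0.5.
#' @return Character vector of member labels.
#' @export
select_consensus_members <- function(sim, height = 0.5) {
  d <- stats::as.dist(1 - sim$similarity)
  hc <- stats::hclust(d, method = "average")
  grp <- stats::cutree(hc, h = height)
  sizes <- table(grp)
  best <- as.integer(names(sizes)[which.max(sizes)])
  sim$labels[grp == best]
}

#' Write a network as an edge-list TSV
#'
#' Columns: `source`, `target`, `directed` (0/1), `sign`, `p_value`,
#' `weight`.
#'
#' @param net a [causal_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path) {
  e <- net$edges
  out <- data.frame(source = e$from, target = e$to,
                    directed = as.integer(e$directed), sign = e$sign,
                    p_value = e$p_value, weight = e$weight,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network in GML for visualization tools
#' @param net a [causal_network()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gml <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("graph [", con)
  writeLines("  directed 1", con)
  idx <- stats::setNames(seq_along(net$nodes) - 1L, net$nodes)
  for (nd in net$nodes)
    writeLines(sprintf('  node [ id %d label "%s" ]', idx[[nd]], nd), con)
  e <- net$edges
  for (k in seq_len(nrow(e))) {
    writeLines(sprintf(
      '  edge [ source %d target %d directed %d sign %d weight %.6g ]',
      idx[[e$from[k]]], idx[[e$to[k]]], as.integer(e$directed[k]),
      as.integer(e$sign[k]), e$weight[k]), con)
  }
  writeLines("]", con)
  invisible(path)
}
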