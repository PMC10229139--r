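# Compact constructors for test networks and random graphs.

make_net <- function(nodes, directed = list(), undirected = list(),
                     signs = NULL, pvals = NULL) {
  rows <- list()
  add <- function(a, b, dir) {
    rows[[length(rows) + 1L]] <<- data.frame(
      from = a, to = b, directed = dir, stringsAsFactors = FALSE)
  }
  for (e in directed) add(e[1L], e[2L], TRUE)
  for (e in undirected) add(e[1L], e[2L], FALSE)
  edges <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(edges)) {
    edges$sign <- signs %||% 0L
    edges$p_value <- pvals %||% 0.01
  }
  causal_network(nodes, edges)
}

# Random partially directed network over the given nodes; directed edges
# follow a random node ranking, so the directed subgraph is acyclic.
random_network <- function(nodes, edge_prob = 0.3, dir_prob = 0.5) {
  p <- length(nodes)
  rank <- sample.int(p)
  rows <- list()
  for (a in seq_len(p - 1L)) for (b in seq(a + 1L, p)) {
    if (stats::runif(1) < edge_prob) {
      dir <- stats::runif(1) < dir_prob
      lo <- if (rank[a] < rank[b]) a else b
      hi <- if (rank[a] < rank[b]) b else a
      rows[[length(rows) + 1L]] <- data.frame(
        from = nodes[lo], to = nodes[hi], directed = dir,
        stringsAsFactors = FALSE)
    }
  }
  causal_network(nodes, if (length(rows)) do.call(rbind, rows) else NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
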