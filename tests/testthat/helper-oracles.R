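# Independent oracles used to verify the package's graph machinery.

# d-separation by explicit path enumeration (small graphs only): a path
# d-connects i and j given S iff every collider on it has a descendant in S
# and no non-collider on it is in S.
paths_between <- function(skel, i, j) {
  p <- nrow(skel)
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == j) { out[[length(out) + 1L]] <<- path; return(invisible()) }
    for (nxt in which(skel[last, ])) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(i)
  out
}

descendants_of <- function(dag, node) {
  reached <- dag[node, ] != 0
  repeat {
    nxt <- (colSums(dag[reached, , drop = FALSE] != 0) > 0) & !reached
    if (!any(nxt)) break
    reached <- reached | nxt
  }
  c(node, which(reached))
}

dsep_by_paths <- function(dag, i, j, S) {
  skel <- (dag + t(dag)) > 0
  for (path in paths_between(skel, i, j)) {
    if (length(path) < 2L) next
    open <- TRUE
    if (length(path) > 2L) {
      for (k in 2:(length(path) - 1L)) {
        a <- path[k - 1L]; m <- path[k]; b <- path[k + 1L]
        collider <- dag[a, m] != 0 && dag[b, m] != 0
        if (collider) {
          if (!any(descendants_of(dag, m) %in% S)) { open <- FALSE; break }
        } else {
          if (m %in% S) { open <- FALSE; break }
        }
      }
    }
    if (open) return(FALSE)
  }
  TRUE
}

# All (i, j, S) d-separation queries for p nodes.
dsep_queries <- function(p) {
  out <- list()
  for (i in seq_len(p - 1L)) for (j in seq(i + 1L, p)) {
    others <- setdiff(seq_len(p), c(i, j))
    for (size in 0:length(others)) {
      subsets <- if (size == 0L) list(integer(0))
                 else utils::combn(others, size, simplify = FALSE)
      for (S in subsets) out[[length(out) + 1L]] <- list(i = i, j = j, S = S)
    }
  }
  out
}

# Complete d-separation signature of a DAG: separation verdict for every
# node pair and every conditioning subset of the remaining nodes.
dsep_signature <- function(dag, queries = dsep_queries(nrow(dag))) {
  vapply(queries, function(q) dsep_by_paths(dag, q$i, q$j, q$S), logical(1L))
}

# Does `dag` have the same d-separation signature as `sig` (early exit)?
matches_signature <- function(dag, sig, queries) {
  for (k in seq_along(queries)) {
    q <- queries[[k]]
    if (dsep_by_paths(dag, q$i, q$j, q$S) != sig[k]) return(FALSE)
  }
  TRUE
}

is_acyclic <- function(dag) {
  p <- nrow(dag)
  indeg <- colSums(dag)
  remaining <- rep(TRUE, p)
  for (step in seq_len(p)) {
    src <- which(remaining & indeg == 0)
    if (length(src) == 0L) return(FALSE)
    remaining[src[1L]] <- FALSE
    indeg <- indeg - dag[src[1L], ]
    indeg[!remaining] <- Inf
  }
  TRUE
}

# Brute-force CPDAG: enumerate every acyclic orientation of the true
# skeleton, keep the orientations whose complete d-separation signature
# matches the truth's (the Markov equivalence class), and take the union of
# their orientations: an edge is directed in the CPDAG iff every member
# orients it the same way.
brute_force_cpdag <- function(dag) {
  p <- nrow(dag)
  nodes <- rownames(dag) %||% paste0("V", seq_len(p))
  skel <- (dag + t(dag)) > 0
  pairs <- which(upper.tri(skel) & skel, arr.ind = TRUE)
  ne <- nrow(pairs)
  queries <- dsep_queries(p)
  truth_sig <- dsep_signature(dag, queries)
  members <- list()
  for (mask in 0:(2^ne - 1L)) {
    cand <- matrix(0L, p, p)
    bits <- bitwAnd(bitwShiftR(mask, seq_len(ne) - 1L), 1L)
    for (e in seq_len(ne)) {
      a <- pairs[e, 1L]; b <- pairs[e, 2L]
      if (bits[e] == 1L) cand[a, b] <- 1L else cand[b, a] <- 1L
    }
    if (!is_acyclic(cand)) next
    if (matches_signature(cand, truth_sig, queries))
      members[[length(members) + 1L]] <- cand
  }
  rows <- list()
  for (e in seq_len(ne)) {
    a <- pairs[e, 1L]; b <- pairs[e, 2L]
    dirs <- vapply(members, function(m) m[a, b] == 1L, logical(1L))
    if (all(dirs)) {
      rows[[length(rows) + 1L]] <- data.frame(from = nodes[a], to = nodes[b],
                                              directed = TRUE)
    } else if (all(!dirs)) {
      rows[[length(rows) + 1L]] <- data.frame(from = nodes[b], to = nodes[a],
                                              directed = TRUE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(from = nodes[a], to = nodes[b],
                                              directed = FALSE)
    }
  }
  causal_network(nodes, if (length(rows)) do.call(rbind, rows) else NULL)
}

# Equality of two partially directed networks (same marks on same pairs).
same_network <- function(g1, g2) {
  setequal(g1$nodes, g2$nodes) && shd(g1, g2) == 0L
}

random_dag_adj <- function(p, edge_prob) {
  ord <- sample.int(p)
  dag <- matrix(0L, p, p,
                dimnames = list(paste0("V", 1:p), paste0("V", 1:p)))
  for (a in seq_len(p - 1L)) for (b in seq(a + 1L, p)) {
    if (stats::runif(1) < edge_prob) dag[ord[a], ord[b]] <- 1L
  }
  dag
}
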