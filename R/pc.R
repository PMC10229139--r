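#' PC-stable skeleton estimation
#'
#' Order-independent skeleton search: starting from the complete undirected
#' graph, pairs are tested against all conditioning subsets of size
#' `0..max_cond_size` drawn from each endpoint's neighborhood as frozen at
#' the start of each level. An edge is removed (and the separating set
#' recorded) on the first test with `p > alpha`; for surviving pairs the
#' largest p-value seen is kept as the edge's evidence annotation.
#'
#' @param data numeric matrix, observations as rows, one column per node.
#' @param tester a [ci_tester()] (or the d-separation oracle variant).
#' @param alpha significance cut-off of the CI test, in (0, 1). Larger
#'   values retain more edges.
#' @param max_cond_size largest conditioning-set size examined (default 3).
#' @param nodes optional node ids (default: column names).
#' @return A `pc_skeleton`: `nodes`, symmetric logical `adj`, `sepsets`
#'   (named list per removed pair), `pair_max_p` (named numeric per retained
#'   pair), `n_tests`.
#' @export
pc_skeleton <- function(data, tester, alpha = 0.1, max_cond_size = 3L,
                        nodes = colnames(data)) {
  stopifnot_scalar_number(alpha, "alpha", lower = 0, upper = 1, strict = TRUE)
  p <- ncol(data)
  if (p < 2L) validation_error("need at least two nodes")
  nodes <- nodes %||% paste0("V", seq_len(p))
  adj <- matrix(TRUE, p, p); diag(adj) <- FALSE
  sepsets <- list()
  pair_max_p <- list()
  n_tests <- 0L
  for (l in 0:max_cond_size) {
    frozen <- adj
    if (max(colSums(frozen)) - 1L < l) break
    for (i in seq_len(p - 1L)) {
      for (j in seq(i + 1L, p)) {
        if (!adj[i, j]) next
        key <- pair_key(nodes[i], nodes[j])
        removed <- FALSE
        for (anchor in list(c(i, j), c(j, i))) {
          nbrs <- setdiff(which(frozen[anchor[1L], ]), anchor[2L])
          if (length(nbrs) < l) next
          subsets <- if (l == 0L) list(integer(0))
                     else utils::combn(nbrs, l, simplify = FALSE)
          for (S in subsets) {
            res <- ci_test(tester, data, i, j, S)
            n_tests <- n_tests + 1L
            pm <- pair_max_p[[key]]
            pair_max_p[[key]] <- max(pm %||% 0, res$p_value)
            if (res$p_value > alpha) {
              adj[i, j] <- adj[j, i] <- FALSE
              sepsets[[key]] <- nodes[S]
              removed <- TRUE
              break
            }
          }
          if (removed) break
          if (l == 0L) break  # empty set tested once per pair
        }
      }
    }
  }
  dimnames(adj) <- list(nodes, nodes)
  structure(list(nodes = nodes, adj = adj, sepsets = sepsets,
                 pair_max_p = unlist(pair_max_p) %||%
                   stats::setNames(numeric(0), character(0)),
                 n_tests = n_tests),
            class = "pc_skeleton")
}

# Is there a directed path from a to b?
directed_reaches <- function(directed, a, b) {
  reached <- directed[a, ]
  repeat {
    if (reached[b]) return(TRUE)
    nxt <- (colSums(directed[reached, , drop = FALSE]) > 0) & !reached
    if (!any(nxt)) return(FALSE)
    reached <- reached | nxt
  }
}

# Meek rules 1-4 applied to a partially directed graph until fixpoint.
# skel: symmetric logical adjacency; directed: logical matrix of oriented
# edges (directed[a, b] means a -> b; such a pair is no longer undirected).
# Orientations that would close a directed cycle (possible when sampling
# error produces inconsistent v-structures) are skipped, keeping the output
# a valid PDAG.
apply_meek_rules <- function(skel, directed) {
  p <- nrow(skel)
  und <- skel & !(directed | t(directed))
  repeat {
    changed <- FALSE
    orient <- function(a, b) {
      if (directed_reaches(directed, b, a)) {
        und[a, b] <<- und[b, a] <<- FALSE  # drop from the worklist
        return(invisible())
      }
      directed[a, b] <<- TRUE
      und[a, b] <<- und[b, a] <<- FALSE
      changed <<- TRUE
    }
    for (a in seq_len(p)) for (b in seq_len(p)) {
      if (!und[a, b] || a == b) next
      # Rule 1: c -> a, a - b, c and b non-adjacent  =>  a -> b
      for (c_ in which(directed[, a])) {
        if (!skel[c_, b] && c_ != b) { orient(a, b); break }
      }
      if (!und[a, b]) next
      # Rule 2: a -> c -> b with a - b  =>  a -> b
      if (any(directed[a, ] & directed[, b])) { orient(a, b); next }
      # Rule 3: a - c -> b and a - d -> b, c and d non-adjacent  =>  a -> b
      cand <- which(und[a, ] & directed[, b])
      done <- FALSE
      if (length(cand) > 1L) {
        for (c_ in cand) for (d_ in cand) {
          if (c_ < d_ && !skel[c_, d_]) { orient(a, b); done <- TRUE; break }
        }
      }
      if (done || !und[a, b]) next
      # Rule 4: a - c, c -> d, d -> b, c and b non-adjacent,
      #         a and d adjacent  =>  a -> b
      for (c_ in which(und[a, ] | directed[a, ] | directed[, a])) {
        if (skel[c_, b] || c_ == b) next
        dd <- which(directed[c_, ] & directed[, b] & skel[a, ])
        if (length(dd) > 0L) { orient(a, b); break }
      }
    }
    if (!changed) break
  }
  directed
}

# Build a causal_network from a skeleton + directed-orientation matrix.
network_from_pdag <- function(nodes, skel, directed, pair_max_p = NULL,
                              conflicts = character(0)) {
  p <- length(nodes)
  rows <- list()
  for (a in seq_len(p - 1L)) {
    for (b in seq(a + 1L, p)) {
      if (!skel[a, b]) next
      key <- pair_key(nodes[a], nodes[b])
      pv <- if (!is.null(pair_max_p) && key %in% names(pair_max_p))
        unname(pair_max_p[key]) else NA_real_
      if (directed[a, b] && !directed[b, a]) {
        from <- nodes[a]; to <- nodes[b]; dir <- TRUE
      } else if (directed[b, a] && !directed[a, b]) {
        from <- nodes[b]; to <- nodes[a]; dir <- TRUE
      } else {
        from <- nodes[a]; to <- nodes[b]; dir <- FALSE
      }
      rows[[length(rows) + 1L]] <- data.frame(
        from = from, to = to, directed = dir, sign = 0L, p_value = pv,
        weight = -log10(max(pv, 1e-300)), conflict = key %in% conflicts,
        stringsAsFactors = FALSE)
    }
  }
  causal_network(nodes, if (length(rows)) do.call(rbind, rows) else NULL)
}

#' Orient a skeleton into a CPDAG
#'
#' Orients every unshielded triple `a - c - b` (with `a`, `b` non-adjacent)
#' as a v-structure `a -> c <- b` when `c` is not in the recorded separating
#' set of `(a, b)`, then propagates orientations with the Meek rules to a
#' fixpoint. Pairs receiving conflicting v-structure orientations are left
#' undirected and flagged. Edge p-values come from the skeleton's retained
#' `pair_max_p`; weights are `-log10(p)`.
#'
#' @param sk a `pc_skeleton` from [pc_skeleton()].
#' @return A [causal_network()].
#' @export
orient_cpdag <- function(sk) {
  stopifnot(inherits(sk, "pc_skeleton"))
  nodes <- sk$nodes
  p <- length(nodes)
  adj <- sk$adj
  demand <- matrix(0L, p, p)  # v-structure orientation demands a -> c
  for (c_ in seq_len(p)) {
    nb <- which(adj[c_, ])
    if (length(nb) < 2L) next
    for (a in nb) for (b in nb) {
      if (a >= b || adj[a, b]) next
      key <- pair_key(nodes[a], nodes[b])
      ss <- sk$sepsets[[key]]
      if (is.null(ss)) next  # pair never separated; not an unshielded triple
      if (!(nodes[c_] %in% ss)) {
        demand[a, c_] <- demand[a, c_] + 1L
        demand[b, c_] <- demand[b, c_] + 1L
      }
    }
  }
  directed <- matrix(FALSE, p, p)
  conflicts <- character(0)
  for (a in seq_len(p)) for (b in seq_len(p)) {
    if (demand[a, b] > 0L && demand[b, a] > 0L) {
      conflicts <- c(conflicts, pair_key(nodes[a], nodes[b]))
    } else if (demand[a, b] > 0L) {
      if (directed_reaches(directed, b, a)) {
        # orienting a -> b would close a cycle among v-structure edges
        conflicts <- c(conflicts, pair_key(nodes[a], nodes[b]))
      } else {
        directed[a, b] <- TRUE
      }
    }
  }
  directed <- apply_meek_rules(adj, directed)
  network_from_pdag(nodes, adj, directed, sk$pair_max_p, unique(conflicts))
}

#' Full PC run: skeleton estimation plus CPDAG orientation
#'
#' @inheritParams pc_skeleton
#' @param node_ids optional node ids (default: column names of `data`).
#' @return A [causal_network()] with p-value/weight annotations (signs 0;
#'   see [annotate_edge_signs()]).
#' @export
pc_infer <- function(data, node_ids = colnames(data), tester = ci_tester("gauss"),
                     alpha = 0.1, max_cond_size = 3L) {
  sk <- pc_skeleton(data, tester, alpha = alpha,
                    max_cond_size = max_cond_size, nodes = node_ids)
  orient_cpdag(sk)
}
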