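# Graph-theoretic d-separation on a known DAG, used for oracle CI tests and
# ground-truth CPDAG construction in benchmarks.

# dag: p x p adjacency matrix, dag[a, b] = 1 for edge a -> b.

dag_ancestors <- function(dag, nodes) {
  p <- nrow(dag)
  anc <- rep(FALSE, p)
  anc[nodes] <- TRUE
  repeat {
    parents <- which(rowSums(dag[, anc, drop = FALSE] == 1) > 0)
    new <- setdiff(parents, which(anc))
    if (length(new) == 0L) break
    anc[new] <- TRUE
  }
  which(anc)
}

#' Test d-separation on a DAG
#'
#' Uses the moralized-ancestral-graph criterion: restrict to the ancestors of
#' `{i, j} union S`, marry co-parents, drop directions, delete `S`, and check
#' whether `i` and `j` are disconnected.
#'
#' @param dag square 0/1 adjacency matrix, `dag[a, b] = 1` meaning `a -> b`.
#' @param i,j node indices.
#' @param S conditioning node indices (possibly empty).
#' @return `TRUE` if `i` and `j` are d-separated given `S`.
#' @export
d_separated <- function(dag, i, j, S = integer(0)) {
  dag <- (as.matrix(dag) != 0) * 1L
  S <- setdiff(as.integer(S), c(i, j))
  anc <- dag_ancestors(dag, c(i, j, S))
  sub <- dag[anc, anc, drop = FALSE]
  # Moralize: undirected skeleton plus edges between co-parents.
  ug <- ((sub + t(sub)) > 0) * 1L
  for (child in seq_along(anc)) {
    pa <- which(sub[, child] == 1)
    if (length(pa) > 1L) ug[pa, pa] <- 1L
  }
  diag(ug) <- 0L
  # Delete conditioned nodes and check connectivity i -- j.
  keep <- !(anc %in% S)
  ug <- ug[keep, keep, drop = FALSE]
  ids <- anc[keep]
  start <- match(i, ids); goal <- match(j, ids)
  if (is.na(start) || is.na(goal)) return(TRUE)
  reached <- rep(FALSE, nrow(ug))
  frontier <- start
  reached[start] <- TRUE
  while (length(frontier) > 0L) {
    nxt <- which(colSums(ug[frontier, , drop = FALSE] == 1) > 0 & !reached)
    if (goal %in% nxt) return(FALSE)
    reached[nxt] <- TRUE
    frontier <- nxt
  }
  !reached[goal]
}

# Oracle CI test: p-value 1 when d-separated, 0 otherwise.
oracle_ci_test <- function(dag, i, j, S) {
  sep <- d_separated(dag, i, j, S)
  ci_result(if (sep) 0 else Inf, if (sep) 1 else 0, "oracle", length(S),
            nrow(dag))
}

#' CPDAG of a known DAG
#'
#' The Markov-equivalence-class representative: the DAG's skeleton with its
#' v-structures oriented, closed under the Meek rules.
#'
#' @param dag 0/1 adjacency matrix (`dag[a, b] = 1` for `a -> b`), optionally
#'   with dimnames supplying node ids.
#' @return A [causal_network] object.
#' @export
true_cpdag <- function(dag) {
  dag <- as.matrix(dag)
  p <- nrow(dag)
  nodes <- rownames(dag) %||% paste0("V", seq_len(p))
  skel <- ((dag + t(dag)) > 0)
  directed <- matrix(FALSE, p, p)
  # v-structures: a -> c <- b with a, b non-adjacent.
  for (c_ in seq_len(p)) {
    pa <- which(dag[, c_] != 0)
    if (length(pa) < 2L) next
    for (a in pa) for (b in pa) {
      if (a < b && !skel[a, b]) {
        directed[a, c_] <- TRUE
        directed[b, c_] <- TRUE
      }
    }
  }
  pdag <- apply_meek_rules(skel, directed)
  network_from_pdag(nodes, skel, pdag)
}
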