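test_that("edge signs follow the Pearson correlation", {
  net <- make_net(c("A", "B", "C"), directed = list(c("A", "B")),
                  undirected = list(c("A", "C")))
  set.seed(1)
  a <- rnorm(50)
  data <- cbind(A = a, B = 2 * a, C = -a)
  out <- annotate_edge_signs(net, data)
  e <- out$edges
  expect_identical(e$sign[e$to == "B"], 1L)
  expect_identical(e$sign[e$to == "C" | e$from == "C"], -1L)
  data2 <- cbind(A = a, B = rep(1, 50), C = -a)
  expect_warning(out2 <- annotate_edge_signs(net, data2), "constant")
  expect_identical(out2$edges$sign[out2$edges$to == "B"], 0L)
})

test_that("SHD counts missing adjacencies and differing marks as one each", {
  ab_dir <- make_net(c("A", "B"), directed = list(c("A", "B")))
  ba_dir <- make_net(c("A", "B"), directed = list(c("B", "A")))
  ab_und <- make_net(c("A", "B"), undirected = list(c("A", "B")))
  none <- make_net(c("A", "B"))
  expect_identical(shd(ab_dir, ab_dir), 0L)
  expect_identical(shd(ab_dir, none), 1L)
  expect_identical(shd(ab_dir, ba_dir), 1L)
  expect_identical(shd(ab_dir, ab_und), 1L)
  expect_error(shd(ab_dir, make_net(c("A", "C"))), "node sets")
})

test_that("SHD satisfies the metric axioms on random triples", {
  set.seed(33)
  nodes <- paste0("n", 1:6)
  for (rep in 1:40) {
    g1 <- random_network(nodes); g2 <- random_network(nodes)
    g3 <- random_network(nodes)
    expect_identical(shd(g1, g1), 0L)
    expect_identical(shd(g1, g2), shd(g2, g1))
    expect_lte(shd(g1, g3), shd(g1, g2) + shd(g2, g3))
  }
})

test_that("similarity transform hits its closed-form values", {
  g0 <- make_net(c("A", "B"))
  res <- similarity_matrix(list(x = g0, y = g0), sigma = 5)
  expect_equal(res$similarity["x", "y"], 1.0)
  # distance 50 at sigma 5: exp(-50/50) = exp(-1)
  expect_equal(exp(-50 / (2 * 5^2)), exp(-1))
  d <- 0:60
  s <- exp(-d / (2 * 5^2))
  expect_true(all(diff(s) < 0))
})

test_that("similarity ordering is the reverse of SHD ordering", {
  set.seed(44)
  nets <- replicate(5, random_network(paste0("n", 1:7)), simplify = FALSE)
  names(nets) <- paste0("N", 1:5)
  res <- similarity_matrix(nets)
  up <- upper.tri(res$shd)
  expect_identical(order(res$shd[up]), order(-res$similarity[up]))
  expect_true(all(res$similarity > 0 & res$similarity <= 1))
})

test_that("consensus keeps unanimous direction and sign, else demotes", {
  ab <- make_net(c("A", "B"), directed = list(c("A", "B")), signs = 1L)
  ba <- make_net(c("A", "B"), directed = list(c("B", "A")), signs = 1L)
  cons <- consensus_network(list(x = ab, y = ba))
  expect_identical(nrow(cons$edges), 1L)
  expect_false(cons$edges$directed[1])
  same <- consensus_network(list(x = ab, y = ab))
  expect_true(same$edges$directed[1])
  expect_identical(same$edges$sign[1], 1L)
  empty <- consensus_network(list(x = ab, y = make_net(c("A", "B"))))
  expect_identical(nrow(empty$edges), 0L)
  expect_error(consensus_network(list(x = ab, y = ab), members = c("x", "z")),
               "unknown")
})

test_that("consensus adjacencies are a subset of every member's", {
  set.seed(55)
  nets <- replicate(4, random_network(paste0("n", 1:8), 0.4),
                    simplify = FALSE)
  names(nets) <- paste0("N", 1:4)
  cons <- consensus_network(nets)
  ck <- sccausal:::adjacency_keys(cons)
  for (nt in nets) {
    expect_true(all(ck %in% sccausal:::adjacency_keys(nt)))
    # overlap + specific partitions the member's adjacency set
    tpr <- tpr_vs_consensus(nt, cons)
    overlap <- length(intersect(sccausal:::adjacency_keys(nt), ck))
    specific <- length(setdiff(sccausal:::adjacency_keys(nt), ck))
    if (overlap + specific > 0)
      expect_equal(tpr, overlap / (overlap + specific))
  }
})

test_that("TPR reproduces the worked 73/33 example and edge cases", {
  nodes <- paste0("g", 1:40)
  # construct a network with 73 overlapping and 33 specific adjacencies
  all_pairs <- t(combn(nodes, 2))
  net_edges <- data.frame(from = all_pairs[1:106, 1], to = all_pairs[1:106, 2],
                          directed = FALSE)
  cons_edges <- data.frame(from = all_pairs[1:73, 1], to = all_pairs[1:73, 2],
                           directed = FALSE)
  net <- causal_network(nodes, net_edges)
  cons <- causal_network(nodes, cons_edges)
  tpr <- tpr_vs_consensus(net, cons)
  expect_equal(tpr, 73 / (73 + 33))
  expect_equal(round(100 * tpr, 1), 68.9)
  expect_equal(tpr_vs_consensus(cons, cons), 1.0)
  disjoint <- causal_network(nodes, data.frame(
    from = all_pairs[107:120, 1], to = all_pairs[107:120, 2],
    directed = FALSE))
  expect_equal(tpr_vs_consensus(disjoint, cons), 0.0)
  expect_warning(t_empty <- tpr_vs_consensus(causal_network(nodes), cons),
                 "TPR defined as 1")
  expect_equal(t_empty, 1)
})

test_that("edge stability fractions count occurrences correctly", {
  ab <- make_net(c("A", "B", "C"), undirected = list(c("A", "B")))
  bc <- make_net(c("A", "B", "C"), undirected = list(c("B", "C")))
  stab_same <- edge_stability(list(ab, ab, ab))
  expect_equal(stab_same$summary$cumulative_fraction[3], 1)
  stab_disj <- edge_stability(list(ab, bc))
  expect_equal(stab_disj$summary$exact_fraction[1], 1)
  expect_equal(sum(stab_disj$summary$exact_fraction), 1)
  # cumulative fractions are non-increasing in k
  set.seed(66)
  nets <- replicate(5, random_network(paste0("n", 1:8), 0.4),
                    simplify = FALSE)
  stab <- edge_stability(nets)
  expect_true(all(diff(stab$summary$cumulative_fraction) <= 1e-12))
  expect_equal(sum(stab$summary$exact_fraction), 1)
})

test_that("consensus member selection picks the tight similarity cluster", {
  set.seed(77)
  base <- random_network(paste0("n", 1:10), 0.6)
  tweak <- function(net, nflip) {
    e <- net$edges
    keep <- seq_len(nrow(e) - nflip)
    causal_network(net$nodes, e[keep, ])
  }
  nets <- list(a = base, b = tweak(base, 1), c = tweak(base, 2),
               d = tweak(base, 22))
  sim <- similarity_matrix(nets)
  members <- select_consensus_members(sim, height = 0.3)
  expect_true(all(c("a", "b", "c") %in% members))
  expect_false("d" %in% members)
})

test_that("edge lists and GML serialize and round-trip key fields", {
  net <- make_net(c("A", "B", "C"), directed = list(c("A", "B")),
                  undirected = list(c("B", "C")), pvals = c(0.01, 0.2))
  tsv <- tempfile(fileext = ".tsv")
  write_edge_list(net, tsv)
  back <- read.delim(tsv)
  expect_identical(nrow(back), 2L)
  expect_setequal(back$source[back$directed == 1], "A")
  gml <- tempfile(fileext = ".gml")
  write_gml(net, gml)
  txt <- readLines(gml)
  expect_true(any(grepl("node", txt)) && any(grepl("edge", txt)))
})
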