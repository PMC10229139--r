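dummy_data <- function(nodes, n = 10) {
  matrix(rnorm(n * length(nodes)), n, length(nodes),
         dimnames = list(NULL, nodes))
}

test_that("oracle skeleton of a collider records the empty sepset", {
  dag <- matrix(0, 3, 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  dag["X", "Z"] <- 1; dag["Y", "Z"] <- 1
  sk <- pc_skeleton(dummy_data(c("X", "Y", "Z")), ci_tester("oracle", dag = dag),
                    alpha = 0.05, max_cond_size = 3)
  expect_true(sk$adj["X", "Z"] && sk$adj["Y", "Z"] && !sk$adj["X", "Y"])
  expect_identical(sk$sepsets[[sccausal:::pair_key("X", "Y")]], character(0))
  net <- orient_cpdag(sk)
  e <- net$edges
  expect_setequal(paste(e$from, e$to), c("X Z", "Y Z"))
  expect_true(all(e$directed))
})

test_that("a chain stays fully undirected (Markov equivalence class)", {
  dag <- matrix(0, 3, 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  dag["X", "Y"] <- 1; dag["Y", "Z"] <- 1
  net <- pc_infer(dummy_data(c("X", "Y", "Z")), c("X", "Y", "Z"),
                  ci_tester("oracle", dag = dag), alpha = 0.05)
  expect_identical(sum(net$edges$directed), 0L)
  expect_identical(nrow(net$edges), 2L)
  key <- sccausal:::pair_key("X", "Z")
  sk <- pc_skeleton(dummy_data(c("X", "Y", "Z")),
                    ci_tester("oracle", dag = dag), alpha = 0.05)
  expect_identical(sk$sepsets[[key]], "Y")
})

test_that("Meek rule 1 and 2 orientations are forced", {
  # rule 1: a -> b, b - c, a and c non-adjacent  =>  b -> c
  sk <- structure(list(
    nodes = c("a", "b", "c"),
    adj = matrix(c(FALSE, TRUE, FALSE,
                   TRUE, FALSE, TRUE,
                   FALSE, TRUE, FALSE), 3, 3,
                 dimnames = rep(list(c("a", "b", "c")), 2)),
    sepsets = list(), pair_max_p = numeric(0)), class = "pc_skeleton")
  directed <- matrix(FALSE, 3, 3)
  directed[1, 2] <- TRUE
  out <- sccausal:::apply_meek_rules(sk$adj, directed)
  expect_true(out[2, 3])
  # rule 2: a -> b -> c with a - c  =>  a -> c
  adj2 <- matrix(TRUE, 3, 3); diag(adj2) <- FALSE
  directed2 <- matrix(FALSE, 3, 3)
  directed2[1, 2] <- TRUE; directed2[2, 3] <- TRUE
  out2 <- sccausal:::apply_meek_rules(adj2, directed2)
  expect_true(out2[1, 3])
})

test_that("max_cond_size = 0 yields the marginal-dependence graph", {
  # X -> Y -> Z: marginally all pairs are dependent, so level 0 keeps all
  dag <- matrix(0, 3, 3, dimnames = rep(list(c("X", "Y", "Z")), 2))
  dag["X", "Y"] <- 1; dag["Y", "Z"] <- 1
  sk <- pc_skeleton(dummy_data(c("X", "Y", "Z")),
                    ci_tester("oracle", dag = dag), alpha = 0.05,
                    max_cond_size = 0)
  expect_true(all(sk$adj[upper.tri(sk$adj)]))
})

test_that("three independent columns give an empty skeleton", {
  empties <- 0L
  for (r in 1:50) {
    set.seed(r)
    d <- matrix(rnorm(900), 300, 3, dimnames = list(NULL, c("A", "B", "C")))
    net <- pc_infer(d, colnames(d), ci_tester("gauss"), alpha = 0.01)
    if (nrow(net$edges) == 0L) empties <- empties + 1L
  }
  expect_gte(empties / 50, 0.85)
})

test_that("two dependent columns give a single undirected edge", {
  set.seed(8)
  x <- rnorm(200); d <- cbind(A = x, B = x + rnorm(200, sd = 0.3))
  net <- pc_infer(d, colnames(d), ci_tester("gauss"), alpha = 0.01)
  expect_identical(nrow(net$edges), 1L)
  expect_false(net$edges$directed[1])
})

test_that("the skeleton is invariant to column permutation (PC-stable)", {
  for (r in 1:2) {
    set.seed(100 + r)
    mod <- random_dag(8, 2, seed = 100 + r)
    x <- simulate_sem(mod, 500, seed = r)
    net1 <- pc_infer(x, colnames(x), ci_tester("gauss"), alpha = 0.05)
    perm <- sample(ncol(x))
    xp <- x[, perm]
    net2 <- pc_infer(xp, colnames(xp), ci_tester("gauss"), alpha = 0.05)
    expect_setequal(sccausal:::adjacency_keys(net1),
                    sccausal:::adjacency_keys(net2))
  }
})

test_that("shrinking alpha never adds edges", {
  set.seed(17)
  mod <- random_dag(8, 2, seed = 17)
  x <- simulate_sem(mod, 300, seed = 17)
  n_large <- nrow(pc_infer(x, colnames(x), ci_tester("gauss"),
                           alpha = 0.1)$edges)
  n_small <- nrow(pc_infer(x, colnames(x), ci_tester("gauss"),
                           alpha = 1e-12)$edges)
  expect_lte(n_small, n_large)
  expect_error(pc_skeleton(x, ci_tester("gauss"), alpha = 1.5), "alpha")
})

test_that("directed subgraphs of inferred CPDAGs are acyclic", {
  for (r in 1:5) {
    set.seed(r)
    mod <- random_dag(8, 2.5, seed = r)
    x <- simulate_sem(mod, 400, seed = r + 50)
    net <- pc_infer(x, colnames(x), ci_tester("gauss"), alpha = 0.1)
    expect_false(sccausal:::has_directed_cycle(net))
  }
})

test_that("linear-Gaussian skeleton recovery reaches F1 0.9", {
  f1 <- numeric(10)
  for (r in 1:10) {
    mod <- random_dag(8, 2, mechanism = "linear", noise_sd = 0.5, seed = r)
    x <- simulate_sem(mod, 2000, seed = r + 1000)
    net <- pc_infer(x, colnames(x), ci_tester("gauss"), alpha = 0.01)
    f1[r] <- evaluate_network(net, mod)$f1
  }
  expect_gte(median(f1), 0.9)
})
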