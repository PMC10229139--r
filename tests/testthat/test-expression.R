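make_case <- function() {
  vals <- matrix(c(0, 0, 4, 4,
                   1, 2, 3, 4,
                   0, 0, 0, 0), nrow = 3, byrow = TRUE,
                 dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:4)))
  expression_matrix(vals)
}

test_that("CSV/TSV loading round-trips values, ids, and raw tag", {
  m <- make_case()
  for (fmt in c("csv", "tsv")) {
    path <- tempfile(fileext = paste0(".", fmt))
    sep <- if (fmt == "csv") "," else "\t"
    df <- data.frame(gene = rownames(m$values), m$values, check.names = FALSE)
    write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    got <- load_expression(path, format = fmt)
    expect_equal(got$values, m$values)
    expect_identical(got$transform, "raw")
  }
})

test_that("MTX triplets densify with zero fill", {
  mm <- Matrix::sparseMatrix(i = 1L, j = 1L, x = 5, dims = c(3L, 2L))
  mtx <- tempfile(fileext = ".mtx")
  Matrix::writeMM(mm, mtx)
  genes <- tempfile(); barcodes <- tempfile()
  writeLines(c("g1", "g2", "g3"), genes)
  writeLines(c("c1", "c2"), barcodes)
  got <- load_expression(mtx, format = "mtx", genes_path = genes,
                         barcodes_path = barcodes)
  expect_equal(dim(got), c(3L, 2L))
  expect_equal(got$values["g1", "c1"], 5)
  expect_equal(sum(got$values), 5)
})

test_that("duplicate gene ids are rejected at load", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("gene,c1,c2", "gA,1,2", "gA,3,4"), path)
  expect_error(load_expression(path, format = "csv"), "duplicate gene ids")
})

test_that("log2 transform maps 0 to 0 and 3 to 2, once only", {
  m <- expression_matrix(matrix(c(0, 3), 1, 2,
                                dimnames = list("g", c("c1", "c2"))))
  lg <- transform_expression(m, "log2")
  expect_equal(unname(lg$values[1, ]), c(0, 2))
  expect_error(transform_expression(lg, "log2"), "requires raw")
})

test_that("log2 output is non-negative and monotone in raw input", {
  set.seed(7)
  raw <- matrix(runif(40, 0, 50), 4, 10,
                dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  lg <- transform_expression(expression_matrix(raw), "log2")
  expect_true(all(lg$values >= 0))
  for (r in 1:4)
    expect_equal(order(lg$values[r, ]), order(raw[r, ]))
})

test_that("zscore standardizes rows exactly and zeroes constant rows", {
  m <- expression_matrix(matrix(c(1, 2, 3, 5, 5, 5), 2, 3, byrow = TRUE,
                                dimnames = list(c("g1", "g2"), paste0("c", 1:3))))
  z <- transform_expression(m, "zscore")
  expect_equal(unname(z$values["g1", ]), c(-1, 0, 1))
  expect_equal(unname(z$values["g2", ]), c(0, 0, 0))
  expect_identical(z$transform, "zscore")
})

test_that("gene attributes match hand computation", {
  attrs <- compute_gene_attributes(make_case())
  a <- attrs[attrs$gene == "gA", ]
  expect_equal(a$mean_expr, 2)
  expect_equal(a$pct_cells, 0.5)
  expect_equal(a$variance, 16 / 3)
  cz <- attrs[attrs$gene == "gC", ]
  expect_equal(unlist(cz[, c("mean_expr", "pct_cells", "variance")]),
               c(mean_expr = 0, pct_cells = 0, variance = 0))
})

test_that("fold change is zero for identical case and control", {
  m <- make_case()
  attrs <- compute_gene_attributes(m, control = m)
  expect_equal(attrs$log_fc, rep(0, 3))
  empty_ctrl <- m
  expect_error(
    compute_gene_attributes(m, control = expression_matrix(
      m$values[, 0, drop = FALSE], cell_ids = character(0))),
    "zero cells")
})

test_that("attributes are invariant to cell permutation", {
  m <- make_case()
  perm <- m
  perm$values <- m$values[, c(3, 1, 4, 2)]
  a1 <- compute_gene_attributes(m)
  a2 <- compute_gene_attributes(perm)
  expect_equal(a1[, -1], a2[, -1])
})

test_that("filtering is a strict conjunction with descending order", {
  attrs <- data.frame(gene = c("g1", "g2", "g3"),
                      mean_expr = c(0.2, 0.1, 0.9),
                      pct_cells = c(0.6, 0.9, 0.4),
                      variance = c(1, 1, 1),
                      log_fc = c(0.4, 2, 2))
  kept <- filter_genes(attrs, default_filter_spec())
  expect_identical(kept, "g1")  # g2 fails strict mean, g3 fails pct
  # boundary: threshold equal to the value is rejected
  expect_length(filter_genes(data.frame(gene = "g", mean_expr = 0.1),
                             filter_spec(min_mean_expr = 0.1)), 0)
  expect_error(filter_spec(), "at least one condition")
  expect_error(filter_genes(attrs, filter_spec(tf_only = TRUE)), "is_tf")
})

test_that("tightening a threshold never enlarges the filtered set", {
  set.seed(11)
  attrs <- data.frame(gene = sprintf("g%02d", 1:40),
                      mean_expr = runif(40, 0, 2),
                      pct_cells = runif(40),
                      variance = runif(40, 0, 4))
  prev <- NULL
  for (thr in c(0.1, 0.5, 1, 1.5)) {
    cur <- filter_genes(attrs, filter_spec(min_mean_expr = thr))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("cell sampling is seed-reproducible and shape-preserving", {
  set.seed(2)
  m <- expression_matrix(matrix(runif(500, 0, 9), 5, 100,
                                dimnames = list(paste0("g", 1:5),
                                                paste0("c", 1:100))))
  s1 <- sample_cells(m, 30, "random", seed = 42)
  s2 <- sample_cells(m, 30, "random", seed = 42)
  expect_identical(s1$values, s2$values)
  expect_identical(gene_ids <- rownames(s1$values), rownames(m$values))
  expect_identical(sample_cells(m, 100, "random", seed = 1)$values, m$values)
  expect_identical(colnames(sample_cells(m, 3, "first")$values),
                   c("c1", "c2", "c3"))
  expect_error(sample_cells(m, 101), "exceeds")
})
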