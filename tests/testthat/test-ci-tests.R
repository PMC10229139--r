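test_that("gauss test matches an independent partial-correlation oracle", {
  set.seed(21)
  n <- 400
  x <- rnorm(n); y <- 0.8 * x + rnorm(n); z <- 0.7 * y + rnorm(n)
  d <- cbind(x, y, z)
  res <- gauss_ci_test(d, 1, 3, 2)
  # independent route: correlation of linear-regression residuals + Fisher z
  rx <- resid(lm(x ~ y)); rz <- resid(lm(z ~ y))
  r <- cor(rx, rz)
  zstat <- sqrt(n - 1 - 3) * 0.5 * log((1 + r) / (1 - r))
  p <- 2 * pnorm(-abs(zstat))
  expect_equal(res$statistic, zstat, tolerance = 1e-10)
  expect_equal(res$p_value, p, tolerance = 1e-10)
  expect_identical(res$cond_size, 1L)
})

test_that("zero correlation gives z = 0 and p = 1", {
  d <- cbind(c(1, -1, 1, -1, 1, -1, 1, -1), c(1, 1, -1, -1, 1, 1, -1, -1))
  res <- gauss_ci_test(d, 1, 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("gauss test is calibrated under independence", {
  rejections <- 0L
  for (r in 1:200) {
    set.seed(r)
    d <- matrix(rnorm(2000), 1000, 2)
    if (gauss_ci_test(d, 1, 2)$p_value < 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.02)
  expect_lte(rejections / 200, 0.09)
})

test_that("permutation variant handles degenerate and boundary cases", {
  set.seed(2)
  d <- cbind(rep(1, 30), rnorm(30))
  res <- hsic_test(d, 1, 2, variant = "perm",
                   params = ci_tester("hsic.perm", B = 19))
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  # observed beats all B = 19 permutations -> add-one estimator gives 1/20
  x <- seq_len(60); y <- x + rnorm(60, sd = 0.01)
  res2 <- hsic_test(cbind(x, y), 1, 2, variant = "perm",
                    params = ci_tester("hsic.perm", B = 19))
  expect_equal(res2$p_value, 1 / 20)
  expect_error(ci_tester("hsic.perm", B = 10), "B >= 19")
})

test_that("kernel tests reject quadratic dependence with high power", {
  for (method in c("hsic.gamma", "hsic.perm", "dcc.gamma", "dcc.perm")) {
    rej <- 0L
    for (r in 1:20) {
      set.seed(r)
      x <- rnorm(300); y <- x^2 + 0.5 * rnorm(300)
      p <- ci_test(ci_tester(method, seed = r), cbind(x, y), 1, 2)$p_value
      if (p < 0.05) rej <- rej + 1L
    }
    expect_gte(rej / 20, 0.9)
  }
})

test_that("hsic/dcov/gauss statistics are symmetric in the tested pair", {
  set.seed(31)
  d <- cbind(rnorm(80), rnorm(80), rnorm(80))
  for (method in c("gauss", "hsic.gamma", "dcc.gamma")) {
    tt <- ci_tester(method, seed = 3)
    a <- ci_test(tt, d, 1, 2, 3)
    b <- ci_test(tt, d, 2, 1, 3)
    expect_equal(abs(a$statistic), abs(b$statistic), tolerance = 1e-9)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-9)
  }
})

test_that("rcit/rcot are deterministic under a fixed seed", {
  set.seed(41)
  d <- matrix(rnorm(900), 300, 3)
  for (variant in c("rcit", "rcot")) {
    p1 <- ci_test(ci_tester(variant, seed = 7), d, 1, 2, 3)$p_value
    p2 <- ci_test(ci_tester(variant, seed = 7), d, 1, 2, 3)$p_value
    expect_identical(p1, p2)
  }
  expect_error(ci_tester("rcot", f_xy = 0), "Fourier")
})

test_that("rcot detects sinusoidal dependence", {
  # frequencies inside the kernel's resolution at the default feature count
  rej <- 0L
  for (r in 1:20) {
    set.seed(r)
    x <- rnorm(500); y <- sin(2 * x) + 0.3 * rnorm(500)
    p <- ci_test(ci_tester("rcot", seed = r), cbind(x, y), 1, 2)$p_value
    if (p < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 20, 0.9)
})

test_that("all testers return p-values in [0, 1] on mixed data", {
  set.seed(51)
  n <- 60
  z <- rnorm(n)
  d <- cbind(z + rnorm(n), exp(z / 2), rbinom(n, 3, 0.4), z^2)
  for (method in c("gauss", "hsic.gamma", "hsic.perm", "dcc.gamma",
                   "dcc.perm", "rcit", "rcot")) {
    tt <- ci_tester(method, B = 19, seed = 1)
    for (S in list(integer(0), 3L, c(3L, 4L))) {
      res <- ci_test(tt, d, 1, 2, S)
      expect_gte(res$p_value, 0)
      expect_lte(res$p_value, 1)
      expect_identical(res$cond_size, length(S))
    }
  }
})

test_that("gamma and permutation p-values agree in ranking", {
  # weak-to-moderate effects, so permutation p-values do not saturate at 1/(B+1)
  set.seed(61)
  strengths <- seq(0, 0.3, length.out = 20)
  scenarios <- lapply(strengths, function(s) {
    n <- 150
    x <- rnorm(n)
    cbind(x, s * x^2 + rnorm(n))
  })
  pg <- pp <- numeric(length(scenarios))
  for (r in seq_along(scenarios)) {
    pg[r] <- ci_test(ci_tester("dcc.gamma", seed = r), scenarios[[r]],
                     1, 2)$p_value
    pp[r] <- ci_test(ci_tester("dcc.perm", B = 399, seed = r),
                     scenarios[[r]], 1, 2)$p_value
  }
  expect_gte(cor(pg, pp, method = "spearman"), 0.9)
})
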