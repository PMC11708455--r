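test_that("K2 matches the independent oracle to 1e-9 over seeded samples", {
  set.seed(314)
  max_dp <- 0
  for (k in 1:200) {
    n <- sample(8:200, 1)
    x <- switch(1 + k %% 3,
                rnorm(n), rexp(n), rt(n, df = 3))
    got <- dagostino_pearson(x)
    ora <- oracle_k2(x)
    max_dp <- max(max_dp, abs(got$p_value - ora$p_value),
                  abs(got$statistic - ora$statistic) /
                    max(1, ora$statistic))
  }
  expect_lt(max_dp, 1e-9)
})

test_that("K2 agrees with reference-implementation values on frozen vectors", {
  for (case in frozen_normaltest_cases()) {
    got <- dagostino_pearson(case$x)
    expect_equal(got$statistic, case$k2, tolerance = 1e-9)
    expect_equal(got$p_value, case$p, tolerance = 1e-7)
  }
})

test_that("K2 flags exponential data and rejects tiny samples", {
  set.seed(12)
  x <- rexp(100)
  expect_lt(dagostino_pearson(x)$p_value, 0.01)  # oracle run: p = 2.4e-08
  set.seed(10)
  expect_gt(dagostino_pearson(rnorm(100))$p_value, 0.05)
  expect_error(dagostino_pearson(rnorm(5)), "n >= 8")
})

test_that("paired comparison reproduces the closed-form t on a fixed case", {
  res <- paired_compare(c(3, 4, 5), c(1, 2, 6))
  # differences (2, 2, -1): mean 1, sd sqrt(3) -> t = 1, df = 2
  expect_equal(res$test, "paired-t")
  expect_equal(res$statistic, 1, tolerance = 1e-6)
  expect_equal(res$df, 2)
  expect_equal(res$p_value, 2 * pt(-1, df = 2), tolerance = 1e-6)
  expect_equal(res$mean_diff, 1)
  expect_error(paired_compare(c(1, 2, 3), c(1, 2, 3)), "degenerate")
  expect_error(paired_compare(1:4, 1:3), "length mismatch")
})

test_that("paired comparison falls back to the signed-rank path", {
  set.seed(21)
  pre <- rnorm(40)
  post <- pre - rcauchy(40)  # heavy-tailed differences
  stopifnot(dagostino_pearson(pre - post)$p_value <= 0.05)  # oracle decision
  res <- paired_compare(pre, post)
  expect_equal(res$test, "signed-rank")
  set.seed(22)
  a <- rnorm(40); b <- a - rnorm(40, 0.1)
  stopifnot(dagostino_pearson(a - b)$p_value > 0.05)
  expect_equal(paired_compare(a, b)$test, "paired-t")
})

test_that("unpaired comparison: Welch closed form, identical groups, errors", {
  a <- c(10, 12, 11, 13); b <- c(1, 2, 1, 2)
  res <- unpaired_compare(a, b)
  se <- sqrt(var(a) / 4 + var(b) / 4)
  expect_equal(res$statistic, (mean(a) - mean(b)) / se, tolerance = 1e-6)
  expect_equal(res$test, "welch-t")
  same <- unpaired_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  expect_error(unpaired_compare(c(1, 2), c(1, 2, 3)), "at least 3")
  # rank-sum fallback on clearly non-normal groups
  set.seed(33)
  g1 <- rcauchy(50); g2 <- rcauchy(50)
  expect_equal(unpaired_compare(g1, g2)$test, "rank-sum")
})

test_that("paired_compare near-constant shift recovers the shift", {
  x <- rnorm(20)
  expect_error(paired_compare(x, x + 3), "degenerate")
  set.seed(5)
  res <- paired_compare(x + 3 + rnorm(20, sd = 1e-6), x)
  expect_equal(res$mean_diff, 3, tolerance = 1e-5)
})

test_that("reported SEMs equal SD/sqrt(n) exactly", {
  a <- c(4.2, 5.1, 3.9, 6.0, 5.5, 4.8, 5.2, 4.4)
  b <- a + rnorm(8, 1)
  res <- unpaired_compare(a, b)
  expect_identical(res$sems[["a"]], sd(a) / sqrt(8))
  expect_identical(res$sems[["b"]], sd(b) / sqrt(8))
  resp <- paired_compare(a, b)
  expect_identical(resp$sems[["pre"]], sd(a) / sqrt(8))
})

test_that("intraobserver variability: raw numbers and percentage", {
  v <- intraobserver_variability(c(100, 110), c(104, 114))
  expect_equal(v$mean_abs_diff, 4)
  expect_equal(v$percent, 4 / 107 * 100)
  ident <- intraobserver_variability(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$mean_abs_diff, 0)
  expect_equal(ident$percent, 0)
  expect_error(intraobserver_variability(1:3, 1:4), "length mismatch")
})
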