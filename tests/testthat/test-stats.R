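test_that("Fisher enumeration reproduces hand-computed and printed tables", {
  # arrhythmia incidence 5/8 vs 0/4: enumeration gives 64/792
  p <- fisher_exact_2x2(matrix(c(5, 0, 3, 4), 2))$p.value
  expect_equal(p, 64 / 792)
  expect_equal(round(p, 2), 0.08)
  # empty outcome column
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 4, 8), 2))$p.value, 1)
  # diagonal 2x2: three tables with margins (2,2)/(2,2), p = 1/3
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2))$p.value, 1 / 3)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)), "all-zero")
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
})

test_that("Fisher p is invariant under row and column swaps and lies in
           (0, 1]", {
  set.seed(5)
  for (i in 1:40) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) next
    p <- fisher_exact_2x2(tab)$p.value
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(fisher_exact_2x2(tab[2:1, ])$p.value, p)
    expect_equal(fisher_exact_2x2(tab[, 2:1])$p.value, p)
  }
})

test_that("summary t-test reproduces the printed nerve-density comparison
           and a numeric oracle", {
  # TH+ area 0.56 +- 0.40 vs 6.41 +- 2.78 %, n = 6/6 -> P = 0.0005
  r <- t_test_from_summary(summary_stats(0.56, 0.40, 6),
                           summary_stats(6.41, 2.78, 6))
  expect_equal(round(r$p.value, 4), 5e-4)
  expect_equal(r$df, 10)
  expect_lt(abs(abs(r$statistic) - 5.102), 0.01)

  r2 <- t_test_from_summary(summary_stats(0, 1, 10), summary_stats(1, 1, 10))
  expect_equal(r2$statistic, -2.236, tolerance = 1e-3)
  expect_equal(r2$df, 18)
  expect_equal(r2$p.value, 2 * pt(-abs(r2$statistic), 18), tolerance = 1e-6)

  eq <- t_test_from_summary(summary_stats(5, 1, 6), summary_stats(5, 1, 6))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
})

test_that("incomplete-beta t tail matches pt over a parameter sweep", {
  for (df in c(1, 2, 5, 10, 30, 120)) {
    for (t in c(0.1, 0.5, 1, 2.5, 5.1, 9)) {
      expect_equal(optimap:::t_two_sided_p(t, df), 2 * pt(-t, df),
                   tolerance = 1e-9)
    }
  }
})

test_that("pooled summary t equals a direct two-sample t on raw data", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(sample(3:12, 1), 2, 1.5)
    y <- rnorm(sample(3:12, 1), 0, 2.5)
    r <- t_test_from_summary(summary_stats(mean(x), sd(x), length(x)),
                             summary_stats(mean(y), sd(y), length(y)))
    o <- t.test(x, y, var.equal = TRUE)
    expect_equal(r$statistic, unname(o$statistic), tolerance = 1e-10)
    expect_equal(r$p.value, o$p.value, tolerance = 1e-8)
    w <- t_test_from_summary(summary_stats(mean(x), sd(x), length(x)),
                             summary_stats(mean(y), sd(y), length(y)),
                             variant = "welch")
    ow <- t.test(x, y)
    expect_equal(w$df, unname(ow$parameter), tolerance = 1e-10)
    expect_equal(w$p.value, ow$p.value, tolerance = 1e-8)
  }
})

test_that("degenerate zero-variance groups follow the documented sentinels", {
  expect_equal(t_test_from_summary(summary_stats(1, 0, 5),
                                   summary_stats(1, 0, 5))$p.value, 1)
  r <- t_test_from_summary(summary_stats(2, 0, 5), summary_stats(1, 0, 5))
  expect_equal(r$p.value, 0)
  expect_true(is.infinite(r$statistic))
  expect_error(t_test_from_summary(summary_stats(1, 1, 1),
                                   summary_stats(1, 1, 5)), "n >= 2")
})

test_that("exact Mann-Whitney reproduces enumeration landmarks", {
  expect_equal(mann_whitney_exact(1, 2)$p.value, 1)
  # complete separation at n = 5/5: 2 / choose(10, 5)
  r <- mann_whitney_exact(c(1.2, 1.9, 2.1, 2.5, 3), c(4, 5.5, 6, 7, 9))
  expect_equal(r$p.value, 2 / 252)
  expect_equal(round(r$p.value, 3), 0.008)
  expect_true(r$exact)
  # complete separation at n = 3/3: 2 / choose(6, 3)
  expect_equal(mann_whitney_exact(1:3, 4:6)$p.value, 0.1)
})

test_that("Mann-Whitney is invariant to sample exchange and monotone
           transforms, and matches wilcox.test without ties", {
  set.seed(13)
  for (i in 1:25) {
    x <- rnorm(sample(2:8, 1))
    y <- rnorm(sample(2:8, 1), 0.8)
    p <- mann_whitney_exact(x, y)$p.value
    expect_equal(mann_whitney_exact(y, x)$p.value, p)
    expect_equal(mann_whitney_exact(exp(x), exp(y))$p.value, p)
    expect_equal(p, wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("tied samples match a brute-force labeling enumeration", {
  naive_mw <- function(x, y) {
    n1 <- length(x)
    r <- rank(c(x, y))
    R1 <- sum(r[seq_len(n1)])
    combos <- combn(length(r), n1)
    sums <- colSums(matrix(r[combos], nrow = n1))
    p_le <- mean(sums <= R1 + 1e-9)
    p_ge <- mean(sums >= R1 - 1e-9)
    min(1, 2 * min(p_le, p_ge))
  }
  cases <- list(list(c(1, 2, 2, 3), c(2, 4, 5)),
                list(c(1, 1, 1), c(1, 1, 2, 2)),
                list(c(0.5, 2, 2), c(2, 2, 3, 3, 5)),
                list(c(7, 7, 8, 9), c(7, 8, 8)))
  for (cs in cases) {
    expect_equal(mann_whitney_exact(cs[[1]], cs[[2]])$p.value,
                 naive_mw(cs[[1]], cs[[2]]), tolerance = 1e-12)
  }
})

test_that("large samples fall back to the flagged normal approximation", {
  set.seed(2)
  x <- rnorm(15)
  y <- rnorm(15, 1)
  r <- mann_whitney_exact(x, y)
  expect_false(r$exact)
  o <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(r$p.value, o$p.value, tolerance = 0.01)
})
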