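test_that("chi-squared on identical proportions is null", {
  t0 <- chi2_2x2(10, 90, 10, 90)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  expect_error(chi2_2x2(0, 0, 5, 5), "margin")
  expect_error(chi2_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("chi-squared matches the reference implementation", {
  # the pooled published fiber counts: 90/800 vs 95/699
  t1 <- chi2_2x2(90, 710, 95, 604)
  expect_equal(t1$statistic, 1.89, tolerance = 0.01)
  expect_equal(t1$p_value, 0.17, tolerance = 0.01)
  set.seed(6)
  for (i in 1:50) {
    cells <- rpois(4, lambda = sample(c(5, 20, 100), 1)) + 1
    mine <- chi2_2x2(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(
      chisq.test(matrix(cells, 2, byrow = TRUE), correct = FALSE))
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("pooled t test reproduces the printed density comparison", {
  t0 <- two_sample_t_summary(3, 1, 5, 3, 2, 5)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # the printed 5 uM vs 20 uM summary statistics
  t1 <- two_sample_t_summary(2.69, 0.095, 3, 4.48, 0.285, 3)
  expect_equal(abs(t1$statistic), 10.32, tolerance = 0.01)
  expect_identical(t1$df, 4)
  expect_lt(t1$p_value, 0.001)
  expect_equal(t1$p_value, 5e-4, tolerance = 0.05)
  expect_error(two_sample_t_summary(1, 1, 1, 2, 1, 5), "n >= 2")
})

test_that("pooled t from summaries equals t.test on reconstructed samples", {
  set.seed(17)
  base <- c(-1, 0, 1) / sd(c(-1, 0, 1))
  for (i in 1:50) {
    m1 <- runif(1, 0, 10); m2 <- runif(1, 0, 10)
    s1 <- runif(1, 0.1, 3); s2 <- runif(1, 0.1, 3)
    x1 <- m1 + s1 * base
    x2 <- m2 + s2 * base
    mine <- two_sample_t_summary(m1, s1, 3, m2, s2, 3)
    ref <- t.test(x2, x1, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-6)
  }
})

test_that("the encounter z test is a one-sample test against one half", {
  t0 <- two_proportion_z(25, 25)
  expect_equal(t0$statistic, 0)
  expect_equal(t0$p_value, 1)
  # the pooled published encounter counts
  t1 <- two_proportion_z(19, 118)
  expect_lt(t1$p_value, 0.001)
  expect_equal(t1$statistic, (118 / 137 - 0.5) / sqrt(0.25 / 137),
               tolerance = 1e-12)
  # normal approximation never exceeds the exact binomial p
  t2 <- two_proportion_z(2, 8)
  ref <- binom.test(8, 10, 0.5)
  expect_equal(t2$p_value, 2 * pnorm(-abs((0.8 - 0.5) / sqrt(0.025))),
               tolerance = 1e-12)
  expect_lte(t2$p_value, ref$p.value)
  expect_error(two_proportion_z(0, 0), "at least one")
})

test_that("independent-sample z squared equals the 2x2 chi-squared", {
  set.seed(23)
  for (i in 1:20) {
    k1 <- sample(1:40, 1); n1 <- k1 + sample(1:40, 1)
    k2 <- sample(1:40, 1); n2 <- k2 + sample(1:40, 1)
    z <- two_proportion_z_indep(k1, n1, k2, n2)
    x2 <- chi2_2x2(k1, n1 - k1, k2, n2 - k2)
    expect_equal(z$statistic^2, x2$statistic, tolerance = 1e-9)
    expect_equal(z$p_value, x2$p_value, tolerance = 1e-9)
  }
})

test_that("t-test p decreases as the mean separation grows", {
  ps <- vapply(seq(0, 3, by = 0.5), function(d)
    two_sample_t_summary(2, 0.5, 3, 2 + d, 0.5, 3)$p_value, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("spacing comparison has correct null behavior and power", {
  x <- rexp(100, 1 / 200)
  self <- compare_spacing(x, x)
  expect_equal(self$statistic, 0)
  expect_equal(self$p_value, 1)
  expect_error(compare_spacing(numeric(0), x), "non-empty")

  set.seed(31)
  null_p <- vapply(1:100, function(i)
    compare_spacing(rexp(100, 1 / 200), rexp(100, 1 / 200))$p_value,
    numeric(1))
  expect_gte(mean(null_p > 0.05), 0.90)

  alt_p <- vapply(1:40, function(i)
    compare_spacing(rexp(300, 1 / 200), rexp(300, 1 / 400))$p_value,
    numeric(1))
  expect_gte(mean(alt_p < 0.01), 0.95)
})

test_that("all tests return probabilities and echo their inputs", {
  tests <- list(chi2_2x2(5, 10, 8, 7),
                two_sample_t_summary(1, 1, 4, 2, 1, 4),
                two_proportion_z(3, 9),
                compare_spacing(rexp(20, 1), rexp(20, 1)))
  for (t in tests) {
    expect_s3_class(t, "fiber_test")
    expect_gte(t$p_value, 0)
    expect_lte(t$p_value, 1)
    expect_output(print(t), "statistic")
  }
})
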