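test_that("identical groups give t = 0, p = 1", {
  gc <- compareGroups(list(a = c(5, 5, 5), b = c(5, 5, 5)))
  expect_equal(gc@statistic, 0)
  expect_equal(gc@pValue, 1)
  gc2 <- compareGroups(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(gc2@statistic, 0)
  expect_equal(gc2@pValue, 1)
})

test_that("degenerate group input errors", {
  expect_error(compareGroups(list(a = 1, b = c(1, 2))), "two observations")
  expect_error(compareGroups(list(a = c(1, 1), b = c(2, 2))), "degenerate")
  expect_error(compareGroups(list(a = c(101, 5), b = c(3, 4)),
                             transform = "arcsine-sqrt"), "percent")
  expect_error(compareGroups(list(a = c(-1, 5), b = c(3, 4)),
                             transform = "log"), "positive")
})

test_that("null p-values are uniform and the test holds its level", {
  ## n = 30 per group, where the Welch df approximation is accurate
  ## (it is only asymptotically exact, so tiny groups fail strict
  ## uniformity checks by design, not by defect)
  set.seed(42)
  p <- replicate(400, {
    compareGroups(list(a = rnorm(30), b = rnorm(30)))@pValue
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})

test_that("ANOVA with post-hoc tests isolates a shifted group", {
  set.seed(7)
  n <- 20
  gc <- compareGroups(list(a = rnorm(n, 10, 1), b = rnorm(n, 10, 1),
                           c = rnorm(n, 12, 1)))  # Cohen's d = 2
  expect_lt(gc@pValue, 0.05)
  ph <- gc@postHoc
  ab <- ph$group1 == "a" & ph$group2 == "b"
  expect_false(ph$rejectBonferroni[ab])
  expect_false(ph$rejectScheffe[ab])
  expect_true(all(ph$rejectBonferroni[!ab]))
  expect_true(all(ph$rejectScheffe[!ab]))
  ## group summaries stay on the original scale
  expect_equal(gc@groups$n, rep(n, 3))
})

test_that("percent data can be compared on the arcsine-sqrt scale", {
  set.seed(9)
  a <- pmin(pmax(rnorm(15, 85, 8), 0), 100)
  b <- pmin(pmax(rnorm(15, 40, 15), 0), 100)
  gc <- compareGroups(list(type2 = a, type1 = b),
                      transform = "arcsine-sqrt")
  expect_lt(gc@pValue, 0.01)
  expect_equal(gc@groups$mean, c(mean(a), mean(b)))
})

test_that("pearson correlation matches the closed-form formula", {
  x <- c(3.1, 4.7, 5.2, 6.0, 7.7, 8.1, 9.4, 10.2, 11.8, 12.5)
  y <- c(2.9, 5.3, 4.8, 6.6, 7.1, 9.0, 8.7, 11.1, 11.2, 13.4)
  got <- pearsonCor(x, y)
  ## independent evaluation from the definition
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((length(x) - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), length(x) - 2)
  expect_equal(got$r, r, tolerance = 1e-12)
  expect_equal(got$p, p, tolerance = 1e-12)
  expect_equal(got$df, 8)

  expect_equal(pearsonCor(x, x)$r, 1)
  expect_equal(pearsonCor(c(1, -1, 1, -1), c(1, 1, -1, -1))$r, 0)
  expect_error(pearsonCor(x, rep(1, 10)), "variance")
})

test_that("correlation is symmetric and affine-invariant", {
  for (s in 1:10) {
    set.seed(1000 + s)
    x <- rnorm(12); y <- rnorm(12) + 0.5 * x
    r1 <- pearsonCor(x, y)$r
    expect_equal(pearsonCor(y, x)$r, r1, tolerance = 1e-12)
    expect_equal(pearsonCor(3 * x + 7, y)$r, r1, tolerance = 1e-12)
    expect_equal(pearsonCor(x, -2 * y + 1)$r, -r1, tolerance = 1e-12)
  }
})
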