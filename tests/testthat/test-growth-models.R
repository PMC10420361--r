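test_that("the first-last rate is total growth over total time, interior points ignored", {
  expect_equal(fitFirstLast(makeSeries(c(0, 2), c(3.0, 3.6)))$rate_mm_per_yr,
               3.0)
  expect_equal(
    fitFirstLast(makeSeries(c(0, 1, 2), c(3.0, 3.9, 3.6)))$rate_mm_per_yr,
    3.0)
  expect_equal(fitFirstLast(makeSeries(c(0, 1), c(3.0, 3.0)))$rate_mm_per_yr,
               0)
  expect_error(fitFirstLast(makeSeries(0, 3.0)), "at least 2")
  expect_error(fitFirstLast(makeSeries(c(1, 1), c(3.0, 3.2))),
               "positive time span")
})

test_that("unpooled linear regression is ordinary least squares of diameter on time", {
  s <- makeSeries(c(0, 1, 2), c(3.0, 3.9, 3.6))
  gf <- fitLinearUnpooled(s)
  expect_equal(gf$rate_mm_per_yr, 3.0)   # closed-form OLS slope 0.30 cm/yr
  s2 <- makeSeries(0:4, 3 + 0.25 * (0:4))
  expect_equal(fitLinearUnpooled(s2)$rate_mm_per_yr, 2.5)
})

test_that("first-last and OLS coincide exactly on every 2-point series", {
  set.seed(12)
  for (i in 1:50) {
    t <- sort(runif(2, 0, 8))
    d <- runif(2, 2.2, 5.5)
    s <- makeSeries(t, d)
    expect_equal(fitFirstLast(s)$rate_mm_per_yr,
                 fitLinearUnpooled(s)$rate_mm_per_yr, tolerance = 1e-12)
  }
})

test_that("the unpooled exponential fit recovers noiseless parameters", {
  a <- 0.2; b <- 1.5
  s <- makeSeries(0:3, diameterAt(a, b, 0:3))
  gf <- fitExponentialUnpooled(s)
  expect_false(gf$fallback)
  expect_equal(gf$fit$a, a, tolerance = 1e-6)
  expect_equal(gf$fit$b, b, tolerance = 1e-6)

  # two points exactly determine the two parameters
  s2 <- makeSeries(c(0, 2), diameterAt(0.1, 0, c(0, 2)))
  gf2 <- fitExponentialUnpooled(s2)
  expect_false(gf2$fallback)
  expect_equal(gf2$fit$a, 0.1, tolerance = 1e-10)
  expect_equal(gf2$fit$b, 0, tolerance = 1e-8)
  expect_equal(predictDiameter(gf2, c(0, 2)), s2$diameter_cm,
               tolerance = 1e-9)
})

test_that("a shrinking series falls back to the linear fit", {
  s <- makeSeries(c(0, 1, 2), c(3.5, 3.3, 3.1))
  gf <- fitExponentialUnpooled(s)
  expect_true(gf$fallback)
  expect_false(gf$converged)
  expect_equal(gf$rate_mm_per_yr, -2.0, tolerance = 1e-10)
  # clipped downstream
  est <- clipNegativeRates(data.frame(rate_mm_per_yr = gf$rate_mm_per_yr))
  expect_equal(est$rate_clipped_mm_per_yr, 0)
  # prediction uses the fallback line
  expect_equal(predictDiameter(gf, 3), 3.5 - 0.2 * 3, tolerance = 1e-10)
})

test_that("the benchmark rate equals 5a/ln(1.25) and handles edge cases", {
  expect_equal(benchmarkRate(0.1), 5 * 0.1 / log(1.25), tolerance = 1e-12)
  expect_equal(benchmarkRate(0.1), 2.2407, tolerance = 1e-4)
  expect_equal(benchmarkRate(log(1.25) / 5), 1.0, tolerance = 1e-12)
  expect_equal(benchmarkRate(0), 0)
  expect_lt(benchmarkRate(-0.05), 0)
  expect_error(benchmarkRate(NA_real_), "finite")
})

test_that("growth rates are invariant to time translation", {
  set.seed(23)
  for (i in 1:10) {
    a <- runif(1, 0.03, 0.3); b <- runif(1, -10, 10)
    t <- sort(runif(4, 0, 6))
    d <- diameterAt(a, b, t) + rnorm(4, 0, 0.05)
    d <- pmax(d, 2.2)
    shift <- runif(1, -5, 5)
    s1 <- makeSeries(t, d)
    s2 <- makeSeries(t + shift, d)
    expect_equal(fitFirstLast(s1)$rate_mm_per_yr,
                 fitFirstLast(s2)$rate_mm_per_yr, tolerance = 1e-9)
    expect_equal(fitLinearUnpooled(s1)$rate_mm_per_yr,
                 fitLinearUnpooled(s2)$rate_mm_per_yr, tolerance = 1e-9)
    g1 <- fitExponentialUnpooled(s1)
    g2 <- fitExponentialUnpooled(s2)
    if (!g1$fallback && !g2$fallback) {
      expect_equal(g1$fit$a, g2$fit$a, tolerance = 1e-4)
      # b absorbs the shift; the standardized rate does not move
      expect_equal(g1$rate_mm_per_yr, g2$rate_mm_per_yr, tolerance = 1e-4)
    }
  }
})

test_that("predictDiameter evaluates chords, lines and curves", {
  fl <- fitFirstLast(makeSeries(c(0, 2), c(3.0, 3.6)))
  expect_equal(predictDiameter(fl, 5), 4.5)
  ef <- fitExponentialUnpooled(
    makeSeries(c(0, 2), diameterAt(0.2, 0, c(0, 2))))
  expect_equal(predictDiameter(ef, 0), 3.0, tolerance = 1e-9)
  expect_equal(predictDiameter(ef, 5), exp(1) + 2, tolerance = 1e-7)
  # monotone increasing for a > 0
  tgrid <- seq(-5, 10, by = 0.5)
  expect_true(all(diff(predictDiameter(ef, tgrid)) > 0))
})

test_that("clipNegativeRates zeroes negatives and preserves the raw column", {
  est <- data.frame(rate_mm_per_yr = c(-0.8, 1.6, 0, -3))
  out <- clipNegativeRates(est)
  expect_equal(out$rate_clipped_mm_per_yr, c(0, 1.6, 0, 0))
  expect_equal(out$rate_mm_per_yr, c(-0.8, 1.6, 0, -3))
})

test_that("fitCohortRates returns one tidy row per patient and model", {
  co <- simulateCohort(defaultCohortConfig(n_patients = 15, seed = 4))
  r <- fitCohortRates(co, models = c("first_last", "linear_unpooled",
                                     "exp_unpooled"))
  expect_equal(nrow(r), 45)
  expect_setequal(unique(r$model),
                  c("first_last", "linear_unpooled", "exp_unpooled"))
  expect_true(all(r$rate_clipped_mm_per_yr >= 0))
  expect_equal(r$rate_clipped_mm_per_yr,
               pmax(r$rate_mm_per_yr, 0))
  fits <- attr(r, "fits")
  expect_named(fits, c("first_last", "linear_unpooled", "exp_unpooled"))
  expect_length(fits$first_last, 15)
})
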