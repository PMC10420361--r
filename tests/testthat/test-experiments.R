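test_that("forecast metrics match hand arithmetic", {
  fm <- forecastMetrics(c(4.0, 3.5), c(3.8, 3.7))
  expect_equal(fm$mean_raw, 0)
  expect_equal(fm$mean_abs, 0.2)
  expect_equal(fm$mse, 0.04)
  expect_equal(fm$median_abs, 0.2)

  perfect <- forecastMetrics(c(3.1, 4.2, 5), c(3.1, 4.2, 5))
  expect_true(all(unlist(perfect[c("mse", "median_abs", "mean_abs",
                                   "mean_raw")]) == 0))

  # triangle inequality: mean |e| >= |mean e|; MSE always >= 0
  set.seed(3)
  for (i in 1:20) {
    e <- rnorm(sample(2:20, 1))
    fm <- forecastMetrics(e, numeric(length(e)))
    expect_gte(fm$mean_abs, abs(fm$mean_raw) - 1e-12)
    expect_gte(fm$mse, 0)
    expect_gte(fm$mse, fm$mean_raw^2 - 1e-12)
  }
})

test_that("Mann-Whitney U matches exact enumeration and handles ties", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1, tolerance = 1e-12)

  expect_warning(tied <- mannWhitneyU(c(1, 1, 1), c(1, 1)), "tied")
  expect_equal(tied$p, 1)

  set.seed(19)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    v <- sample(1000, n1 + n2)  # tie-free across both groups
    x <- v[seq_len(n1)]; y <- v[-seq_len(n1)]
    expect_equal(mannWhitneyU(x, y)$p, enumMannWhitneyP(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman matches exact enumeration and detects monotone association", {
  x <- c(1, 4, 9, 16, 25)
  expect_equal(spearmanTest(x, sqrt(x))$rho, 1)
  set.seed(29)
  for (n in 4:7) {
    x <- sample(1000, n); y <- sample(1000, n)
    st <- spearmanTest(x, y)
    expect_equal(st$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
    expect_equal(st$p, enumSpearmanP(x, y), tolerance = 1e-12)
  }
})

test_that("stability deltas are exactly zero for models blind to the removed points", {
  # interior-point removal: first_last only sees endpoints, so injected
  # datasets with interior points removed must give zero deltas
  mk <- function(drop_idx) {
    rows <- lapply(1:5, function(i) {
      t <- c(0, 1, 2, 4); d <- c(3, 3.2, 3.3, 3.9) + i / 100
      keep <- setdiff(seq_along(t), drop_idx)
      makeSeries(t[keep], d[keep], sprintf("q%d", i))
    })
    aaaCohort(do.call(rbind, rows))
  }
  datasets <- list(full = mk(NULL), left = mk(2), right = mk(3))
  st <- runStability(datasets$full, models = "first_last",
                     datasets = datasets)
  expect_true(all(st$deltas$delta_left == 0))
  expect_true(all(st$deltas$delta_right == 0))

  # endpoint removal on exactly linear trajectories leaves linear model
  # rates unchanged
  co <- makeLinearCohort(n = 12, noise_sd = 0, n_points = 4, seed = 6)
  st2 <- runStability(co, models = c("first_last", "linear_unpooled"))
  expect_lt(max(abs(st2$deltas$delta_left)), 1e-9)
  expect_lt(max(abs(st2$deltas$delta_right)), 1e-9)
  expect_equal(st2$summary$frac_large_change, c(0, 0))
})

test_that("risk-factor screening flags a configured effect and skips empty groups", {
  cfg <- cohortConfig(n_patients = 250, seed = 33,
                      covariate_effects = list(diabetes = 0.4),
                      covariate_prevalence = list(diabetes = 0.3),
                      numeric_covariates = list(
                        hba1c = list(mean = 6.5, sd = 1, log_a_slope = -0.4)))
  co <- simulateCohort(cfg)
  merged <- mergeCloseMeasurements(co)
  two <- suppressMessages(filterMinMeasurements(merged, 2))
  r <- fitCohortRates(two, models = c("first_last", "exp_unpooled"))
  rf <- runRiskFactors(two, r)
  a <- rf$associations
  dia <- a[a$variable == "diabetes", ]
  expect_true(all(dia$difference < 0))   # slower growth in carriers
  expect_true(any(dia$p < 0.05))
  hb <- a[a$variable == "hba1c", ]
  expect_equal(unique(hb$type), "numeric")
  expect_true(all(hb$rho < 0))
  # detection-window associations are reported for every variable
  expect_setequal(unique(rf$detection$variable), c("diabetes", "hba1c"))
  expect_setequal(unique(rf$detection$outcome), c("detection_cm", "age_yr"))
  expect_equal(rf$n_tests, nrow(a))

  # empty-group covariates are skipped with a warning
  co$covariates$always0 <- 0
  expect_warning(runRiskFactors(co, r, variables = "always0"),
                 "empty group")
})

test_that("baseline characterisation reports medians and size correlation", {
  r <- data.frame(patient_id = sprintf("p%d", 1:5), model = "first_last",
                  rate_mm_per_yr = c(1, 2, 3, 4, 5))
  co <- makeCohortFrom(
    makeSeries(0:1, c(2.6, 2.8), "p1"), makeSeries(0:1, c(3.1, 3.4), "p2"),
    makeSeries(0:1, c(3.6, 4.0), "p3"), makeSeries(0:1, c(4.1, 4.6), "p4"),
    makeSeries(0:1, c(4.6, 5.2), "p5"))
  bl <- characterizeBaseline(co, r)
  expect_equal(bl$summary$median_rate_mm_per_yr, 3)
  expect_equal(bl$summary$spearman_rho, 1)  # rates rise with detection size
  expect_setequal(bl$by_size$size_group,
                  c("<3.0", "3.0-3.4", "3.5-3.9", "4.0-4.4", ">=4.5"))
})

test_that("convexity induces detection-size correlation for chord models but not exponential fits", {
  co <- simulateCohort(defaultCohortConfig(n_patients = 250, seed = 55))
  merged <- mergeCloseMeasurements(co)
  two <- suppressMessages(filterMinMeasurements(merged, 2))
  r <- fitCohortRates(two, models = c("first_last", "exp_unpooled"))
  bl <- characterizeBaseline(two, r)
  s <- bl$summary
  fl <- s[s$model == "first_last", ]
  eu <- s[s$model == "exp_unpooled", ]
  expect_gt(fl$spearman_rho, 0)
  expect_lt(fl$spearman_p, 0.05)
  expect_lt(abs(eu$spearman_rho), abs(fl$spearman_rho))
})
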