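test_that("readCohort groups, sorts and re-zeroes time per patient", {
  tab <- data.frame(
    patient_id = c("a", "a", "a", "b", "b"),
    time_yr = c(2, 0, 1, 5, 4),
    diameter_cm = c(3.4, 3.0, 3.2, 4.0, 3.8))
  co <- readCohort(tab)
  ser <- patientSeries(co)
  expect_length(ser, 2)
  expect_equal(nrow(ser[["a"]]), 3)
  expect_equal(nrow(ser[["b"]]), 2)
  expect_equal(ser[["a"]]$time_yr, c(0, 1, 2))
  expect_equal(ser[["b"]]$time_yr, c(0, 1))  # re-zeroed to first visit
  expect_equal(ser[["a"]]$diameter_cm, c(3.0, 3.2, 3.4))
})

test_that("readCohort converts dates to years at 365.25 days/year", {
  tab <- data.frame(
    patient_id = c("a", "a"),
    date = c("2015-01-01", "2016-01-01"),
    diameter_cm = c(3.0, 3.3))
  co <- readCohort(tab)
  expect_equal(co$measurements$time_yr, c(0, 365 / 365.25),
               tolerance = 1e-10)
})

test_that("readCohort error contracts name the offending row and columns", {
  expect_error(readCohort(data.frame(patient_id = "a", time_yr = 0)),
               "diameter_cm")
  bad <- data.frame(patient_id = c("a", "a"), time_yr = c(0, 1),
                    diameter_cm = c(3.0, -1))
  expect_error(readCohort(bad), "non-positive.*'a'.*row 2")
  cov <- data.frame(patient_id = c("a", "zz"), diabetes = c(1, 0))
  good <- data.frame(patient_id = c("a", "a"), time_yr = c(0, 1),
                     diameter_cm = c(3.0, 3.1))
  expect_warning(co <- readCohort(good, cov), "ignored")
  expect_equal(co$covariates$patient_id, "a")
})

test_that("close measurements merge to cluster means", {
  s <- makeSeries(c(0, 100) / 365.25, c(3.0, 3.2))
  m <- mergeCloseMeasurements(s)
  expect_equal(nrow(m), 1)
  expect_equal(m$time_yr, 50 / 365.25)
  expect_equal(m$diameter_cm, 3.1)

  s2 <- makeSeries(c(0, 200) / 365.25, c(3.0, 3.4))
  expect_equal(mergeCloseMeasurements(s2)$diameter_cm, c(3.0, 3.4))

  # {0, 100} cluster; 290 stands alone (gap to the previous cluster
  # member, 290 - 100 = 190 days, is at least the window)
  s3 <- makeSeries(c(0, 100, 290) / 365.25, c(3.0, 3.2, 3.4))
  m3 <- mergeCloseMeasurements(s3)
  expect_equal(m3$time_yr, c(50, 290) / 365.25)
  expect_equal(m3$diameter_cm, c(3.1, 3.4))

  # three points each 100 days apart chain into one cluster even though
  # the endpoints are 200 days apart
  s4 <- makeSeries(c(0, 100, 200) / 365.25, c(3.0, 3.2, 3.4))
  m4 <- mergeCloseMeasurements(s4)
  expect_equal(nrow(m4), 1)
  expect_equal(m4$time_yr, 100 / 365.25)
  expect_equal(m4$diameter_cm, 3.2)
})

test_that("merging matches an independent oracle and is idempotent and mass-preserving", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:10, 1)
    t <- sort(runif(n, 0, 6))
    d <- runif(n, 2.5, 5)
    s <- makeSeries(t, d)
    m <- mergeCloseMeasurements(s)
    o <- oracleMerge(t, d)
    expect_equal(m$time_yr, o$time, tolerance = 1e-12)
    expect_equal(m$diameter_cm, o$diameter, tolerance = 1e-12)
    # mass preservation: cluster sizes x cluster means recover the sum
    expect_equal(sum(o$sizes * m$diameter_cm), sum(d), tolerance = 1e-9)
    # all consecutive gaps now at least the window
    if (nrow(m) > 1) expect_true(all(diff(m$time_yr) >= 150 / 365.25))
    # idempotence
    expect_equal(mergeCloseMeasurements(m), m)
  }
})

test_that("minimum-measurement filter keeps exactly the right patients", {
  co <- makeCohortFrom(
    makeSeries(0:1, c(3, 3.1), "a"),
    makeSeries(0:2, c(3, 3.1, 3.2), "b"),
    makeSeries(0:4, c(3, 3.1, 3.2, 3.3, 3.4), "c"),
    makeSeries(0, 3, "d"))
  expect_message(f2 <- filterMinMeasurements(co, 2), "3 patients")
  expect_equal(nPatients(f2), 3)
  expect_message(f3 <- filterMinMeasurements(co, 3), "2 patients")
  expect_equal(nPatients(f3), 2)
  expect_error(filterMinMeasurements(co, 0), "k must be")
  empty <- suppressMessages(filterMinMeasurements(co, 10))
  expect_equal(nPatients(empty), 0)
  expect_equal(nPatients(suppressMessages(filterMinMeasurements(empty, 2))),
               0)
})

test_that("endpoint censoring drops exactly the first/last point per patient", {
  co <- makeCohortFrom(
    makeSeries(c(0, 1, 2), c(3.0, 3.2, 3.5), "a"),
    makeSeries(c(0, 0.8, 1.7, 3.1), c(3.1, 3.2, 3.4, 3.8), "b"))
  cs <- makeCensoredDatasets(co)
  expect_named(cs, c("full", "left", "right"))
  a_left <- patientSeries(cs$left)[["a"]]
  a_right <- patientSeries(cs$right)[["a"]]
  expect_equal(a_left$time_yr, c(1, 2))      # earliest removed, no re-zero
  expect_equal(a_right$time_yr, c(0, 1))     # latest removed
  for (nm in c("left", "right")) {
    counts_full <- table(cs$full$measurements$patient_id)
    counts_cens <- table(cs[[nm]]$measurements$patient_id)
    expect_equal(as.numeric(counts_cens), as.numeric(counts_full) - 1)
    expect_equal(nPatients(cs[[nm]]), nPatients(cs$full))
  }
  bad <- makeCohortFrom(makeSeries(0:1, c(3, 3.1), "x"))
  expect_error(makeCensoredDatasets(bad), ">= 3 measurements")
})

test_that("forecast splits censor the pre-target gap, then merge", {
  # all training candidates retained
  co1 <- makeCohortFrom(makeSeries(c(0, 1, 2, 5), c(3, 3.1, 3.3, 4), "a"))
  sp1 <- suppressMessages(makeForecastSplits(co1))
  expect_length(sp1$splits, 1)
  expect_equal(sp1$splits[["a"]]$target_time_yr, 5)
  expect_equal(sp1$splits[["a"]]$train$time_yr, c(0, 1, 2))

  # measurement 4.5 lies within 2 years of the target and is censored,
  # leaving one point: patient excluded
  co2 <- makeCohortFrom(makeSeries(c(0, 4.5, 5), c(3, 3.8, 4), "b"))
  sp2 <- suppressMessages(makeForecastSplits(co2))
  expect_length(sp2$splits, 0)
  expect_equal(sp2$n_excluded, 1L)

  # censor first, then merge: 0 and 0.3 yr (109.6 days) merge afterwards
  co3 <- makeCohortFrom(makeSeries(c(0, 0.3, 3, 6), c(3.0, 3.1, 3.4, 4), "c"))
  sp3 <- suppressMessages(makeForecastSplits(co3))
  tr <- sp3$splits[["c"]]$train
  expect_equal(tr$time_yr, c(0.15, 3))
  expect_equal(tr$diameter_cm, c(3.05, 3.4))

  # invariant on simulated data: every training time at least gap_yr
  # before the target
  co <- simulateCohort(defaultCohortConfig(n_patients = 60, seed = 8))
  sp <- suppressMessages(makeForecastSplits(co))
  for (s in sp$splits) {
    expect_lte(max(s$train$time_yr), s$target_time_yr - 2)
    expect_gte(nrow(s$train), 2)
  }
})
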