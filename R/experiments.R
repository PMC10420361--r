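#' Mann-Whitney U test between two groups of growth rates
#'
#' Two-sided rank-sum comparison. Uses the exact null distribution for
#' small tie-free samples and the normal approximation with tie and
#' continuity correction otherwise (the behaviour of [stats::wilcox.test()]).
#' If every value in both groups is identical the test is degenerate: the
#' p-value is reported as 1 with a tie warning.
#'
#' @param x,y numeric vectors (e.g. clipped growth rates of carriers and
#'   non-carriers of a risk factor).
#' @return list with `U` (the statistic for `x`), `p`, `n_x`, `n_y`.
#' @export
mannWhitneyU <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) == 0 || length(y) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(x, y))) == 1) {
    warning("all values tied across both groups; p reported as 1")
    return(list(U = length(x) * length(y) / 2, p = 1,
                n_x = length(x), n_y = length(y)))
  }
  wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       n_x = length(x), n_y = length(y))
}

#' Spearman rank correlation with p-value
#'
#' Two-sided Spearman rank test; exact p for small tie-free samples,
#' otherwise the usual approximation (the behaviour of
#' [stats::cor.test()]). Incomplete pairs are dropped.
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p`, `n` (complete pairs used).
#' @export
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Forecast error metrics
#'
#' The projection error is predicted minus actual diameter at the held-out
#' target. Four summaries: mean of squared errors (cm^2), median and mean
#' of absolute errors (cm), and the mean of the raw signed errors (cm; a
#' negative mean means the model tends to underestimate future diameter).
#'
#' @param predicted,actual numeric vectors, cm.
#' @return list with `mse`, `median_abs`, `mean_abs`, `mean_raw`, `n`.
#' @export
forecastMetrics <- function(predicted, actual) {
  stopifnot(length(predicted) == length(actual))
  e <- predicted - actual
  list(mse = mean(e^2), median_abs = median(abs(e)),
       mean_abs = mean(abs(e)), mean_raw = mean(e), n = length(e))
}

allModels <- c("first_last", "linear_unpooled", "exp_unpooled",
               "linear_mixed", "exp_mixed")

#' Censoring stability experiment
#'
#' Fits every requested model to the full cohort and to its left- and
#' right-censored copies (each patient's earliest / latest measurement
#' removed) and compares the per-patient growth-rate estimates. A
#' noise-tolerant model changes little when a single endpoint is removed;
#' a temporally unbiased model changes symmetrically. Reported per model:
#' mean/median/IQR of the left and right deltas (censored minus full rate,
#' mm/year), the fraction of patients with |delta| above 10 mm/year (1
#' cm/year), the asymmetry statistic `mean(delta_left) -
#' mean(delta_right)` (a direction-blind model changes the same way
#' whichever endpoint is removed, so its left and right deltas share a
#' mean and the statistic is about 0; a temporally biased model inflates
#' after left-censoring and deflates after right-censoring, pushing it
#' positive), and a two-sided Mann-Whitney comparison of the
#' `delta_left` and `delta_right` distributions.
#'
#' @param cohort an [aaaCohort()] merged and filtered to >= 3
#'   measurements per patient.
#' @param models models to compare (default all five).
#' @param control sampler settings for the mixed models.
#' @param datasets optionally, a pre-built list of `full`/`left`/`right`
#'   cohorts (as from [makeCensoredDatasets()]); built from `cohort` when
#'   omitted.
#' @return An `aaaStabilityResult`: list with `deltas` (per patient and
#'   model) and `summary` (per model).
#' @export
runStability <- function(cohort, models = allModels,
                         control = samplerControl(), datasets = NULL) {
  if (is.null(datasets)) datasets <- makeCensoredDatasets(cohort)
  rates <- lapply(datasets, fitCohortRates, models = models,
                  control = control)
  deltas <- NULL
  for (m in unique(rates$full$model)) {
    rf <- rates$full[rates$full$model == m, ]
    rl <- rates$left[rates$left$model == m, ]
    rr <- rates$right[rates$right$model == m, ]
    ids <- Reduce(intersect, list(rf$patient_id, rl$patient_id,
                                  rr$patient_id))
    df <- data.frame(
      patient_id = ids, model = m,
      rate_full = rf$rate_mm_per_yr[match(ids, rf$patient_id)],
      rate_left = rl$rate_mm_per_yr[match(ids, rl$patient_id)],
      rate_right = rr$rate_mm_per_yr[match(ids, rr$patient_id)],
      stringsAsFactors = FALSE)
    df$delta_left <- df$rate_left - df$rate_full
    df$delta_right <- df$rate_right - df$rate_full
    deltas <- rbind(deltas, df)
  }
  summary <- do.call(rbind, lapply(split(deltas, deltas$model), function(d) {
    # all-tied deltas (e.g. exactly linear cohorts) degenerate to p = 1
    symm <- suppressWarnings(mannWhitneyU(d$delta_left, d$delta_right))
    data.frame(
      model = d$model[1], n = nrow(d),
      mean_delta_left = mean(d$delta_left),
      mean_delta_right = mean(d$delta_right),
      median_delta_left = median(d$delta_left),
      median_delta_right = median(d$delta_right),
      iqr_delta_left = stats::IQR(d$delta_left),
      iqr_delta_right = stats::IQR(d$delta_right),
      frac_large_change = mean(abs(c(d$delta_left, d$delta_right)) > 10),
      asymmetry = mean(d$delta_left) - mean(d$delta_right),
      symmetry_p = symm$p,
      stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  summary <- summary[match(intersect(allModels, summary$model),
                           summary$model), ]
  structure(list(deltas = deltas, summary = summary),
            class = "aaaStabilityResult")
}

#' @export
print.aaaStabilityResult <- function(x, ...) {
  cat("Censoring stability (rates in mm/year):\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Future-diameter forecasting experiment
#'
#' Builds train/target splits with [makeForecastSplits()] (each patient's
#' last measurement is the target; anything within `gap_yr` years before
#' it is censored from training), fits every requested model on the
#' training data only, predicts each patient's diameter at the target
#' time, and summarises the projection errors with [forecastMetrics()]
#' plus the mean over patients of each model's mean squared residual to
#' its own training points.
#'
#' @param cohort a raw (unmerged) [aaaCohort()].
#' @param models models to compare.
#' @param control sampler settings for the mixed models.
#' @param gap_yr,window_days passed to [makeForecastSplits()].
#' @param splits optionally a pre-built `aaaForecastSplits`.
#' @return An `aaaForecastResult`: list with `errors` (per patient and
#'   model: predicted, actual, raw error) and `metrics` (per model: the
#'   four projection-error summaries and `train_mse`).
#' @export
runForecast <- function(cohort, models = allModels,
                        control = samplerControl(), gap_yr = 2.0,
                        window_days = 150, splits = NULL) {
  if (is.null(splits)) {
    splits <- makeForecastSplits(cohort, gap_yr = gap_yr,
                                 window_days = window_days)
  }
  sp <- splits$splits
  if (length(sp) == 0) stop("no forecastable patients", call. = FALSE)
  train_meas <- do.call(rbind, c(lapply(sp, `[[`, "train"),
                                 list(make.row.names = FALSE)))
  train_cohort <- rebuildCohort(cohort, train_meas)
  rates <- fitCohortRates(train_cohort, models = models, control = control)
  fits <- attr(rates, "fits")
  target_t <- vapply(sp, `[[`, 0, "target_time_yr")
  target_d <- vapply(sp, `[[`, 0, "target_diameter_cm")
  ids <- vapply(sp, `[[`, "", "patient_id")
  errors <- NULL
  metrics <- NULL
  for (m in names(fits)) {
    pred <- vapply(ids, function(id) {
      predictDiameter(fits[[m]][[id]], target_t[[id]])
    }, 0)
    e <- data.frame(patient_id = ids, model = m, predicted_cm = pred,
                    actual_cm = target_d, raw_error_cm = pred - target_d,
                    stringsAsFactors = FALSE)
    errors <- rbind(errors, e)
    fm <- forecastMetrics(pred, target_d)
    train_mse <- mean(vapply(ids, function(id) {
      tr <- sp[[id]]$train
      mean((predictDiameter(fits[[m]][[id]], tr$time_yr) -
              tr$diameter_cm)^2)
    }, 0))
    metrics <- rbind(metrics, data.frame(
      model = m, n = fm$n, mse = fm$mse, median_abs = fm$median_abs,
      mean_abs = fm$mean_abs, mean_raw = fm$mean_raw,
      train_mse = train_mse, stringsAsFactors = FALSE))
  }
  rownames(errors) <- rownames(metrics) <- NULL
  metrics <- metrics[match(intersect(allModels, metrics$model),
                           metrics$model), ]
  structure(list(errors = errors, metrics = metrics, splits = splits),
            class = "aaaForecastResult")
}

#' @export
print.aaaForecastResult <- function(x, ...) {
  cat("Forecasting errors (cm; mse and train_mse in cm^2):\n")
  print(x$metrics, digits = 4, row.names = FALSE)
  invisible(x)
}

isBinaryVariable <- function(v) {
  u <- unique(v[!is.na(v)])
  length(u) <= 2 && all(u %in% c(0, 1, TRUE, FALSE))
}

#' Risk-factor screening across growth models
#'
#' Tests each clinical variable against the clipped growth rates of each
#' model: two-sided Mann-Whitney U for binary variables, Spearman rank
#' correlation for numeric variables, flagging p below 0.05 (and
#' borderline p below 0.1) without adjustment for repeated comparisons
#' (the number of tests is recorded in the result). Each variable is also
#' tested against the model-independent diameter at detection and age at
#' detection, since a variable that shifts the observation window can
#' confound rate associations.
#'
#' @param cohort an [aaaCohort()] with a covariate table.
#' @param rates a rate table from [fitCohortRates()] (clipped rates are
#'   used; the clipped column is recomputed if absent).
#' @param variables covariate columns to test; default every covariate
#'   except `patient_id` and `age_at_detection_yr`.
#' @return An `aaaRiskFactorResult`: list with `associations` (variable x
#'   model), `detection` (variable vs detection size/age) and `n_tests`.
#' @export
runRiskFactors <- function(cohort, rates, variables = NULL) {
  cov <- cohort$covariates
  if (is.null(cov)) stop("cohort has no covariate table", call. = FALSE)
  if (is.null(rates$rate_clipped_mm_per_yr)) {
    rates <- clipNegativeRates(rates)
  }
  if (is.null(variables)) {
    variables <- setdiff(names(cov), c("patient_id", "age_at_detection_yr"))
  }
  meas <- cohort$measurements
  det <- data.frame(
    patient_id = meas$patient_id[!duplicated(meas$patient_id)],
    detection_cm = meas$diameter_cm[!duplicated(meas$patient_id)],
    stringsAsFactors = FALSE)
  det$age_yr <- if ("age_at_detection_yr" %in% names(cov)) {
    cov$age_at_detection_yr[match(det$patient_id, cov$patient_id)]
  } else NA_real_

  assoc <- NULL
  detection <- NULL
  for (v in variables) {
    val <- cov[[v]][match(det$patient_id, cov$patient_id)]
    binary <- isBinaryVariable(val)
    if (binary && (sum(val == 1, na.rm = TRUE) == 0 ||
                   sum(val == 0, na.rm = TRUE) == 0)) {
      warning("variable '", v, "' has an empty group; skipped")
      next
    }
    for (m in unique(rates$model)) {
      r <- rates[rates$model == m, ]
      rv <- r$rate_clipped_mm_per_yr[match(det$patient_id, r$patient_id)]
      ok <- !is.na(val) & is.finite(rv)
      if (binary) {
        g1 <- rv[ok & val == 1]; g0 <- rv[ok & val == 0]
        mw <- mannWhitneyU(g1, g0)
        assoc <- rbind(assoc, data.frame(
          variable = v, type = "categorical", model = m,
          n_present = mw$n_x, n_absent = mw$n_y,
          mean_present = mean(g1), mean_absent = mean(g0),
          difference = mean(g1) - mean(g0),
          statistic = mw$U, rho = NA_real_, p = mw$p,
          stringsAsFactors = FALSE))
      } else {
        st <- spearmanTest(val[ok], rv[ok])
        assoc <- rbind(assoc, data.frame(
          variable = v, type = "numeric", model = m,
          n_present = st$n, n_absent = NA_integer_,
          mean_present = NA_real_, mean_absent = NA_real_,
          difference = NA_real_,
          statistic = NA_real_, rho = st$rho, p = st$p,
          stringsAsFactors = FALSE))
      }
    }
    for (outcome in c("detection_cm", "age_yr")) {
      ov <- det[[outcome]]
      ok <- !is.na(val) & is.finite(ov)
      if (sum(ok) < 3) next
      if (binary) {
        g1 <- ov[ok & val == 1]; g0 <- ov[ok & val == 0]
        if (length(g1) == 0 || length(g0) == 0) next
        mw <- mannWhitneyU(g1, g0)
        detection <- rbind(detection, data.frame(
          variable = v, outcome = outcome, type = "categorical",
          mean_present = mean(g1), mean_absent = mean(g0),
          difference = mean(g1) - mean(g0), rho = NA_real_, p = mw$p,
          stringsAsFactors = FALSE))
      } else {
        st <- spearmanTest(val[ok], ov[ok])
        detection <- rbind(detection, data.frame(
          variable = v, outcome = outcome, type = "numeric",
          mean_present = NA_real_, mean_absent = NA_real_,
          difference = NA_real_, rho = st$rho, p = st$p,
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(assoc)) {
    assoc$significant <- assoc$p < 0.05
    assoc$borderline <- assoc$p < 0.1
    rownames(assoc) <- NULL
  }
  if (!is.null(detection)) rownames(detection) <- NULL
  structure(list(associations = assoc, detection = detection,
                 n_tests = nrow(assoc) %||% 0L),
            class = "aaaRiskFactorResult")
}

#' @export
print.aaaRiskFactorResult <- function(x, ...) {
  cat(sprintf(
    "Risk-factor screening: %d tests, no multiple-testing adjustment\n",
    x$n_tests))
  if (!is.null(x$associations)) {
    print(x$associations[, c("variable", "model", "difference", "rho",
                             "p", "significant")],
          digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Baseline characterisation of the growth-rate distributions
#'
#' Per model: the median clipped growth rate and the Spearman correlation
#' between the growth rate and the diameter at detection (the first
#' measurement), plus rates binned by starting-size group. A strong
#' positive correlation indicates that the model assigns higher rates to
#' aneurysms detected at larger sizes -- the signature of temporal bias in
#' linear growth summaries of a convex natural history.
#'
#' @param cohort an [aaaCohort()].
#' @param rates a rate table from [fitCohortRates()].
#' @param use_clipped summarise clipped (default) or raw rates.
#' @return An `aaaBaselineResult`: list with `summary` (per model:
#'   `median_rate`, `spearman_rho`, `spearman_p`) and `by_size` (mean and
#'   median rate per starting-size bin).
#' @export
characterizeBaseline <- function(cohort, rates, use_clipped = TRUE) {
  if (is.null(rates$rate_clipped_mm_per_yr)) {
    rates <- clipNegativeRates(rates)
  }
  col <- if (use_clipped) "rate_clipped_mm_per_yr" else "rate_mm_per_yr"
  meas <- cohort$measurements
  det <- data.frame(
    patient_id = meas$patient_id[!duplicated(meas$patient_id)],
    detection_cm = meas$diameter_cm[!duplicated(meas$patient_id)],
    stringsAsFactors = FALSE)
  bins <- c(0, 3.0, 3.5, 4.0, 4.5, Inf)
  labels <- c("<3.0", "3.0-3.4", "3.5-3.9", "4.0-4.4", ">=4.5")
  det$size_group <- cut(det$detection_cm, bins, labels = labels,
                        right = FALSE)
  summary <- NULL
  by_size <- NULL
  for (m in unique(rates$model)) {
    r <- rates[rates$model == m, ]
    rv <- r[[col]][match(det$patient_id, r$patient_id)]
    st <- spearmanTest(det$detection_cm, rv)
    summary <- rbind(summary, data.frame(
      model = m, n = sum(is.finite(rv)),
      median_rate_mm_per_yr = median(rv, na.rm = TRUE),
      spearman_rho = st$rho, spearman_p = st$p, stringsAsFactors = FALSE))
    for (g in levels(det$size_group)) {
      sel <- !is.na(det$size_group) & det$size_group == g & is.finite(rv)
      if (!any(sel)) next
      by_size <- rbind(by_size, data.frame(
        model = m, size_group = g, n = sum(sel),
        mean_rate = mean(rv[sel]), median_rate = median(rv[sel]),
        stringsAsFactors = FALSE))
    }
  }
  rownames(summary) <- NULL
  summary <- summary[match(intersect(allModels, summary$model),
                           summary$model), ]
  structure(list(summary = summary, by_size = by_size),
            class = "aaaBaselineResult")
}

#' @export
print.aaaBaselineResult <- function(x, ...) {
  cat("Baseline characterisation (clipped rates, mm/year):\n")
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
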