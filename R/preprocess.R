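#' Merge close-together measurements
#'
#' To prevent extreme slopes from measurements taken almost simultaneously,
#' measurements of the same patient less than `window_days` apart are
#' averaged together. Clustering is greedy left-to-right: a cluster starts
#' at the earliest unclustered point and absorbs each subsequent point lying
#' less than `window_days` after the previous point in the cluster (so a
#' chain of points each 100 days apart forms one cluster). Each cluster is
#' replaced by a single measurement at the mean time with the mean diameter.
#' The result has all consecutive gaps `>= window_days` and the operation is
#' idempotent and preserves total measurement mass
#' (`sum(cluster size * cluster mean) == original diameter sum`).
#'
#' @param x an [aaaCohort()] (merged per patient) or a single patient's
#'   measurement data.frame (`time_yr`, `diameter_cm`).
#' @param window_days merging window, days (default 150).
#' @return Object of the same type as `x`.
#' @export
mergeCloseMeasurements <- function(x, window_days = 150) {
  if (inherits(x, "aaaCohort")) {
    merged <- lapply(patientSeries(x), mergeSeries, window_days = window_days)
    return(rebuildCohort(x, do.call(rbind, c(merged,
                                             list(make.row.names = FALSE)))))
  }
  mergeSeries(x, window_days)
}

mergeSeries <- function(series, window_days) {
  n <- nrow(series)
  if (n <= 1) return(series)
  window_yr <- window_days / 365.25
  t <- series$time_yr
  cluster <- integer(n)
  cluster[1] <- 1L
  for (j in 2:n) {
    cluster[j] <- if (t[j] - t[j - 1] < window_yr) cluster[j - 1]
                  else cluster[j - 1] + 1L
  }
  out <- series[!duplicated(cluster), , drop = FALSE]
  out$time_yr <- as.numeric(tapply(series$time_yr, cluster, mean))
  out$diameter_cm <- as.numeric(tapply(series$diameter_cm, cluster, mean))
  rownames(out) <- NULL
  out
}

#' Keep patients with at least k measurements
#'
#' @param cohort an [aaaCohort()].
#' @param k minimum number of measurements per patient (>= 1).
#' @return The filtered cohort; the retained patient count is reported via
#'   a message.
#' @export
filterMinMeasurements <- function(cohort, k) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  counts <- table(cohort$measurements$patient_id)
  keep <- names(counts)[counts >= k]
  meas <- cohort$measurements[cohort$measurements$patient_id %in% keep, ,
                              drop = FALSE]
  message(length(keep), " patients had at least ", k, " measurements")
  if (nrow(meas) == 0) {
    out <- cohort
    out$measurements <- meas
    out$covariates <- if (!is.null(cohort$covariates))
      cohort$covariates[0, , drop = FALSE]
    out$truth <- if (!is.null(cohort$truth)) cohort$truth[0, , drop = FALSE]
    return(out)
  }
  rebuildCohort(cohort, meas)
}

#' Build left- and right-censored copies of a cohort
#'
#' Simulates missing natural history: the left-censored dataset removes
#' each patient's earliest measurement (an aneurysm detected late in its
#' course); the right-censored dataset removes each patient's latest
#' measurement (an aneurysm not yet followed to a large size). Every
#' patient must have at least 3 measurements so each censored series keeps
#' at least 2. Times keep their original per-patient origin (growth-rate
#' estimates are translation invariant for every model here).
#'
#' @param cohort an [aaaCohort()], already merged and filtered to >= 3
#'   measurements per patient.
#' @return Named list of three cohorts over the identical patient set:
#'   `full`, `left`, `right`.
#' @export
makeCensoredDatasets <- function(cohort) {
  counts <- table(cohort$measurements$patient_id)
  if (any(counts < 3)) {
    stop("all patients must have >= 3 measurements before endpoint ",
         "censoring; found one with ", min(counts), call. = FALSE)
  }
  meas <- cohort$measurements
  firstRow <- !duplicated(meas$patient_id)
  lastRow <- !duplicated(meas$patient_id, fromLast = TRUE)
  list(full = cohort,
       left = rebuildCohort(cohort, meas[!firstRow, , drop = FALSE]),
       right = rebuildCohort(cohort, meas[!lastRow, , drop = FALSE]))
}

#' Build train/target splits for future-diameter forecasting
#'
#' For each patient of a raw (unmerged) cohort, the last measurement
#' becomes the prediction target; the target and any measurement less than
#' `gap_yr` years before it are censored from the training data, so the
#' forecast spans a substantial gap. The surviving points are then merged
#' with [mergeCloseMeasurements()] (censor first, then merge) and the
#' patient is kept only if at least 2 training points remain.
#'
#' @param cohort an [aaaCohort()] of raw series.
#' @param gap_yr minimum gap between the last training point and the
#'   target, years (default 2).
#' @param window_days merging window passed on, days.
#' @return Object of class `aaaForecastSplits`: a list with `splits` (one
#'   element per retained patient: `patient_id`, `train` data.frame,
#'   `target_time_yr`, `target_diameter_cm`) and `n_excluded`.
#' @export
makeForecastSplits <- function(cohort, gap_yr = 2.0, window_days = 150) {
  out <- list()
  excluded <- 0L
  for (series in patientSeries(cohort)) {
    n <- nrow(series)
    if (n < 2) { excluded <- excluded + 1L; next }
    target_t <- series$time_yr[n]
    target_d <- series$diameter_cm[n]
    train <- series[series$time_yr <= target_t - gap_yr, , drop = FALSE]
    train <- mergeSeries(train, window_days)
    if (nrow(train) < 2) { excluded <- excluded + 1L; next }
    out[[series$patient_id[1]]] <-
      list(patient_id = series$patient_id[1], train = train,
           target_time_yr = target_t, target_diameter_cm = target_d)
  }
  message(length(out), " patients retained for forecasting (",
          excluded, " excluded)")
  structure(list(splits = out, n_excluded = excluded),
            class = "aaaForecastSplits")
}

#' @export
print.aaaForecastSplits <- function(x, ...) {
  cat(sprintf("aaaForecastSplits: %d patients (%d excluded)\n",
              length(x$splits), x$n_excluded))
  invisible(x)
}
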