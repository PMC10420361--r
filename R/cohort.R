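#' Construct a surveillance cohort object
#'
#' An `aaaCohort` bundles the long-format measurement table with the
#' per-patient covariate table (and, for simulated cohorts, the generative
#' truth). It is the unit every preprocessing, fitting and evaluation
#' function in the package operates on.
#'
#' @param measurements data.frame with columns `patient_id`, `time_yr`
#'   (years since that patient's first measurement), `diameter_cm`
#'   (maximal aortic diameter, cm) and optionally `modality`.
#' @param covariates optional data.frame keyed by `patient_id`; remaining
#'   columns are clinical variables (binary flags coded 0/1, or numeric).
#' @param truth optional data.frame of generative truth for simulated
#'   cohorts: `patient_id`, `a_true`, `b_true`, `detection_diameter_cm`.
#'
#' @return An object of class `aaaCohort`: a list with elements
#'   `measurements`, `covariates`, `truth`.
#' @seealso [readCohort()], [simulateCohort()]
#' @export
aaaCohort <- function(measurements, covariates = NULL, truth = NULL) {
  req <- c("patient_id", "time_yr", "diameter_cm")
  miss <- setdiff(req, names(measurements))
  if (length(miss) > 0) {
    stop("measurement table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  measurements$patient_id <- as.character(measurements$patient_id)
  if (is.null(measurements$modality)) measurements$modality <- NA_character_
  bad <- which(!is.finite(measurements$diameter_cm) |
                 measurements$diameter_cm <= 0)
  if (length(bad) > 0) {
    stop(sprintf(
      "non-positive or missing diameter for patient '%s' (row %d)",
      measurements$patient_id[bad[1]], bad[1]), call. = FALSE)
  }
  if (any(!is.finite(measurements$time_yr) | measurements$time_yr < 0)) {
    stop("measurement times must be finite and >= 0 years", call. = FALSE)
  }
  ord <- order(measurements$patient_id, measurements$time_yr)
  measurements <- measurements[ord, c(req, "modality"), drop = FALSE]
  rownames(measurements) <- NULL
  dup <- stats::aggregate(time_yr ~ patient_id, measurements,
                          function(t) anyDuplicated(t) > 0)
  if (any(dup$time_yr)) {
    stop("duplicate measurement times for patient '",
         dup$patient_id[which(dup$time_yr)[1]], "'", call. = FALSE)
  }
  if (!is.null(covariates)) {
    if (is.null(covariates$patient_id)) {
      stop("covariate table must have a patient_id column", call. = FALSE)
    }
    covariates$patient_id <- as.character(covariates$patient_id)
    unmatched <- setdiff(covariates$patient_id, measurements$patient_id)
    if (length(unmatched) > 0) {
      warning(length(unmatched),
              " covariate row(s) without measurements were ignored")
      covariates <- covariates[!covariates$patient_id %in% unmatched, ,
                               drop = FALSE]
    }
    rownames(covariates) <- NULL
  }
  structure(list(measurements = measurements, covariates = covariates,
                 truth = truth),
            class = "aaaCohort")
}

#' @export
print.aaaCohort <- function(x, ...) {
  n <- nPatients(x)
  m <- nrow(x$measurements)
  cat(sprintf("aaaCohort: %d patients, %d measurements (%.1f per patient)\n",
              n, m, if (n > 0) m / n else 0))
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(setdiff(names(x$covariates), "patient_id"),
                             collapse = ", "), "\n")
  }
  if (!is.null(x$truth)) cat("simulated cohort (generative truth attached)\n")
  invisible(x)
}

#' Number of patients in a cohort
#' @param cohort an [aaaCohort()].
#' @return integer count of distinct patients.
#' @export
nPatients <- function(cohort) {
  length(unique(cohort$measurements$patient_id))
}

#' Split a cohort into per-patient measurement series
#'
#' @param cohort an [aaaCohort()].
#' @return Named list (by patient id) of time-ordered data.frames with
#'   columns `patient_id`, `time_yr`, `diameter_cm`, `modality`.
#' @export
patientSeries <- function(cohort) {
  split(cohort$measurements, cohort$measurements$patient_id)
}

# Rebuild a cohort from an edited measurement table, keeping covariates and
# truth rows for the patients still present.
rebuildCohort <- function(cohort, measurements) {
  keep <- unique(measurements$patient_id)
  cov <- cohort$covariates
  if (!is.null(cov)) cov <- cov[cov$patient_id %in% keep, , drop = FALSE]
  tr <- cohort$truth
  if (!is.null(tr)) tr <- tr[tr$patient_id %in% keep, , drop = FALSE]
  aaaCohort(measurements, covariates = cov, truth = tr)
}

#' Read a surveillance cohort from long-format tables
#'
#' Accepts either data.frames or CSV paths. The measurement table must have
#' columns `patient_id`, `diameter_cm`, and a time column: `time_yr`
#' (numeric years) or a date column (`date`, parsed as `YYYY-MM-DD`), which
#' is converted to years since each patient's first measurement using
#' 365.25 days/year. The optional covariate table is keyed by `patient_id`;
#' covariate rows with no matching measurements are dropped with a warning.
#'
#' @param measurements data.frame or CSV path of measurements.
#' @param covariates optional data.frame or CSV path of per-patient
#'   covariates.
#' @return An [aaaCohort()].
#' @export
readCohort <- function(measurements, covariates = NULL) {
  if (is.character(measurements)) {
    measurements <- read.csv(measurements, stringsAsFactors = FALSE)
  }
  if (is.character(covariates)) {
    covariates <- read.csv(covariates, stringsAsFactors = FALSE)
  }
  if (is.null(measurements$patient_id) || is.null(measurements$diameter_cm)) {
    stop("measurement table must have patient_id and diameter_cm columns",
         call. = FALSE)
  }
  tcol <- intersect(c("time_yr", "date_or_time_yr", "date", "time"),
                    names(measurements))
  if (length(tcol) == 0) {
    stop("measurement table must have a time column ",
         "(time_yr, date_or_time_yr, date or time)", call. = FALSE)
  }
  tval <- measurements[[tcol[1]]]
  if (inherits(tval, "Date") ||
      (is.character(tval) && all(grepl("^\\d{4}-\\d{2}-\\d{2}$",
                                       tval[!is.na(tval)])))) {
    d <- as.Date(tval)
    first <- tapply(d, measurements$patient_id, min)
    measurements$time_yr <-
      as.numeric(d - first[as.character(measurements$patient_id)]) / 365.25
  } else {
    tval <- as.numeric(tval)
    first <- tapply(tval, measurements$patient_id, min)
    measurements$time_yr <- tval -
      as.numeric(first[as.character(measurements$patient_id)])
  }
  aaaCohort(measurements, covariates = covariates)
}

#' Write a cohort to CSV files
#'
#' Writes `measurements.csv`, `covariates.csv` (if present) and `truth.csv`
#' (if present, simulated cohorts only) into `dir`.
#'
#' @param cohort an [aaaCohort()].
#' @param dir output directory, created if needed.
#' @return Invisibly, the paths written.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "measurements.csv")
  write.csv(cohort$measurements, paths[1], row.names = FALSE)
  if (!is.null(cohort$covariates)) {
    p <- file.path(dir, "covariates.csv")
    write.csv(cohort$covariates, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(cohort$truth)) {
    p <- file.path(dir, "truth.csv")
    write.csv(cohort$truth, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
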