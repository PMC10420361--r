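#' Configuration for the synthetic surveillance-cohort simulator
#'
#' Defines the population the simulator draws from. Each patient follows the
#' offset-exponential natural history `d(t) = exp(a (t + b)) + 2` (diameter
#' in cm, time in years since first measurement), with `a` drawn lognormal
#' (so the generative truth always grows), the diameter at detection drawn
#' uniformly over a detection window, `b` solved so the first noiseless
#' diameter equals the detection diameter, irregular visit schedules, and
#' homoscedastic Gaussian measurement noise. Binary covariates act
#' multiplicatively on `a`; optional numeric covariates act on `log a`.
#'
#' @param n_patients number of patients.
#' @param a_log_mean,a_log_sd mean and sd of `log a` in the population
#'   (per-year growth-shape parameter; the default median `a` of 0.08
#'   corresponds to a benchmark rate of about 1.8 mm/year).
#' @param noise_sd_cm measurement noise standard deviation, cm.
#' @param visit_gap_mean_yr,visit_gap_sd_yr inter-visit interval
#'   distribution (Gaussian, resampled until above `visit_gap_min_yr`),
#'   years.
#' @param visit_gap_min_yr smallest admissible inter-visit gap, years.
#' @param n_visits_min,n_visits_max visits per patient (discrete uniform);
#'   `n_visits_min` must be at least 2.
#' @param detection_min_cm,detection_max_cm range of the (noiseless)
#'   diameter at the first visit, cm; must satisfy
#'   `2 < detection_min_cm <= detection_max_cm`.
#' @param covariate_effects named numeric vector/list: multiplicative effect
#'   on `a` for carriers of each binary covariate (e.g.
#'   `c(diabetes = 0.5)` halves the growth parameter of diabetics).
#' @param covariate_prevalence named numeric vector/list of carrier
#'   probabilities in `[0, 1]`; names must match `covariate_effects`.
#' @param numeric_covariates named list of numeric covariates, each a list
#'   with elements `mean`, `sd` and `log_a_slope` (additive effect of one
#'   unit of the covariate, centred at `mean`, on `log a`).
#' @param age_mean_yr,age_sd_yr age at detection distribution, years.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the configuration including the seed.
#'
#' @return A validated list of class `aaaCohortConfig`.
#' @seealso [defaultCohortConfig()], [simulateCohort()]
#' @export
cohortConfig <- function(n_patients = 100,
                         a_log_mean = log(0.08),
                         a_log_sd = 0.6,
                         noise_sd_cm = 0.15,
                         visit_gap_mean_yr = 1.5,
                         visit_gap_sd_yr = 0.6,
                         visit_gap_min_yr = 0.15,
                         n_visits_min = 2L,
                         n_visits_max = 6L,
                         detection_min_cm = 2.5,
                         detection_max_cm = 5.0,
                         covariate_effects = list(),
                         covariate_prevalence = list(),
                         numeric_covariates = list(),
                         age_mean_yr = 72,
                         age_sd_yr = 8,
                         seed = 1L) {
  cfg <- list(
    n_patients = as.integer(n_patients),
    a_log_mean = a_log_mean, a_log_sd = a_log_sd,
    noise_sd_cm = noise_sd_cm,
    visit_gap_mean_yr = visit_gap_mean_yr,
    visit_gap_sd_yr = visit_gap_sd_yr,
    visit_gap_min_yr = visit_gap_min_yr,
    n_visits_min = as.integer(n_visits_min),
    n_visits_max = as.integer(n_visits_max),
    detection_min_cm = detection_min_cm,
    detection_max_cm = detection_max_cm,
    covariate_effects = as.list(covariate_effects),
    covariate_prevalence = as.list(covariate_prevalence),
    numeric_covariates = numeric_covariates,
    age_mean_yr = age_mean_yr, age_sd_yr = age_sd_yr,
    seed = as.integer(seed))
  validateCohortConfig(cfg)
  structure(cfg, class = "aaaCohortConfig")
}

validateCohortConfig <- function(cfg) {
  stopifnot(cfg$n_patients >= 1)
  if (cfg$noise_sd_cm < 0) stop("noise_sd_cm must be >= 0", call. = FALSE)
  if (cfg$visit_gap_min_yr <= 0 || cfg$visit_gap_mean_yr <= 0) {
    stop("visit gaps must be positive", call. = FALSE)
  }
  if (cfg$n_visits_min < 2) stop("n_visits_min must be >= 2", call. = FALSE)
  if (cfg$n_visits_max < cfg$n_visits_min) {
    stop("n_visits_max must be >= n_visits_min", call. = FALSE)
  }
  if (cfg$detection_min_cm <= 2) {
    stop("detection_min_cm must exceed the 2 cm asymptote: the ",
         "offset-exponential diameter is always > 2 cm", call. = FALSE)
  }
  if (cfg$detection_max_cm < cfg$detection_min_cm) {
    stop("detection_max_cm must be >= detection_min_cm", call. = FALSE)
  }
  eff <- cfg$covariate_effects; prev <- cfg$covariate_prevalence
  if (!setequal(names(eff), names(prev))) {
    stop("covariate_effects and covariate_prevalence must share names",
         call. = FALSE)
  }
  if (length(prev) > 0 &&
      any(unlist(prev) < 0 | unlist(prev) > 1)) {
    stop("covariate prevalences must lie in [0, 1]", call. = FALSE)
  }
  invisible(cfg)
}

#' Default cohort configuration resembling a hospital surveillance program
#'
#' A cohort of 540 patients with 2-6 visits each at irregular multi-year
#' intervals, detection diameters between 2.5 cm (ectatic threshold) and
#' 5.0 cm, 0.15 cm measurement noise, and a growth-parameter population
#' giving a median benchmark rate of roughly 1.8 mm/year. Includes a
#' diabetes flag (prevalence 0.24) that multiplies the growth parameter by
#' 0.7, and a tobacco-history flag (prevalence 0.6) with effect 1.15.
#' Illustrative defaults, not a reference dataset.
#'
#' @param ... overrides passed to [cohortConfig()].
#' @return An `aaaCohortConfig`.
#' @export
defaultCohortConfig <- function(...) {
  args <- list(
    n_patients = 540L,
    a_log_mean = log(0.08), a_log_sd = 0.6,
    noise_sd_cm = 0.15,
    visit_gap_mean_yr = 1.5, visit_gap_sd_yr = 0.6, visit_gap_min_yr = 0.15,
    n_visits_min = 2L, n_visits_max = 6L,
    detection_min_cm = 2.5, detection_max_cm = 5.0,
    covariate_effects = list(diabetes = 0.7, tobacco = 1.15),
    covariate_prevalence = list(diabetes = 0.24, tobacco = 0.6),
    seed = 20260921L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohortConfig, args)
}

#' Offset-exponential diameter curve
#'
#' Evaluates `d(t) = exp(a (t + b)) + 2`, the natural-history model: as
#' `t + b` tends to minus infinity the diameter approaches the normal
#' aortic diameter of 2 cm from above.
#'
#' @param a growth-shape parameter, per year.
#' @param b time translation, years.
#' @param t_yr time(s) in years since first measurement.
#' @return diameter(s) in cm.
#' @export
diameterAt <- function(a, b, t_yr) exp(a * (t_yr + b)) + 2

#' Simulate a surveillance cohort
#'
#' Draws per-patient growth parameters, covariates, visit schedules and
#' noisy diameter measurements according to a [cohortConfig()]. The first
#' visit is at `t = 0`; the time translation `b` is solved so the first
#' noiseless diameter equals the drawn detection diameter,
#' `b = log(d0 - 2) / a`. Output is a deterministic function of the
#' configuration (including its seed).
#'
#' @param config an `aaaCohortConfig`.
#' @return An [aaaCohort()] with generative truth attached
#'   (`truth`: `patient_id`, `a_true`, `b_true`, `detection_diameter_cm`,
#'   plus one column per covariate).
#' @export
simulateCohort <- function(config) {
  validateCohortConfig(config)
  withSeed(config$seed, {
    n <- config$n_patients
    ids <- sprintf("P%04d", seq_len(n))
    loga <- rnorm(n, config$a_log_mean, config$a_log_sd)

    covs <- list()
    for (nm in names(config$covariate_effects)) {
      flag <- rbinom(n, 1, config$covariate_prevalence[[nm]])
      loga <- loga + flag * log(config$covariate_effects[[nm]])
      covs[[nm]] <- flag
    }
    for (nm in names(config$numeric_covariates)) {
      nc <- config$numeric_covariates[[nm]]
      val <- rnorm(n, nc$mean, nc$sd)
      loga <- loga + (nc$log_a_slope %||% 0) * (val - nc$mean)
      covs[[nm]] <- val
    }
    a <- exp(loga)
    d0 <- runif(n, config$detection_min_cm, config$detection_max_cm)
    b <- log(d0 - 2) / a
    age <- round(rnorm(n, config$age_mean_yr, config$age_sd_yr), 1)

    nv <- sample(seq(config$n_visits_min, config$n_visits_max), n,
                 replace = TRUE)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      gaps <- numeric(nv[i] - 1)
      for (k in seq_along(gaps)) {
        g <- rnorm(1, config$visit_gap_mean_yr, config$visit_gap_sd_yr)
        while (g < config$visit_gap_min_yr) {
          g <- rnorm(1, config$visit_gap_mean_yr, config$visit_gap_sd_yr)
        }
        gaps[k] <- g
      }
      t <- cumsum(c(0, gaps))
      d <- diameterAt(a[i], b[i], t)
      if (config$noise_sd_cm > 0) {
        d <- d + rnorm(length(t), 0, config$noise_sd_cm)
      }
      d <- pmax(d, 0.1)  # diameters are physically positive
      modality <- sample(c("CT", "US", "other"), length(t), replace = TRUE,
                         prob = c(0.58, 0.41, 0.01))
      rows[[i]] <- data.frame(patient_id = ids[i], time_yr = t,
                              diameter_cm = d, modality = modality,
                              stringsAsFactors = FALSE)
    }
    measurements <- do.call(rbind, rows)

    covariates <- data.frame(patient_id = ids, stringsAsFactors = FALSE)
    for (nm in names(covs)) covariates[[nm]] <- covs[[nm]]
    covariates$age_at_detection_yr <- age

    truth <- data.frame(patient_id = ids, a_true = a, b_true = b,
                        detection_diameter_cm = d0,
                        stringsAsFactors = FALSE)
    for (nm in names(covs)) truth[[nm]] <- covs[[nm]]

    aaaCohort(measurements, covariates = covariates, truth = truth)
  })
}
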