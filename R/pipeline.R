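#' Pipeline run configuration
#'
#' Collects everything one reproducible end-to-end run needs: the input
#' (either a simulator configuration or paths to measurement/covariate
#' CSVs), the model list, sampler settings, experiment toggles and the
#' output directory. Can also be read from a YAML file with
#' [readRunConfig()].
#'
#' @param cohort_config an [cohortConfig()] used to simulate the input
#'   cohort (ignored when `measurements_csv` is given).
#' @param measurements_csv,covariates_csv paths to input CSVs (optional
#'   alternative to simulation).
#' @param models models to fit, see [fitCohortRates()].
#' @param control sampler settings, see [samplerControl()].
#' @param experiments character subset of
#'   `c("baseline", "stability", "forecast", "riskfactors")`.
#' @param out_dir output directory for the report bundle.
#' @param make_figures write summary PNG figures (histograms of censoring
#'   deltas, rate by starting size).
#' @param seed master seed recorded in the manifest; it reseeds the
#'   simulator and sampler unless those were configured explicitly.
#' @return list of class `aaaRunConfig`.
#' @export
runConfig <- function(cohort_config = defaultCohortConfig(),
                      measurements_csv = NULL, covariates_csv = NULL,
                      models = allModels,
                      control = samplerControl(),
                      experiments = c("baseline", "stability", "forecast",
                                      "riskfactors"),
                      out_dir = "aagrowth-run",
                      make_figures = TRUE,
                      seed = NULL) {
  experiments <- match.arg(experiments, several.ok = TRUE,
                           choices = c("baseline", "stability", "forecast",
                                       "riskfactors"))
  if (!is.null(seed)) {
    cohort_config$seed <- as.integer(seed)
    control$seed <- as.integer(seed)
  }
  if (!is.null(measurements_csv) && !file.exists(measurements_csv)) {
    stop("measurements_csv does not exist: ", measurements_csv,
         call. = FALSE)
  }
  structure(list(cohort_config = cohort_config,
                 measurements_csv = measurements_csv,
                 covariates_csv = covariates_csv,
                 models = models, control = control,
                 experiments = experiments, out_dir = out_dir,
                 make_figures = make_figures),
            class = "aaaRunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map to [cohortConfig()], [samplerControl()] and
#' [runConfig()] arguments under the keys `cohort`, `sampler`, and the
#' top level respectively.
#'
#' @param path YAML file.
#' @return An `aaaRunConfig`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cc <- do.call(cohortConfig, y$cohort %||% list())
  sc <- do.call(samplerControl, y$sampler %||% list())
  args <- y[setdiff(names(y), c("cohort", "sampler"))]
  do.call(runConfig, c(list(cohort_config = cc, control = sc), args))
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the cohort, applies the preprocessing rules
#' (merging of measurements less than 150 days apart, minimum-measurement
#' filters), fits the requested growth models, runs the selected
#' experiments, and writes a report bundle to the output directory:
#' `manifest.json` (seeds, settings, patient counts at every filter
#' stage), tidy CSVs per stage, optional PNG figures, and a
#' human-readable `summary.md`. Deterministic given the configuration.
#'
#' @param config an [runConfig()].
#' @return Invisibly, a list with the in-memory results
#'   (`cohort`, `rates`, `baseline`, `stability`, `forecast`,
#'   `riskfactors`, `manifest`).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "aaaRunConfig"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    message(sprintf("[%s] starting", name))
    r <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    r
  }

  cohort <- stage("ingest", {
    if (!is.null(config$measurements_csv)) {
      readCohort(config$measurements_csv, config$covariates_csv)
    } else {
      simulateCohort(config$cohort_config)
    }
  })
  writeCohort(cohort, file.path(out, "cohort"))

  merged <- stage("preprocess", mergeCloseMeasurements(cohort))
  two_plus <- suppressMessages(filterMinMeasurements(merged, 2))
  three_plus <- suppressMessages(filterMinMeasurements(merged, 3))

  rates <- stage("fit", fitCohortRates(two_plus, models = config$models,
                                       control = config$control))
  write.csv(rates, file.path(out, "rates.csv"), row.names = FALSE)

  results <- list(cohort = cohort, rates = rates)
  manifest <- list(
    package_version = as.character(utils::packageVersion("aagrowth")),
    seed_cohort = config$cohort_config$seed,
    seed_sampler = config$control$seed,
    models = config$models,
    sampler = unclass(config$control),
    counts = list(
      patients_raw = nPatients(cohort),
      patients_min2_merged = nPatients(two_plus),
      patients_min3_merged = nPatients(three_plus)))

  if ("baseline" %in% config$experiments) {
    results$baseline <- stage("baseline",
                              characterizeBaseline(two_plus, rates))
    write.csv(results$baseline$summary,
              file.path(out, "baseline_summary.csv"), row.names = FALSE)
    write.csv(results$baseline$by_size,
              file.path(out, "baseline_by_size.csv"), row.names = FALSE)
  }
  if ("stability" %in% config$experiments) {
    results$stability <- stage("stability", suppressMessages(
      runStability(three_plus, models = config$models,
                   control = config$control)))
    write.csv(results$stability$summary,
              file.path(out, "stability_summary.csv"), row.names = FALSE)
    write.csv(results$stability$deltas,
              file.path(out, "stability_deltas.csv"), row.names = FALSE)
  }
  if ("forecast" %in% config$experiments) {
    splits <- suppressMessages(makeForecastSplits(cohort))
    manifest$counts$patients_forecast <- length(splits$splits)
    results$forecast <- stage("forecast", suppressMessages(
      runForecast(cohort, models = config$models,
                  control = config$control, splits = splits)))
    write.csv(results$forecast$metrics,
              file.path(out, "forecast_metrics.csv"), row.names = FALSE)
    write.csv(results$forecast$errors,
              file.path(out, "forecast_errors.csv"), row.names = FALSE)
  }
  if ("riskfactors" %in% config$experiments &&
      !is.null(two_plus$covariates)) {
    results$riskfactors <- stage("riskfactors",
                                 runRiskFactors(two_plus, rates))
    if (!is.null(results$riskfactors$associations)) {
      write.csv(results$riskfactors$associations,
                file.path(out, "riskfactor_associations.csv"),
                row.names = FALSE)
    }
    if (!is.null(results$riskfactors$detection)) {
      write.csv(results$riskfactors$detection,
                file.path(out, "riskfactor_detection.csv"),
                row.names = FALSE)
    }
  }

  if (config$make_figures) {
    stage("figures", writePipelineFigures(results, out))
  }
  results$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(renderSummaryMd(results), file.path(out, "summary.md"))
  invisible(results)
}

writePipelineFigures <- function(results, out) {
  if (!is.null(results$stability)) {
    grDevices::png(file.path(out, "stability_deltas.png"),
                   width = 1200, height = 300 *
                     length(unique(results$stability$deltas$model)))
    d <- results$stability$deltas
    models <- unique(d$model)
    graphics::par(mfrow = c(length(models), 1), mar = c(4, 4, 2, 1))
    for (m in models) {
      dm <- d[d$model == m, ]
      rng <- range(c(dm$delta_left, dm$delta_right), finite = TRUE)
      if (diff(rng) == 0) rng <- rng + c(-1, 1)
      br <- seq(rng[1], rng[2], length.out = 40)
      hl <- graphics::hist(dm$delta_left, breaks = br, plot = FALSE)
      hr <- graphics::hist(dm$delta_right, breaks = br, plot = FALSE)
      ylim <- c(0, max(hl$counts, hr$counts))
      graphics::plot(hl, col = grDevices::rgb(1, 0.5, 0, 0.5),
                     ylim = ylim, main = m,
                     xlab = "rate change after censoring (mm/yr)")
      graphics::plot(hr, col = grDevices::rgb(0, 0.4, 1, 0.5), add = TRUE)
      graphics::legend("topright", c("left-censored", "right-censored"),
                       fill = c(grDevices::rgb(1, 0.5, 0, 0.5),
                                grDevices::rgb(0, 0.4, 1, 0.5)))
    }
    grDevices::dev.off()
  }
  if (!is.null(results$baseline)) {
    bs <- results$baseline$by_size
    grDevices::png(file.path(out, "rate_by_size.png"),
                   width = 1000, height = 600)
    models <- unique(bs$model)
    groups <- unique(bs$size_group)
    mat <- sapply(models, function(m) {
      sapply(groups, function(g) {
        v <- bs$mean_rate[bs$model == m & bs$size_group == g]
        if (length(v) == 0) NA else v
      })
    })
    graphics::barplot(t(mat), beside = TRUE, names.arg = groups,
                      legend.text = models,
                      xlab = "diameter at detection (cm)",
                      ylab = "mean clipped growth rate (mm/yr)")
    grDevices::dev.off()
  }
  invisible(NULL)
}

renderSummaryMd <- function(results) {
  lines <- c("# AAA growth-rate pipeline summary", "")
  m <- results$manifest
  lines <- c(lines,
             sprintf("- patients (raw): %d", m$counts$patients_raw),
             sprintf("- patients with >= 2 merged measurements: %d",
                     m$counts$patients_min2_merged),
             sprintf("- patients with >= 3 merged measurements: %d",
                     m$counts$patients_min3_merged))
  if (!is.null(m$counts$patients_forecast)) {
    lines <- c(lines, sprintf("- forecast-eligible patients: %d",
                              m$counts$patients_forecast))
  }
  fmt <- function(df) c("", paste(utils::capture.output(
    print(df, digits = 3, row.names = FALSE)), collapse = "\n"), "")
  if (!is.null(results$baseline)) {
    lines <- c(lines, "", "## Median growth rates and size correlation",
               "```", fmt(results$baseline$summary), "```")
  }
  if (!is.null(results$stability)) {
    lines <- c(lines, "", "## Censoring stability", "```",
               fmt(results$stability$summary), "```")
  }
  if (!is.null(results$forecast)) {
    lines <- c(lines, "", "## Forecasting errors", "```",
               fmt(results$forecast$metrics), "```")
  }
  if (!is.null(results$riskfactors) &&
      !is.null(results$riskfactors$associations)) {
    a <- results$riskfactors$associations
    lines <- c(lines, "", "## Risk factors",
               sprintf("%d tests, no multiple-comparison adjustment",
                       results$riskfactors$n_tests), "```",
               fmt(a[, c("variable", "model", "difference", "rho", "p",
                         "significant")]), "```")
  }
  lines
}
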