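#' MCMC sampler settings for the hierarchical mixed models
#'
#' @param chains number of MCMC chains.
#' @param adapt adaptation iterations.
#' @param warmup burn-in iterations discarded after adaptation.
#' @param draws retained iterations per chain.
#' @param seed integer seed; each chain gets a deterministic RNG stream
#'   derived from it, so identical cohort + settings give identical
#'   summaries.
#' @param central central-tendency summary of the pooled post-warm-up
#'   draws used for per-patient parameters: `"median"` (default; robust to
#'   the skew typical of nonlinear-model posteriors) or `"mean"`.
#' @param rhat_threshold per-patient convergence flag: split-R-hat above
#'   this value on any per-patient parameter marks the patient
#'   non-converged (estimates are still returned).
#' @return list of class `aaaSamplerControl`.
#' @export
samplerControl <- function(chains = 4, adapt = 500, warmup = 1000,
                           draws = 1000, seed = 1L,
                           central = c("median", "mean"),
                           rhat_threshold = 1.1) {
  central <- match.arg(central)
  structure(list(chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 seed = as.integer(seed), central = central,
                 rhat_threshold = rhat_threshold),
            class = "aaaSamplerControl")
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed after splitting each chain in
#' half, so within-chain trends are detected as well as between-chain
#' disagreement. Values near 1 indicate convergence.
#'
#' @param x matrix of posterior draws, iterations x chains.
#' @return the split-R-hat value (NA for constant draws).
#' @export
splitRhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  pieces <- do.call(cbind, lapply(seq_len(ncol(x)), function(j) {
    cbind(x[seq_len(half), j], x[(n - half + 1):n, j])
  }))
  m <- ncol(pieces); nn <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, var)
  W <- mean(vars)
  B <- nn * var(means)
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

jagsLinearModel <- "
model {
  for (j in 1:N) {
    y[j] ~ dnorm(alpha[pid[j]] + beta[pid[j]] * t[j], tau_e)
  }
  for (i in 1:P) {
    alpha[i] ~ dnorm(mu_alpha, tau_alpha)
    beta[i] ~ dnorm(mu_beta, tau_beta)
  }
  mu_alpha ~ dnorm(0, 0.01)
  mu_beta ~ dnorm(0, 0.01)
  sd_alpha ~ dnorm(0, 1) T(0,)
  tau_alpha <- pow(sd_alpha, -2)
  sd_beta ~ dnorm(0, 1) T(0,)
  tau_beta <- pow(sd_beta, -2)
  sd_e ~ dnorm(0, 1) T(0,)
  tau_e <- pow(sd_e, -2)
}"

# Offset-exponential hierarchical model. The per-patient random effects are
# log a_i (positivity of a is structural) and the log baseline excess
# c_i = a_i * b_i = log(d_i(0) - 2), which lives on a unit scale where a
# half-Normal(0,1) spread prior is sensible; b_i = c_i / a_i is derived.
jagsExpModel <- "
model {
  for (j in 1:N) {
    mu[j] <- exp(a[pid[j]] * t[j] + c[pid[j]]) + 2
    y[j] ~ dnorm(mu[j], tau_e)
  }
  for (i in 1:P) {
    loga[i] ~ dnorm(mu_loga, tau_loga)
    a[i] <- exp(loga[i])
    c[i] ~ dnorm(mu_c, tau_c)
    b[i] <- c[i] / a[i]
  }
  mu_loga ~ dnorm(-2, 0.4444444)
  mu_c ~ dnorm(0, 0.01)
  sd_loga ~ dnorm(0, 1) T(0,)
  tau_loga <- pow(sd_loga, -2)
  sd_c ~ dnorm(0, 1) T(0,)
  tau_c <- pow(sd_c, -2)
  sd_e ~ dnorm(0, 1) T(0,)
  tau_e <- pow(sd_e, -2)
}"

runJags <- function(model_string, data, inits_pars, monitor, control) {
  inits <- lapply(seq_len(control$chains), function(k) {
    c(inits_pars,
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = control$seed * 1000L + k))
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = control$chains,
                          n.adapt = control$adapt, quiet = TRUE)
  stats::update(jm, control$warmup, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = control$draws,
                      progress.bar = "none")
}

summariseDraws <- function(samples, par, ids, central) {
  cols <- sprintf("%s[%d]", par, seq_along(ids))
  perChain <- lapply(samples, function(ch) as.matrix(ch)[, cols, drop = FALSE])
  pooled <- do.call(rbind, perChain)
  cfun <- if (central == "median") stats::median else mean
  data.frame(
    patient_id = ids,
    estimate = apply(pooled, 2, cfun),
    sd = apply(pooled, 2, sd),
    q2.5 = apply(pooled, 2, quantile, 0.025),
    q97.5 = apply(pooled, 2, quantile, 0.975),
    rhat = vapply(cols, function(cc) {
      splitRhat(sapply(perChain, function(m) m[, cc]))
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

summariseHyper <- function(samples, pars, central) {
  pooled <- do.call(rbind, lapply(samples, function(ch)
    as.matrix(ch)[, pars, drop = FALSE]))
  perChain <- lapply(samples, function(ch)
    as.matrix(ch)[, pars, drop = FALSE])
  cfun <- if (central == "median") stats::median else mean
  data.frame(
    parameter = pars,
    estimate = apply(pooled, 2, cfun),
    sd = apply(pooled, 2, sd),
    rhat = vapply(pars, function(p) {
      splitRhat(sapply(perChain, function(m) m[, p]))
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)
}

mixedData <- function(cohort) {
  meas <- cohort$measurements
  ids <- unique(meas$patient_id)
  counts <- table(meas$patient_id)
  if (any(counts < 2)) {
    stop("every patient needs >= 2 measurements for the mixed models ",
         "(filter the cohort first)", call. = FALSE)
  }
  list(ids = ids,
       data = list(y = meas$diameter_cm, t = meas$time_yr,
                   pid = match(meas$patient_id, ids),
                   N = nrow(meas), P = length(ids)))
}

newMixedFit <- function(model, estimates, patient_summary, hyper, fits,
                        control) {
  structure(list(model = model, estimates = estimates,
                 patient_summary = patient_summary, hyper = hyper,
                 fits = fits, control = control),
            class = "aaaMixedFit")
}

#' @export
print.aaaMixedFit <- function(x, ...) {
  cat(sprintf(
    "aaaMixedFit [%s]: %d patients, %d chains x %d draws (seed %d)\n",
    x$model, nrow(x$estimates), x$control$chains, x$control$draws,
    x$control$seed))
  nc <- sum(!x$estimates$converged)
  cat(sprintf("  non-converged patients (split-R-hat > %.2f): %d (%.1f%%)\n",
              x$control$rhat_threshold, nc, 100 * nc / nrow(x$estimates)))
  print(x$hyper, digits = 3)
  invisible(x)
}

#' Hierarchical Bayesian linear mixed-effects growth model
#'
#' Partial-pooling linear model of diameter on time,
#' `d_ij ~ Normal(alpha_i + beta_i t_ij, sigma)`, with per-patient
#' intercepts and slopes drawn from Normal population distributions and
#' weakly informative hyperpriors (`Normal(0, 10)` on the population
#' means, half-Normal(0, 1) on all scales, in cm units). Fitted by Gibbs
#' sampling (JAGS). The per-patient growth rate is 10 times the central
#' tendency of the pooled post-warm-up `beta_i` draws, mm/year. Estimates
#' are returned for every patient regardless of convergence; patients
#' whose split-R-hat exceeds the control threshold are flagged, not
#' dropped.
#'
#' @param cohort an [aaaCohort()] with >= 2 measurements per patient.
#' @param control an [samplerControl()].
#' @return An `aaaMixedFit`: list with `estimates` (the tidy rate table),
#'   `patient_summary` (per-patient posterior summaries with split-R-hat),
#'   `hyper` (population-level summaries), and `fits` (per-patient
#'   `aaaLinearFit`s at the posterior central tendency, for
#'   [predictDiameter()]).
#' @export
fitLinearMixed <- function(cohort, control = samplerControl()) {
  md <- mixedData(cohort)
  d <- md$data
  firsts <- d$y[!duplicated(d$pid)]  # rows are sorted by patient then time
  inits <- list(alpha = as.numeric(firsts),
                beta = rep(0.15, d$P),
                mu_alpha = mean(d$y), mu_beta = 0.15,
                sd_alpha = 0.5, sd_beta = 0.1, sd_e = 0.2)
  s <- runJags(jagsLinearModel, d, inits,
               c("alpha", "beta", "mu_alpha", "mu_beta",
                 "sd_alpha", "sd_beta", "sd_e"), control)
  salpha <- summariseDraws(s, "alpha", md$ids, control$central)
  sbeta <- summariseDraws(s, "beta", md$ids, control$central)
  hyper <- summariseHyper(s, c("mu_alpha", "mu_beta", "sd_alpha",
                               "sd_beta", "sd_e"), control$central)
  converged <- (is.na(salpha$rhat) | salpha$rhat <= control$rhat_threshold) &
    (is.na(sbeta$rhat) | sbeta$rhat <= control$rhat_threshold)
  patient_summary <- data.frame(
    patient_id = md$ids,
    alpha = salpha$estimate, alpha_sd = salpha$sd, alpha_rhat = salpha$rhat,
    beta = sbeta$estimate, beta_sd = sbeta$sd, beta_rhat = sbeta$rhat,
    converged = converged, stringsAsFactors = FALSE)
  fits <- setNames(lapply(seq_along(md$ids), function(i) {
    linearFit(salpha$estimate[i], sbeta$estimate[i])
  }), md$ids)
  estimates <- data.frame(
    patient_id = md$ids, model = "linear_mixed",
    rate_mm_per_yr = 10 * sbeta$estimate,
    fallback = FALSE, converged = converged, stringsAsFactors = FALSE)
  newMixedFit("linear_mixed", estimates, patient_summary, hyper, fits,
              control)
}

#' Hierarchical Bayesian offset-exponential mixed-effects growth model
#'
#' Partial-pooling nonlinear model
#' `d_ij ~ Normal(exp(a_i (t_ij + b_i)) + 2, sigma)` on the raw diameter
#' scale (no log transform of the data, so diameters at or below 2 cm from
#' measurement noise pose no difficulty). Positivity of the growth-shape
#' parameter is structural: `log a_i` has a Normal population
#' distribution, with `Normal(-2, 1.5)` hyperprior on its mean (centred on
#' clinically plausible growth, a of roughly 0.02-0.5 per year). The
#' sampled per-patient baseline parameter is `c_i = a_i b_i =
#' log(d_i(0) - 2)`, the log baseline excess diameter -- a unit-scale
#' quantity with a Normal population distribution and half-Normal(0, 1)
#' spread prior; the time translation `b_i = c_i / a_i` is derived from it.
#' Fitted by MCMC (JAGS). Per-patient `(a_i, b_i)` are the central
#' tendencies of the pooled post-warm-up draws; the growth rate is the
#' [benchmarkRate()] of `a_i`. A small fraction of non-converged patients
#' is expected and tolerated: they are flagged, and their central-tendency
#' estimates are returned all the same.
#'
#' @inheritParams fitLinearMixed
#' @return An `aaaMixedFit` (see [fitLinearMixed()]); `fits` holds
#'   per-patient `aaaExpFit`s at the posterior central tendency.
#' @export
fitExponentialMixed <- function(cohort, control = samplerControl()) {
  md <- mixedData(cohort)
  d <- md$data
  firsts <- d$y[!duplicated(d$pid)]
  inits <- list(loga = rep(log(0.08), d$P),
                c = log(pmax(as.numeric(firsts) - 2, 0.05)),
                mu_loga = log(0.08), mu_c = 0,
                sd_loga = 0.5, sd_c = 0.5, sd_e = 0.2)
  s <- runJags(jagsExpModel, d, inits,
               c("a", "b", "mu_loga", "mu_c", "sd_loga", "sd_c", "sd_e"),
               control)
  sa <- summariseDraws(s, "a", md$ids, control$central)
  sb <- summariseDraws(s, "b", md$ids, control$central)
  hyper <- summariseHyper(s, c("mu_loga", "mu_c", "sd_loga", "sd_c",
                               "sd_e"), control$central)
  converged <- (is.na(sa$rhat) | sa$rhat <= control$rhat_threshold) &
    (is.na(sb$rhat) | sb$rhat <= control$rhat_threshold)
  patient_summary <- data.frame(
    patient_id = md$ids,
    a = sa$estimate, a_sd = sa$sd, a_rhat = sa$rhat,
    b = sb$estimate, b_sd = sb$sd, b_rhat = sb$rhat,
    converged = converged, stringsAsFactors = FALSE)
  fits <- setNames(lapply(seq_along(md$ids), function(i) {
    expFit(sa$estimate[i], sb$estimate[i], converged = converged[i])
  }), md$ids)
  estimates <- data.frame(
    patient_id = md$ids, model = "exp_mixed",
    rate_mm_per_yr = vapply(sa$estimate, benchmarkRate, 0),
    fallback = FALSE, converged = converged, stringsAsFactors = FALSE)
  newMixedFit("exp_mixed", estimates, patient_summary, hyper, fits,
              control)
}
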