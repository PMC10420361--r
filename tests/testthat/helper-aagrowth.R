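# Shared fixtures built in code.

# A single patient's measurement series.
makeSeries <- function(t, d, id = "p1") {
  data.frame(patient_id = id, time_yr = t, diameter_cm = d,
             modality = NA_character_, stringsAsFactors = FALSE)
}

# Cohort assembled from a list of series data.frames.
makeCohortFrom <- function(..., covariates = NULL) {
  aaaCohort(do.call(rbind, list(...)), covariates = covariates)
}

# Small sampler settings for unit tests of the MCMC machinery; acceptance
# checks use the package defaults.
tinyControl <- function(seed = 11) {
  samplerControl(chains = 2, adapt = 200, warmup = 300, draws = 300,
                 seed = seed)
}

# Cohort of exactly linear trajectories (for linear-model ground truth).
makeLinearCohort <- function(n = 40, noise_sd = 0, n_points = 6,
                             slope_range = c(0.05, 0.3),
                             intercept_range = c(2.5, 4), seed = 5) {
  set.seed(seed)
  alpha <- runif(n, intercept_range[1], intercept_range[2])
  beta <- runif(n, slope_range[1], slope_range[2])
  rows <- lapply(seq_len(n), function(i) {
    t <- seq(0, 5, length.out = n_points)
    d <- alpha[i] + beta[i] * t
    if (noise_sd > 0) d <- d + rnorm(n_points, 0, noise_sd)
    makeSeries(t, d, sprintf("L%03d", i))
  })
  cohort <- aaaCohort(do.call(rbind, rows))
  attr(cohort, "alpha_true") <- alpha
  attr(cohort, "beta_true") <- beta
  cohort
}

# Independent re-implementation of the <150-day merging rule used as a
# test oracle: repeatedly finds the first adjacent pair closer than the
# window and averages cluster members tracked explicitly.
oracleMerge <- function(t, d, window_days = 150) {
  w <- window_days / 365.25
  clusters <- as.list(seq_along(t))
  repeat {
    ct <- vapply(clusters, function(ix) mean(t[ix]), 0)
    done <- TRUE
    for (i in seq_len(length(clusters) - 1)) {
      # adjacency is between the last member of one cluster and the first
      # member of the next, matching the greedy chained rule
      lastOf <- max(clusters[[i]])
      firstOf <- min(clusters[[i + 1]])
      if (t[firstOf] - t[lastOf] < w) {
        clusters[[i]] <- c(clusters[[i]], clusters[[i + 1]])
        clusters[[i + 1]] <- NULL
        done <- FALSE
        break
      }
    }
    if (done) break
  }
  list(
    time = vapply(clusters, function(ix) mean(t[ix]), 0),
    diameter = vapply(clusters, function(ix) mean(d[ix]), 0),
    sizes = vapply(clusters, length, 0L))
}

# Exact two-sided Mann-Whitney p-value by enumeration of all group
# assignments (tie-free inputs only).
enumMannWhitneyP <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pool <- c(x, y)
  r <- rank(pool)
  idx <- utils::combn(n1 + n2, n1)
  Us <- apply(idx, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  Uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  pLow <- mean(Us <= Uobs)
  pUp <- mean(Us >= Uobs)
  min(1, 2 * min(pLow, pUp))
}

# All permutations of a vector (for the Spearman enumeration oracle).
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in allPerms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
  }
  out
}

# Exact two-sided Spearman p-value by enumeration of all rank
# permutations (tie-free inputs only).
enumSpearmanP <- function(x, y) {
  rx <- rank(x)
  rhoObs <- stats::cor(rx, rank(y))
  rhos <- vapply(allPerms(rank(y)), function(ry) stats::cor(rx, ry), 0)
  pLow <- mean(rhos <= rhoObs + 1e-12)
  pUp <- mean(rhos >= rhoObs - 1e-12)
  min(1, 2 * min(pLow, pUp))
}
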