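# aagrowth

Growth-rate estimation for abdominal aortic aneurysm (AAA) surveillance.

AAAs are monitored by periodic imaging of the maximal aortic diameter, and
both clinical decisions (surveillance intervals, timing of repair) and
research findings (risk factors for fast growth) hinge on how that growth
is summarised. Surveillance data are sparse (a handful of irregular visits
per patient), noisy, and windowed arbitrarily — an aneurysm may be
detected late in its course or not yet followed to a large size — and
different growth summaries behave very differently under those conditions.
This package implements five estimators side by side, for
biostatisticians and clinical researchers who need to choose one (or audit
a published choice):

* **first–last**: (last − first diameter) / (last − first time), interior
  measurements ignored;
* **unpooled linear regression**: per-patient OLS of diameter on time;
* **unpooled offset-exponential**: per-patient nonlinear least squares of
  *d(t) = e^{a(t+b)} + 2* (the +2 makes the curve approach the normal
  aortic diameter of 2 cm in the distant past), with a flagged linear
  fallback when no growing curve is feasible;
* **linear mixed model**: hierarchical Bayesian partial pooling of
  per-patient intercepts and slopes, fitted by MCMC;
* **offset-exponential mixed model**: the same offset-exponential with
  per-patient *(a, b)* drawn from population distributions (log-normal in
  *a*, so positivity is structural), fitted by MCMC.

Exponential fits are standardised to a comparable linear rate via the
**benchmark rate** — the chord between the model-implied 4.0 cm and
4.5 cm crossing times, which reduces to *5a / ln 1.25* mm/yr. Negative
rates are clipped to zero for downstream analyses (raw values kept for
audit). Rates are reported in mm/year; diameters are stored in cm.

Around the estimators the package provides the full comparison
machinery: a synthetic surveillance-cohort simulator (there is no public
dataset at this scale), the standard preprocessing rules (merging of
measurements under 150 days apart, minimum-measurement filters),
endpoint-censoring stability analysis, future-diameter forecasting with
a two-year gap, nonparametric risk-factor screening (Mann–Whitney U /
Spearman), and a one-call pipeline that writes a reproducible report
bundle. See the vignette in `vignettes/aaa-growth-methods.Rmd` for the
models, priors and design decisions in detail.

## Worked example

```r
library(aagrowth)

cohort <- simulateCohort(defaultCohortConfig(n_patients = 150, seed = 42))
cohort
#> aaaCohort: 150 patients, 595 measurements (4.0 per patient)
#> covariates: diabetes, tobacco, age_at_detection_yr
#> simulated cohort (generative truth attached)

merged <- mergeCloseMeasurements(cohort)
two    <- filterMinMeasurements(merged, 2)
#> 150 patients had at least 2 measurements

rates <- fitCohortRates(two,
                        models  = c("first_last", "exp_unpooled", "exp_mixed"),
                        control = samplerControl(seed = 42))
characterizeBaseline(two, rates)
#> Baseline characterisation (clipped rates, mm/year):
#>         model   n median_rate_mm_per_yr spearman_rho spearman_p
#>    first_last 150                  1.91       0.4391   1.90e-08
#>  exp_unpooled 150                  1.86       0.0907   2.70e-01
#>     exp_mixed 150                  1.70       0.1645   4.44e-02
```

All three models agree the median aneurysm grows 1.7–1.9 mm/yr, but the
first–last chord correlates strongly with the diameter at detection
(rho 0.44): on a convex natural history, chords over late observation
windows are steeper, so a chord-type summary assigns faster growth to
aneurysms found large. The exponential fits estimate the shape parameter
directly and show little or no such correlation — in this simulated
cohort the growth parameter is drawn independently of detection size, so
the small exponential-model correlations are the unbiased answer.

```r
rf <- runRiskFactors(two, rates)
subset(rf$associations, variable == "diabetes",
       select = c(model, mean_present, mean_absent, difference, p))
#>          model mean_present mean_absent difference         p
#> 1   first_last     2.283925    2.633263 -0.3493375 0.4271598
#> 2 exp_unpooled     2.071758    2.192510 -0.1207515 0.7199976
#> 3    exp_mixed     1.809411    2.109427 -0.3000162 0.2586153
```

The simulated diabetes effect (growth parameter multiplied by 0.7,
prevalence 0.24) shows the expected negative rate difference in every
model; at 150 patients none reaches p < 0.05 — the power analysis in the
test-suite shows the exponential mixed model reliably detects a halving
effect at 400 patients.

The full pipeline — preprocessing, all five models, stability,
forecasting, risk factors, figures, manifest and markdown summary — is
one call:

```r
runPipeline(runConfig(out_dir = "aagrowth-run", seed = 1))
```

or from a shell, `Rscript inst/scripts/aagrowth.R run-all --seed 1 --out
aagrowth-run` (subcommands `simulate`, `preprocess`, `fit`, `baseline`,
`stability`, `forecast`, `riskfactors`, `run-all`).

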