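---
title: "Modelling abdominal aortic aneurysm growth: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling abdominal aortic aneurysm growth: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Abdominal aortic aneurysms (AAAs) are monitored by periodic imaging of the
maximal aortic diameter, and the decision to repair hinges on that diameter
and on how fast it is expected to grow. Surveillance datasets are awkward
material for growth estimation: patients contribute only a handful of
irregularly spaced measurements, the measurements are noisy (ultrasound in
particular), and the observation window is arbitrary — an aneurysm may be
detected late in its course (missing early history, "left-censored" in the
loose sense used here) or not yet followed to a large size
("right-censored"). Published studies summarise growth with very different
estimators, and those estimators do not behave alike under these
conditions. This package implements five of them side by side, together
with the preprocessing and evaluation machinery needed to compare their
noise tolerance, temporal bias, forecasting accuracy and power to detect
clinical risk factors.

## The growth models

Diameters are stored in cm, times in years since each patient's first
measurement, and rates are reported in mm/year (a factor of 10 on the
cm/year slope).

1. **First–last** (`fitFirstLast`): total growth divided by total time
   observed, the chord between a patient's first and last measurements;
   interior points are disregarded.
2. **Unpooled linear regression** (`fitLinearUnpooled`): ordinary least
   squares of diameter on time, one patient at a time. Identical to
   first–last when a patient has exactly two points.
3. **Unpooled offset-exponential** (`fitExponentialUnpooled`): nonlinear
   least squares of
   $$d(t) = e^{a\,(t + b)} + 2,$$
   where $a > 0$ controls the shape and $b$ translates the curve in time
   so that one functional form accommodates aneurysms detected at any
   diameter. The offset encodes the assumption that in the distant past
   the vessel approaches the normal aortic diameter of 2 cm.
4. **Linear mixed model** (`fitLinearMixed`): hierarchical Bayesian
   partial pooling, $d_{ij} \sim \mathrm{N}(\alpha_i + \beta_i t_{ij},
   \sigma)$ with $\alpha_i \sim \mathrm{N}(\mu_\alpha, \tau_\alpha)$ and
   $\beta_i \sim \mathrm{N}(\mu_\beta, \tau_\beta)$.
5. **Offset-exponential mixed model** (`fitExponentialMixed`): the same
   offset-exponential mean function with per-patient parameters drawn
   from population distributions (details below). This is the package's
   centrepiece.

### Benchmark-rate standardisation

Exponential fits do not have a single slope, so they are standardised to a
comparable linear rate: the chord between the model-implied times at which
the curve crosses 4.0 cm and 4.5 cm, two diameters in the middle of a
typical surveillance curve. With $t(d) = \log(d - 2)/a - b$ this is

$$\mathrm{rate} = \frac{10 \times 0.5}{t(4.5) - t(4.0)}
               = \frac{5\,a}{\log 1.25}\ \mathrm{mm/yr},$$

independent of $b$. `benchmarkRate()` computes the crossing-time form and
asserts agreement with the closed form. Two conventions are worth
flagging: $a = 0$ maps to rate 0 (a flat curve never crosses the
benchmarks; this is consistent with downstream clipping rather than an
error), and for the downstream analyses every negative rate — whichever
model produced it — is replaced by zero (`clipNegativeRates`), with the
raw value preserved for audit.

## Preprocessing rules

* **Merging** (`mergeCloseMeasurements`): measurements of the same
  patient less than 150 days apart are averaged, to stop near-coincident
  scans from generating extreme slopes. Clustering is greedy
  left-to-right and *chained*: a point joins the current cluster if it
  lies within the window of the cluster's previous **member** (so three
  points each 100 days apart form one cluster although the endpoints are
  200 days apart). The merged point sits at the arithmetic mean time with
  the arithmetic mean diameter — symmetric and order-free within a
  cluster. The operation is idempotent and preserves total measurement
  mass; both properties are tested.
* **Endpoint censoring** (`makeCensoredDatasets`): left- and
  right-censored copies drop each patient's earliest / latest point;
  patients need at least three points so the censored series keep two.
  Times are *not* re-zeroed after censoring: every estimator here is
  translation invariant ($b$ absorbs translation in the exponential
  models), so the choice is immaterial for rates, and keeping the origin
  makes per-patient deltas directly comparable.
* **Forecast splits** (`makeForecastSplits`): the last measurement is the
  prediction target; the target and anything less than 2 years before it
  are censored from training, *then* the survivors are merged
  (censor-first order matters and is tested), and patients with fewer
  than two training points are dropped.

## The hierarchical exponential model in detail

The likelihood is on the raw diameter scale,
$d_{ij} \sim \mathrm{N}(e^{a_i (t_{ij} + b_i)} + 2, \sigma)$ — no log
transform, so noisy measurements at or below 2 cm are unproblematic.
Positivity of $a_i$ is structural: $\log a_i \sim \mathrm{N}(\mu_{\log a},
\tau_a)$, so a negative growth rate can only arise from the unpooled or
linear paths, where it is clipped downstream. The hyperprior
$\mu_{\log a} \sim \mathrm{N}(-2, 1.5)$ is weakly informative on the
clinically plausible range $a \approx 0.02$–$0.5$/yr.

**Parameterisation of the baseline.** The time translation $b_i =
\log(d_i(0) - 2)/a_i$ spans tens of years in either direction in a
realistic cohort (a slow-growing aneurysm detected at 5 cm has
$b \approx \log(3)/0.02 \approx 55$ years), so a Normal random effect
with a unit-scale spread prior placed directly on $b$ would be mis-scaled
by an order of magnitude and would distort the fit. The sampled
per-patient quantity is instead the **log baseline excess diameter**

$$c_i = a_i b_i = \log(d_i(0) - 2),$$

which lives on a unit scale where $c_i \sim \mathrm{N}(\mu_c, \tau_c)$
with a half-Normal(0, 1) spread prior is sensible; $b_i = c_i / a_i$ is a
derived node. The likelihood is unchanged and $(a_i, b_i)$ keep their
interpretation. All remaining scales ($\sigma$ and the random-effect
spreads, in cm units) get half-Normal(0, 1) priors; population means get
$\mathrm{N}(0, 10)$.

**Sampling and summaries.** Both mixed models are written in the BUGS
language and fitted with JAGS (4 chains, 500 adaptation, 1000 warm-up,
1000 retained draws by default; every chain's RNG is seeded
deterministically from the control seed, so identical cohort + settings
give identical summaries). Per-patient parameters are the **posterior
median** of the pooled post-warm-up draws — robust to the skew typical of
nonlinear-model posteriors; the mean is available via
`samplerControl(central = "mean")`. Convergence is summarised per patient
by split-$\widehat{R}$ (each chain split in half, so within-chain drift
counts against convergence); patients with split-$\widehat{R} > 1.1$ on
any of their parameters are flagged but **not** dropped — estimates are
reported regardless of convergence, and a small fraction of flagged
patients is expected and tolerated for the nonlinear model. Random
effects are independent across parameters by design; correlating them is
a possible extension, not currently exposed.

**Failure handling in the unpooled exponential fit.** Starting values
come from regressing $\log(d - 2)$ on $t$ over points with $d > 2.05$ cm.
If fewer than two such points exist, the starting slope is non-positive,
or the optimiser fails or returns non-finite parameters, the estimator
substitutes the unpooled linear fit and flags the fallback — this is the
expected failure mode when a patient's diameters shrink or are flat, where
no growing curve is feasible. With exactly two usable points the
two-parameter curve is solved exactly instead of optimised.

## The synthetic cohort generator

There is no public surveillance dataset at this scale, so every analysis
in the package is exercised against `simulateCohort()`, whose defaults
encode the study conditions the package targets:

* 540 patients; 2–6 visits each; inter-visit gaps Normal(1.5, 0.6) years
  (resampled above 0.15 yr) — surveillance guidelines space imaging
  between 6 months and 3 years depending on size, and multi-year
  follow-up is typical;
* detection diameter uniform on 2.5–5.0 cm (2.5 cm is the ectatic
  threshold; 5 cm is near the repair threshold);
* $\log a \sim \mathrm{N}(\log 0.08, 0.6)$: the median benchmark rate is
  $5 \times 0.08 / \log 1.25 \approx 1.8$ mm/yr, and the central 95% of
  patients span roughly 0.55–6 mm/yr, matching the scale and spread
  reported across surveillance studies;
* homoscedastic Gaussian measurement noise, SD 0.15 cm — between CT and
  ultrasound repeatability; modality is recorded as an inert tag only;
* $b_i$ solved from the detection diameter, $b = \log(d_0 - 2)/a$, with
  the first visit at $t = 0$;
* binary covariates act multiplicatively on $a$ (default: diabetes,
  prevalence 0.24, effect 0.7; tobacco, prevalence 0.6, effect 1.15);
  numeric covariates act additively on $\log a$.

What the generator does **not** emulate: modality-specific measurement
bias, informative dropout (surgery, rupture, death ending follow-up),
visit schedules that react to observed size, and secular drift in
measurement practice. Tests passing on this generator therefore
demonstrate the estimators' mathematical behaviour under irregular sparse
noisy sampling of offset-exponential growth — not robustness to every
pathology of real clinical data. In particular the generative truth *is*
the offset-exponential family, so the exponential models enjoy a
correct-specification advantage that real data would not grant them.

## The evaluation suite

* **Censoring stability** (`runStability`): each model is fitted to the
  full, left-censored and right-censored cohorts and per-patient deltas
  (censored minus full rate, unclipped) are summarised. The asymmetry
  statistic is $\overline{\Delta}_{\mathrm{left}} -
  \overline{\Delta}_{\mathrm{right}}$: a direction-blind model changes
  the same way whichever endpoint is removed, so the statistic sits near
  0, while a temporally biased model inflates after losing early data and
  deflates after losing late data, pushing it positive. (The difference,
  not the sum, is used deliberately: chord-type models on a convex
  natural history have $\overline{\Delta}_{\mathrm{left}} > 0 >
  \overline{\Delta}_{\mathrm{right}}$ of similar magnitude, so their sum
  cancels to noise and would hide exactly the bias the experiment is
  designed to expose.) A two-sided Mann–Whitney test comparing the
  $\Delta_{\mathrm{left}}$ and $\Delta_{\mathrm{right}}$ samples
  accompanies it, and the fraction of patients whose estimate moves by
  more than 1 cm/yr after removing a single point summarises instability.
* **Forecasting** (`runForecast`): models are fitted to the training
  splits only and evaluated at the target time. Five metrics: mean
  squared, median absolute, mean absolute and mean raw (signed)
  projection error, plus the mean over patients of each model's mean
  squared residual to its own training points. Raw error is predicted
  minus actual, so a negative mean means underestimation — the clinically
  risky direction.
* **Risk-factor screening** (`runRiskFactors`): clipped rates per model
  against each covariate — two-sided Mann–Whitney U for binary flags,
  Spearman rank correlation for numeric variables, p < 0.05 flagged and
  p < 0.1 marked borderline, explicitly without multiple-testing
  adjustment (the number of tests performed is recorded in the result so
  a reader can apply their own correction). Each variable is also tested
  against diameter- and age-at-detection, because a variable that shifts
  *when* an aneurysm is detected can masquerade as a growth-rate effect
  under chord-type estimators.
* **Baseline characterisation** (`characterizeBaseline`): median rate per
  model and the Spearman correlation between rate and detection diameter
  (plus a binned table by starting-size group). Clipped rates are used by
  default (`use_clipped = FALSE` switches to raw).

## Numerical choices and degenerate inputs

* Dates convert to years at 365.25 days/year.
* Growth estimation refuses series with under two points or zero time
  span (an error, not a fallback).
* All-tied rank tests degenerate gracefully: Mann–Whitney on identical
  groups reports p = 1 with a tie warning; empty covariate groups are
  skipped with a warning.
* Simulated diameters are floored at 0.1 cm (measurement noise cannot
  produce a non-positive physical diameter; at the default noise level
  the floor is never reached in practice).
* `benchmarkRate` internally cross-checks the crossing-time computation
  against the closed form at 10^-8 relative tolerance on every call.

## Problem sizes used by the tests

The packaged test-suite exercises the MCMC machinery at reduced sizes
chosen to make its properties visible quickly: unit tests run 2 chains of
a few hundred draws on cohorts of 20–120 patients; the cohort-scale
property checks use the 540-patient default cohort with the default
sampler, a 300-patient recovery cohort, and twenty 400-patient replicates
(2 chains, 500 + 500 draws) for the risk-factor power check. On one CPU
the full suite completes in well under half an hour.

## Known limitations

* Recovering the per-patient growth-shape parameter $a$ from sparse noisy
  series is information-limited: with 3–5 visits and 0.15 cm noise the
  posterior-median estimates carry a median absolute relative error on
  the order of 15–20%, and no estimator can do materially better under
  those conditions — the partial-pooling posterior is already close to
  the information-theoretic optimum, which is why the package reports
  convergence flags and posterior spreads rather than pretending to
  per-patient precision.
* The covariate model is screening-grade: effects are tested one at a
  time post hoc, never jointly inside the growth model.
* Frequentist nonlinear mixed-effects fitting and quadratic growth
  shapes are out of scope; the linear and offset-exponential families
  are the comparison of interest.
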