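---
title: "Pooling heterogeneous dietary surveys into national SSB intake estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooling heterogeneous dietary surveys into national SSB intake estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The estimation problem

National mean sugar-sweetened beverage (SSB) intake is not observed
directly anywhere. What exists is a scattered collection of dietary
surveys: some nationally representative, some urban-only; some
individual-level 24-hour recalls or food-frequency questionnaires (FFQ),
some household budget surveys (HBS) that only report household totals;
some jointly stratified by age, sex, education and residence, others
reporting only coarse cells. Most country-years have no survey at all.

`ssbpool` turns such a collection into posterior estimates of mean intake
(8 oz servings/week) for every joint demographic stratum of every
country-year — 22 age bands × 2 sexes × 3 education levels × 2
urbanicity levels = 264 strata — together with 95% uncertainty intervals
(UIs), population-weighted aggregates, inequity contrasts and
demographic-standardized time trends. Everything downstream of the model
operates on the full set of posterior draws, so uncertainty propagates
into every reported number.

Because no real survey corpus ships with the package, a synthetic-data
module generates worlds with a *known* true intake surface and simulates
survey collections from them; all tests and the acceptance script run
against that known truth.

## Harmonization

Raw records are standardized before modeling:

* **Units.** Intakes are expressed in 8 oz servings/week; grams convert
  at 248 g per serving (the reporting convention; 236.5 g request-time
  servings are accepted on input through the same converter).
* **Energy adjustment (residual method).** Within each survey and broad
  age class (20–74 vs 75+), individual intake is regressed on reported
  total energy; each person keeps their residual plus the prediction at
  the standard energy (2000 kcal/day for ages 20–74, 1700 for 75+).
  Negative adjusted values are floored at zero, since intake is
  nonnegative by definition. The fit is per survey so that one survey's
  reporting quirks cannot leak into another's adjustment.
* **Household disaggregation (adult male equivalent, AME).** Household
  totals are split over members in proportion to age- and sex-specific
  energy requirements; member shares always sum to the household total.
  The requirement table shipped here is a plausible synthetic convention,
  not a published reference.
* **Summarization.** Assessment days are averaged per participant first;
  participant means are then summarized (mean, SD, n) at whatever
  granularity the survey reports. Coarse cells are *kept coarse* — an
  observation spanning a 10-year band or pooling education enters the
  model against the population-weighted average of the fine strata it
  covers, rather than being split heuristically.
* **Screening.** Stratum means outside [0, 70] servings/week (~10/day),
  negative SDs, or invalid sample sizes are rejected with
  machine-readable reason codes. The bound is a configurable stand-in
  for production plausibility algorithms.

## The hierarchical intake model

Let $y_j$ be observation $j$'s mean with sample size $n_j$, covering a
set $S_j$ of fine strata with population weights $w_{js}$. The model is

$$y_j \sim \mathrm{Normal}\!\Big(\sum_{s \in S_j} w_{js}\,\mu_s,\;
  \sigma_j^2 \, e^{\gamma \cdot \mathrm{infl}_j}\Big), \qquad
  \mu_s = \exp\big(c_{c(s)} + a_{k(s)} + \beta_{\mathrm{sex}} x^{\mathrm{sex}}_s
  + \beta_{\mathrm{em}} x^{\mathrm{em}}_s + \beta_{\mathrm{eh}} x^{\mathrm{eh}}_s
  + \beta_{\mathrm{urb}} x^{\mathrm{urb}}_s + \beta_{\mathrm{cov}} z_{c(s),t(s)}\big)$$

with a nested hierarchy of levels: country $c_c \sim \mathrm{N}(r_{r(c)},
\sigma_c^2)$, region $r_r \sim \mathrm{N}(b_0, \sigma_r^2)$, and a global
intercept $b_0$. The age curve $a_k$ is a first-order random walk over
the 22 ordered bands, anchored at the 20–24 reference band, which borrows
strength between adjacent ages without forcing a parametric shape. The
sex/education/urbanicity design columns are *centered* (e.g. male = ±1/2),
so the country level is interpretable as the country's overall log level
and, importantly, is nearly orthogonal to the demographic effects — a
requirement for well-mixed Gibbs updates. The covariate $z$ is the
z-scored log beverage-availability proxy per country-year. There are no
demographic interactions, which keeps the model stable under sparse data.

Choices worth calling out:

* **Positivity** comes from the log-additive mean, not from truncation.
* **Overdispersion.** $\mathrm{infl}_j = 1$ when an observation is not
  nationally representative, spans more than 10 years of age, or pools
  any of sex/education/urbanicity; $\gamma \ge 0$ (half-Normal prior) is
  learned from the data.
* **Observation variances.** Weighting every cell by its own estimated
  SD biases pooled means downward on skewed intake data, because a
  cell's sample mean and sample SD are positively correlated (for
  lognormal-like intakes a cell that happens to draw low also claims
  high precision). Instead, each survey's cells share the survey's
  pooled per-participant relative variance, referenced to a smoothed
  plug-in cell mean (a per-survey additive log-linear OLS fit):
  $\sigma_j^2 = (\widehat{\mathrm{relsd}}^2/n_j)\,\hat y_j^2$, floored at
  a 1% relative standard error. In our synthetic experiments the naive
  weighting depressed every surveyed country's level by ~2% and pushed
  95% UI coverage to ~0.73; the moderated weighting restores ~0.92.
* **Unsurveyed countries** appear in the model as country-level nodes
  with no likelihood term: their levels are drawn from the region
  distribution, so they inherit the regional mean with honestly wider
  intervals.
* **Priors.** Normal(0, 1) on log-scale fixed effects, Normal(0, 2) on
  the global intercept, half-Normal(0, 1) on all hierarchy SDs. All are
  configurable in `model_config()`.

### Inference backend

Sampling uses JAGS (Gibbs/slice) through `rjags`, with the model written
for that backend: hierarchical centering of the country/region levels,
centered design columns, and a reference-anchored random walk — all of
which remove the translation ridges that make naive additive
parametrizations unusable under single-site updates. Two chains run with
data-derived starting values (a pooled age curve and per-country moment
levels, jittered per chain). The data-derived inits matter: the
overdispersion effect admits a spurious local mode in which the inflated
survey class is ignored wholesale, and chains started from the prior can
land there. A fit must reach split-chain R-hat < 1.05 on every monitored
parameter or it errors (callers can opt into deterministic retries with
doubled chain lengths). Scaled-down runs may use a single chain, in
which case the split diagnostic operates on the chain's halves. Draw counts default to 4000, the reporting
convention; the package's own tests and acceptance runs use 300–500
draws, which our experiments show is ample for medians and 95% UIs at
the reported precision.

## The trend model and combination

A second, deliberately simpler Bayesian model strengthens time trends:
log country-year mean intake regressed on the standardized availability
covariate with country-specific intercepts and slopes drawn from a
pooled bivariate distribution (estimated correlation $\rho$ — the
"varying slopes" structure). No explicit time term exists; time enters
only through covariate variation. The bivariate prior is written as
intercept marginal × slope conditional, again for Gibbs-friendly
updates, and the residual SD carries a 1% floor so exactly-fitting
synthetic series keep a proper likelihood.

To combine the two models, the trend fit's country-year level —
including a draw of its regression residual, since the fit predicts an
actual level, not a regression line — is distributed over strata using
the primary model's draw-wise demographic pattern, matched on the adult
(20+) slice that observed survey series represent. The default
combination is per-stratum inverse-variance weighting of the two draw
sets (an equal-weight rule is available behind a flag); each combined
draw is a convex mix, so it always lies between its inputs. Whether
combination should operate on parameters or on final stratum draws is
isolated behind this one interface.

## Aggregation conventions

* Percentiles (median, 2.5th, 97.5th) use linear interpolation between
  order statistics; for draws 1..4000 the median is 2000.5.
* Population-weighted aggregation is draw-wise; weights renormalize
  within scope.
* Temporal changes difference the two years stratum-by-stratum,
  draw-wise, under a *fixed* (latest-year) population table, so changes
  reflect intake, not demography. Percent change divides by the
  baseline level reconstructed on the same weighted pathway, unrounded.
  The aggregated change draws are exactly additive over chained periods.
* Significance of a change or contrast means its 95% UI excludes zero.
* Report tables round to 1 decimal, half away from zero; internal
  computation is unrounded.
* Adult reporting collapses 85–89/90–94/95+ into one population-weighted
  85+ band, draw-wise, giving 14 adult bands.

## The synthetic world

The generator is first-class, tested code. The true surface is built
additively on the log scale — global intercept, region and country
effects (SDs 0.3), a monotone-beyond-20–24 age curve, sex (+0.1 male),
education (0/+0.15/+0.3), urbanicity (+0.25 urban), and a covariate
slope (0.3) on the z-scored log availability series — then
exponentiated. These magnitudes are the package's synthetic conventions,
chosen as plausible for a beverage intake surface with strong
demographic gradients; none is a claim about any real population.

Surveys are simulated with method-specific error structure: lognormal
mean-preserving between-person variation (CV 0.5 by default),
multiplicative within-person day-to-day noise for 24HR (CV 0.5 over 2
days), an optional multiplicative FFQ bias (default 1, i.e. a validated
instrument), reported energy Normal around the age-specific standard
(15% CV, truncated at 800 kcal/day) with intake coupled proportionally
to energy so the residual adjustment has real work to do, and urban-only
frames for subnational/community designs. Participants are allocated to
the fine strata inside each reported cell proportionally to population —
a survey's cell mean then estimates the same population-weighted
quantity the model predicts for it. Household surveys emit member
rosters and household totals, reported at household stratification
(education × urbanicity, age and sex pooled — which the overdispersion
rule flags, as it should).

The default study scenario covers ~60% of the 15 country-years — one
survey per covered country-year: 45% national 24HR (5-year bands,
education pooled), 30% national FFQ (fully stratified, 10-year bands),
20% urban-only subnational FFQ, 5% HBS, n = 50 per reported cell — and
always leaves at least one country completely unsurveyed so
extrapolation is exercised. These sizes were chosen once as a realistic,
computationally comfortable synthetic corpus.

What passing tests on this world do **not** show about real data: the
generator's truth is exactly log-additive (no interactions), its FFQs
are unbiased, its populations and availability series are smooth
parametric constructions, and its noise distributions are known. Real
surveys violate all of these in unknown ways; recovery on this world is
a necessary, not sufficient, check.

## Validation harness

* **Noiseless closure**: with all noise and bias off, the end-to-end
  pipeline reproduces the true stratum means (RMSE well under 0.1
  servings/week on surveyed strata). Household surveys are excluded from
  this scenario because the AME allocation is an approximation whose
  error is systematic — it does not vanish with noise — and closure is a
  statement about the noise limit of individual-level instruments.
* **Parameter recovery** on the default world: correlation between true
  and estimated country-year adult means ≥ 0.9 and stratum-level 95% UI
  coverage inside [0.88, 0.99] at 500 draws.
* **Uncertainty ordering**: mean adult UI width of unsurveyed countries
  strictly exceeds that of countries with two or more national surveys.
* **Five-fold survey-level cross-validation**: whole surveys are held
  out (never splitting a survey's strata across folds), the model is
  refitted per fold, and held-out cell means are predicted from the
  posterior; implausible predictions (outside the screening bounds) are
  excluded and counted. CV runs on a compact low-noise world (two
  countries, two years, two replicate FFQs per country-year, 1%
  between-person CV, ages 20–39 at 5-year bands): the criterion compares
  held-out error to the noiseless-closure error, which is only a
  meaningful comparison when observation noise is subordinate to closure
  error. Fold fits are scaled down (300 draws) and the mode is recorded
  in the report. CV metrics are computed on the energy-adjusted scale,
  matching what the model consumes.

## Numerical and degenerate-input choices

* Constant energy vectors make the adjustment slope undefined: intakes
  pass through unchanged with a warning.
* Zero-variance observation cells (noiseless simulations, n = 1) are
  caught by the 1% relative standard-error floor.
* All-zero population weights in a collapsed cell fall back to an
  unweighted mean; all-zero weights in an aggregation scope are an
  error.
* Identical contrast slices return the degenerate zero difference;
  partially overlapping slices are rejected.
* Every stochastic step (world generation, survey simulation, fold
  assignment, MCMC, trend projection) derives its stream from one seed;
  a pipeline run is reproducible file-for-file.

## Known limitations

* The overdispersion inflation is a single shared effect across all
  flagged observation classes; class-specific effects would be a natural
  extension.
* The combination rule treats the two models' draws as independent,
  which they are not (both see the same surveys); combined intervals are
  accordingly a little narrow, and the recovery criteria are therefore
  assessed on the primary model's posterior.
* HBS inputs are down-weighted only through the overdispersion rule; the
  AME approximation's systematic allocation error is not otherwise
  modeled.
* Child-age strata (under 20) are carried in the grid and the model, but
  the default scenario's surveys cover ages 20+, so child estimates rest
  on the random-walk prior; reporting targets adults.
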