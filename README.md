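# ssbpool

Hierarchical Bayesian pooling of heterogeneous dietary surveys into
national and subnational estimates of mean sugar-sweetened beverage
(SSB) intake.

## The problem

Dietary surveillance data are sparse and inconsistent: 24-hour recalls,
food-frequency questionnaires and household budget surveys report
different quantities at different demographic granularities, with
different representativeness, and most country-years have no survey at
all. Policy questions, though, need comparable numbers — mean intake in
8 oz (248 g) servings per week — for every joint demographic stratum
(22 age bands × 2 sexes × 3 education levels × 2 urbanicity levels =
264 strata per country-year), with honest uncertainty, trends over time
and subgroup contrasts.

`ssbpool` implements the full estimation chain for this problem:

1. **Harmonize** raw records: serving-unit conversion, residual-method
   energy adjustment to age-specific standards (2000 kcal/day for ages
   20–74, 1700 for 75+), adult-male-equivalent disaggregation of
   household totals, day averaging, stratum summarization, and
   plausibility screening.
2. **Pool** survey-stratum observations with a nested hierarchical
   Bayesian model (random effects by country within region within
   global; a random-walk age curve; additive sex, education, urbanicity
   and covariate effects; extra variance for non-representative or
   coarsely stratified surveys), sampled with JAGS. Coarse observations
   are matched against the population-weighted average of the fine
   strata they cover. Countries without surveys get estimates from the
   hierarchy, with wider intervals.
3. **Strengthen trends** with a varying-slopes model: log country-year
   intake on a standardized beverage-availability covariate, country
   intercepts and slopes drawn from a pooled bivariate distribution with
   estimated correlation; the two models' draws are combined by
   per-stratum inverse-variance weighting.
4. **Aggregate** the posterior draws into population-weighted estimates
   with 95% uncertainty intervals, male–female / education / urban–rural
   contrasts with significance flags, temporal changes standardized to
   the latest year's demographics, threshold country counts, and
   correlations with a sociodemographic development index.
5. **Validate** with a synthetic-world harness: parameter recovery
   against a known true surface, noiseless closure, uncertainty
   ordering, and survey-level five-fold cross-validation.

Because real survey corpora are not redistributable, the package ships a
first-class synthetic-data generator (`generate_world()`,
`simulate_survey_collection()`) whose ground truth every stage is tested
against. The methods vignette (`vignettes/ssb-intake-pooling.Rmd`)
documents the model, its priors, the generator's conventions, and known
limitations.

## Worked example

A compact end-to-end run (one region, three countries, two years, 200
posterior draws):

```r
library(ssbpool)

cfg <- pipeline_config(
  seed = 6,
  world = world_config(n_regions = 1, countries_per_region = 3,
                       years = c(2005, 2018)),
  coverage = 0.8, n_per_stratum = 30,
  model = model_config(n_draws = 200)
)
res <- run_pipeline(cfg, out_dir = "ssb_run")

# adult (20+) population-weighted mean for a surveyed country in 2018
rd  <- collapse_reporting_grid(res$combined, res$world$grid)
pop <- attr(rd, "population")
aggregate_estimate(rd, pop, list(year = 2018, country = "C01"))
#>                   scope median  lo95  hi95 population
#> 1 year=2018,country=C01  2.208 2.149 2.269    5340322

# its change 2005 -> 2018, standardized to 2018 demographics
change_estimate(year_slice(rd, 2005), year_slice(rd, 2018),
                pop[pop$year == 2018, ], list(country = "C01"))
#>         scope absolute   lo95   hi95 percent level_y1 significant
#> 1 country=C01   0.1554 0.1054 0.2061   7.569    2.054        TRUE

# the country with no surveys at all still gets an estimate -- from the
# hierarchy, with an honestly enormous interval
aggregate_estimate(rd, pop, list(year = 2018, country = "C02"))
#>                   scope median   lo95  hi95 population
#> 1 year=2018,country=C02  4.954 0.6164 144.5    3024685

# how well was the known truth recovered?
res$recovery$stratum$correlation
#> [1] 0.969
```

Reading the output: adults in surveyed country C01 drank a median 2.21
servings/week in 2018 (95% UI 2.15–2.27; the generator's true value is
2.24), and intake rose by +0.16 servings/week (+7.6%) since 2005 with an
interval excluding zero, so the change is flagged significant. C02,
which has no surveys, is estimated purely from the regional hierarchy —
its interval honestly spans two orders of magnitude. The final number is
the correlation between estimated and true stratum means, computable
only because the world is synthetic.

`run_pipeline()` writes every stage's table (`world.csv`,
`observations.csv`, `estimates.csv`, report tables) plus a run log with
seeds and convergence diagnostics into the output directory; rerunning
with the same config reproduces the files bit for bit.

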