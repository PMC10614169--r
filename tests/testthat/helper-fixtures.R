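# Expensive fixtures (Bayesian fits) are built once per test run and
# shared across test files through this cache.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache, inherits = FALSE)
}

# the seeded default synthetic world with moderate noise: 3 regions x 5
# countries, years 1990/2005/2018, ~60% country-year survey coverage,
# fitted with 500 draws
default_world_fit <- function() {
  fixture("default_world_fit", function() {
    world <- generate_world(world_config(), seed = 20240901)
    scenario <- default_scenario(world, coverage = 0.6, seed = 20240901)
    collection <- simulate_survey_collection(world, scenario, seed = 20240901)
    screened <- harmonize_surveys(collection)
    grid <- dplyr::left_join(world$grid, world$countries, by = "country")
    inputs <- assemble_inputs(screened$kept, grid, world$covariate,
                              model_config(n_draws = 500, burnin = 1200, min_iter_per_chain = 1500))
    fit <- fit_intake_model(inputs, seed = 20240901, max_retries = 2)
    est <- stratum_estimates(fit)
    list(world = world, collection = collection, observations = screened$kept,
         grid = grid, inputs = inputs, fit = fit, estimates = est,
         recovery = recovery_report(world, est))
  })
}

# the same scenario with all noise and bias switched off (no household
# surveys: the AME allocation error is systematic, not noise)
noiseless_closure_fit <- function() {
  fixture("noiseless_closure_fit", function() {
    world <- generate_world(world_config(), seed = 20240901)
    scenario <- default_scenario(world, coverage = 0.6, seed = 20240901,
                                 noise = 0)
    collection <- simulate_survey_collection(world, scenario, seed = 20240901)
    screened <- harmonize_surveys(collection)
    grid <- dplyr::left_join(world$grid, world$countries, by = "country")
    inputs <- assemble_inputs(screened$kept, grid, world$covariate,
                              model_config(n_draws = 500, burnin = 1200, min_iter_per_chain = 1500))
    fit <- fit_intake_model(inputs, seed = 20240901, max_retries = 2)
    est <- stratum_estimates(fit)
    truth <- world$grid
    i <- match(do.call(paste, truth[, 1:6]), do.call(paste, est[, 1:6]))
    est <- est[i, ]
    adult <- match(truth$age_group, age_bands()) >= 7
    surveyed <- paste(truth$country, truth$year) %in%
      paste(collection$manifest$country, collection$manifest$year)
    sel <- adult & surveyed
    rmse <- sqrt(mean((est$median - truth$true_mean)[sel]^2))
    list(world = world, estimates = est, rmse = rmse)
  })
}

# compact low-noise world for the cross-validation harness: every
# country-year carries two identically designed national FFQs with 1%
# between-person variation, reported at 5-year bands for ages 20-39
cv_fixture <- function() {
  fixture("cv_fixture", function() {
    world <- generate_world(
      world_config(n_regions = 1, countries_per_region = 2,
                   years = c(1990L, 2018L)),
      seed = 20240902
    )
    design <- survey_design("FFQ", "national", age_band_width = 5,
                            age_min = "20-24", age_max = "35-39",
                            n_per_stratum = 50, person_cv = 0.01,
                            energy_cv = 0)
    s <- tidyr::expand_grid(country = world$countries$country,
                            year = world$years, rep = 1:2)
    scenario <- tibble::tibble(
      survey_id = sprintf("S%03d", seq_len(nrow(s))),
      country = s$country, year = s$year, kind = "ffq",
      design = replicate(nrow(s), design, simplify = FALSE)
    )
    collection <- simulate_survey_collection(world, scenario, seed = 20240902)
    obs <- harmonize_surveys(collection)$kept
    grid <- dplyr::left_join(world$grid, world$countries, by = "country")
    folds <- kfold_split(unique(obs$survey_id), k = 5, seed = 20240902)
    # the compact world has a pronounced covariate/country-level ridge,
    # so the per-fold fits get generous chains (they are tiny and fast)
    report <- cv_evaluate(obs, folds, grid, world$covariate,
                          model_config(n_draws = 300, burnin = 6000,
                                       min_iter_per_chain = 6000),
                          seed = 20240902)
    list(world = world, observations = obs, folds = folds, report = report)
  })
}

# a tiny one-country world whose grid/covariates can host hand-written
# observation tables for conjugate-oracle checks
toy_grid <- function(n_countries = 1, years = 2018L, seed = 1) {
  world <- generate_world(
    world_config(n_regions = 1, countries_per_region = n_countries,
                 years = years),
    seed = seed
  )
  list(world = world,
       grid = dplyr::left_join(world$grid, world$countries, by = "country"))
}

# a full sex x education x urbanicity cross of observation cells at one
# age band, all with the same mean: identifies every demographic effect,
# so tiny conjugate-oracle fits mix well
toy_obs_cross <- function(survey_id, country, year, mean, sd = 0.5, n = 400) {
  cells <- tidyr::expand_grid(sex = c("female", "male"),
                              education = c("low", "medium", "high"),
                              urbanicity = c("rural", "urban"))
  tibble::tibble(
    survey_id = survey_id, country = country, year = as.integer(year),
    age_lo = 7L, age_hi = 7L, sex = cells$sex, education = cells$education,
    urbanicity = cells$urbanicity, mean = mean, sd = sd, n = as.integer(n),
    method = "FFQ", representativeness = "national",
    pooled_sex = FALSE, pooled_education = FALSE, pooled_urbanicity = FALSE
  )
}

# hand-written single-cell observation rows (age band index 7, female,
# low education, rural unless overridden)
toy_obs <- function(survey_id, country, year, mean, sd = 0.5, n = 400,
                    representativeness = "national") {
  tibble::tibble(
    survey_id = survey_id, country = country, year = as.integer(year),
    age_lo = 7L, age_hi = 7L, sex = "female", education = "low",
    urbanicity = "rural", mean = mean, sd = sd, n = as.integer(n),
    method = "FFQ", representativeness = representativeness,
    pooled_sex = FALSE, pooled_education = FALSE, pooled_urbanicity = FALSE
  )
}
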