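#' Configuration for a synthetic world
#'
#' The synthetic world defines a known true mean SSB intake (servings/week)
#' for every stratum of every country-year, built additively on the log
#' scale from a global intercept, region and country random effects,
#' demographic (age/sex/education/urbanicity) effects, and a
#' covariate-driven time term. The log-additive construction guarantees
#' positivity and contains no demographic interactions; it is a synthetic
#' convention of this package, chosen so effect recovery by the intake
#' model is well defined.
#'
#' @param n_regions Number of world regions.
#' @param countries_per_region Countries per region.
#' @param years Calendar years carried by the world.
#' @param intercept Global intercept on the log servings/week scale.
#' @param region_sd,country_sd SDs of region and country random effects
#'   (log scale).
#' @param age_decline Mean absolute per-band decline of the age effect
#'   beyond the 20-24 band (log scale); the age curve is monotone
#'   non-increasing beyond that band by construction.
#' @param child_rise Per-band rise from the youngest band up to 20-24.
#' @param sex_effect Male minus female effect (log scale).
#' @param education_effects Named vector with `medium` and `high` effects
#'   relative to low education (log scale).
#' @param urban_effect Urban minus rural effect (log scale).
#' @param covariate_slope Effect (log scale) of the z-scored log beverage
#'   availability proxy; this is the only source of time variation in the
#'   true surface.
#' @param covariate_growth Mean yearly growth rate of the availability
#'   proxy.
#' @param base_population Median country population (persons).
#' @return A list of class `ssb_world_config`.
#' @export
world_config <- function(n_regions = 3,
                         countries_per_region = 5,
                         years = c(1990L, 2005L, 2018L),
                         intercept = log(2.7),
                         region_sd = 0.3,
                         country_sd = 0.3,
                         age_decline = 0.08,
                         child_rise = 0.05,
                         sex_effect = 0.1,
                         education_effects = c(medium = 0.15, high = 0.3),
                         urban_effect = 0.25,
                         covariate_slope = 0.3,
                         covariate_growth = 0.015,
                         base_population = 5e6) {
  assert_scalar_count(n_regions, "n_regions")
  assert_scalar_count(countries_per_region, "countries_per_region")
  if (length(years) < 1) stop("at least one year is required")
  structure(
    list(
      n_regions = as.integer(n_regions),
      countries_per_region = as.integer(countries_per_region),
      years = sort(as.integer(years)),
      intercept = intercept,
      region_sd = region_sd, country_sd = country_sd,
      age_decline = age_decline, child_rise = child_rise,
      sex_effect = sex_effect,
      education_effects = education_effects,
      urban_effect = urban_effect,
      covariate_slope = covariate_slope,
      covariate_growth = covariate_growth,
      base_population = base_population
    ),
    class = "ssb_world_config"
  )
}

#' Generate a synthetic world with a known true intake surface
#'
#' Draws region/country effects, a monotone age curve, per-country beverage
#' availability series, SDI values, and a stratum population table, then
#' evaluates the closed-form true mean for all 264 strata of every
#' country-year. Deterministic for a fixed `(config, seed)`.
#'
#' @param config An [world_config()] object.
#' @param seed Integer seed; fully determines the world.
#' @return An object of class `ssb_world`: a list with `regions`,
#'   `countries` (country-to-region map), `years`, `effects` (the true
#'   log-scale effects), `covariate` (country-year availability with its
#'   z-score), `sdi`, and `grid` (one row per stratum with `true_mean` and
#'   `population`).
#' @export
generate_world <- function(config = world_config(), seed = 1L) {
  stopifnot(inherits(config, "ssb_world_config"))
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  regions <- sprintf("R%d", seq_len(config$n_regions))
  n_c <- config$n_regions * config$countries_per_region
  countries <- tibble::tibble(
    country = sprintf("C%02d", seq_len(n_c)),
    region = rep(regions, each = config$countries_per_region)
  )

  effects <- list(
    intercept = config$intercept,
    region = stats::setNames(rnorm_sd0(config$n_regions, config$region_sd), regions),
    country = stats::setNames(rnorm_sd0(n_c, config$country_sd), countries$country),
    age = age_curve(config, stats::runif(22)),
    sex_male = config$sex_effect,
    education = c(low = 0,
                  medium = unname(config$education_effects["medium"]),
                  high = unname(config$education_effects["high"])),
    urban = config$urban_effect,
    covariate_slope = config$covariate_slope
  )

  # availability proxy: per-country level and growth; log-linear in time
  log_base <- stats::rnorm(n_c, 0, 0.4)
  growth <- config$covariate_growth * (1 + stats::rnorm(n_c, 0, 0.5))
  covariate <- tidyr::expand_grid(country = countries$country, year = config$years)
  i <- match(covariate$country, countries$country)
  covariate$availability <-
    exp(1 + log_base[i] + growth[i] * (covariate$year - min(config$years)))
  lc <- log(covariate$availability)
  cov_center <- mean(lc)
  cov_scale <- if (length(lc) > 1 && stats::sd(lc) > 0) stats::sd(lc) else 1
  covariate$z <- (lc - cov_center) / cov_scale

  sdi <- tibble::tibble(country = countries$country,
                        sdi = stats::runif(n_c, 0.15, 0.95))

  population <- build_population(config, countries, seed)

  world <- structure(
    list(
      regions = regions,
      countries = countries,
      years = config$years,
      effects = effects,
      covariate = covariate,
      covariate_scaling = c(center = cov_center, scale = cov_scale),
      sdi = sdi,
      config = config,
      seed = as.integer(seed)
    ),
    class = "ssb_world"
  )

  grid <- stratum_grid(countries$country, config$years)
  grid$true_mean <- true_stratum_mean(world, grid)
  grid$population <- population$population[match(
    paste(grid$country, grid$year, grid$age_group, grid$sex,
          grid$education, grid$urbanicity),
    paste(population$country, population$year, population$age_group,
          population$sex, population$education, population$urbanicity)
  )]
  world$grid <- grid
  world
}

# rnorm that returns exact zeros when sd == 0 (degenerate configs)
rnorm_sd0 <- function(n, sd) {
  if (sd == 0) rep(0, n) else stats::rnorm(n, 0, sd)
}

# monotone age curve: rises up to the 20-24 band, non-increasing after it
age_curve <- function(config, u) {
  a <- numeric(22)
  for (k in 6:1) a[k] <- a[k + 1] - config$child_rise
  if (config$age_decline > 0) {
    steps <- config$age_decline * (0.5 + u[8:22]) # strictly positive declines
    for (k in 8:22) a[k] <- a[k - 1] - steps[k - 7]
  }
  stats::setNames(a, .AGE_BANDS)
}

build_population <- function(config, countries, seed) {
  n_c <- nrow(countries)
  log_pop <- stats::rnorm(n_c, log(config$base_population), 0.5)
  urban_base <- stats::runif(n_c, 0.3, 0.8)
  edu_raw <- matrix(stats::rgamma(n_c * 3, shape = c(7, 8, 5)), ncol = 3,
                    byrow = TRUE)
  edu_p <- edu_raw / rowSums(edu_raw)
  mid <- .AGE_LOWER + .AGE_WIDTHS / 2
  age_w <- .AGE_WIDTHS * exp(-0.025 * mid)
  age_w <- age_w / sum(age_w)

  pop <- stratum_grid(countries$country, config$years)
  i <- match(pop$country, countries$country)
  a <- age_band_index(pop$age_group)
  e <- match(pop$education, .EDUCATIONS)
  urb_share <- stats::plogis(stats::qlogis(urban_base[i]) +
                               0.01 * (pop$year - min(config$years)))
  pop$population <- exp(log_pop[i]) * 1.012^(pop$year - min(config$years)) *
    age_w[a] * 0.5 *
    edu_p[cbind(i, e)] *
    ifelse(pop$urbanicity == "urban", urb_share, 1 - urb_share)
  pop
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' True mean intake for strata of a synthetic world
#'
#' Evaluates the generator's closed-form log-additive surface exactly:
#' `exp(intercept + region + country + age + sex + education + urbanicity
#' + slope * z(covariate))`.
#'
#' @param world An `ssb_world`.
#' @param key A data frame with stratum key columns (`country`, `year`,
#'   `age_group`, `sex`, `education`, `urbanicity`).
#' @return Numeric vector of true mean intakes (servings/week), one per
#'   row of `key`.
#' @export
true_stratum_mean <- function(world, key) {
  stopifnot(inherits(world, "ssb_world"))
  ef <- world$effects
  ci <- match(key$country, world$countries$country)
  if (anyNA(ci)) {
    stop("unknown country: ",
         paste(unique(key$country[is.na(ci)]), collapse = ", "))
  }
  if (!all(key$year %in% world$years)) {
    stop("unknown year: ",
         paste(setdiff(unique(key$year), world$years), collapse = ", "))
  }
  zi <- match(paste(key$country, key$year),
              paste(world$covariate$country, world$covariate$year))
  eta <- ef$intercept +
    ef$region[world$countries$region[ci]] +
    ef$country[key$country] +
    ef$age[key$age_group] +
    ef$sex_male * (key$sex == "male") +
    ef$education[key$education] +
    ef$urban * (key$urbanicity == "urban") +
    ef$covariate_slope * world$covariate$z[zi]
  unname(exp(eta))
}

#' Describe a survey design
#'
#' A survey design captures the assessment method and its error structure,
#' representativeness, stratification granularity, and per-stratum sample
#' size, mirroring the survey metadata the pooling model conditions on.
#'
#' @param method One of `"24HR"` (multi-day recall with within-person
#'   day-to-day noise), `"FFQ"` (usual intake with an optional
#'   multiplicative bias), `"HBS"` (household totals plus member rosters).
#' @param representativeness `"national"`, `"subnational"` or
#'   `"community"`. Non-national designs sample urban strata only (the
#'   commonest real-world coverage bias).
#' @param age_band_width Reporting age-band width in years (5 or 10).
#' @param pool_age If `TRUE` the survey pools its whole covered age range
#'   into a single reported band (typical of household budget surveys).
#' @param report_sex,report_education,report_urbanicity Whether the survey
#'   reports that dimension or pools over it.
#' @param n_per_stratum Participants (or households for HBS) per reported
#'   cell; allocated across the fine strata a cell covers in proportion
#'   to their population, so survey cell means estimate the same
#'   population-weighted quantity the model predicts for the cell.
#' @param days Assessment days for 24HR.
#' @param age_min,age_max Age band labels bounding the covered range.
#' @param person_cv Between-person coefficient of variation of usual
#'   intake (lognormal, mean-preserving).
#' @param day_cv Within-person day-to-day coefficient of variation for
#'   24HR (each day is the person's usual intake times `1 + N(0,
#'   day_cv)`, floored at zero); for a person with usual intake u the
#'   within-person SD is `day_cv * u`.
#' @param ffq_bias Multiplicative reporting bias of the FFQ instrument.
#' @param energy_cv CV of reported total energy around the age-specific
#'   standard (truncated at 800 kcal/day).
#' @param energy_coupling Exponent coupling observed intake to the ratio
#'   of reported energy to standard energy; 1 means intake scales
#'   proportionally with total consumption, which is what the residual
#'   energy adjustment removes.
#' @return A list of class `ssb_survey_design`.
#' @export
survey_design <- function(method = c("24HR", "FFQ", "HBS"),
                          representativeness = c("national", "subnational", "community"),
                          age_band_width = 5,
                          pool_age = FALSE,
                          report_sex = TRUE,
                          report_education = TRUE,
                          report_urbanicity = TRUE,
                          n_per_stratum = 50,
                          days = 2,
                          age_min = "20-24",
                          age_max = "95+",
                          person_cv = 0.5,
                          day_cv = 0.5,
                          ffq_bias = 1,
                          energy_cv = 0.15,
                          energy_coupling = 1) {
  method <- match.arg(method)
  representativeness <- match.arg(representativeness)
  assert_scalar_count(n_per_stratum, "n_per_stratum")
  assert_scalar_count(days, "days")
  if (!age_band_width %in% c(5, 10)) stop("age_band_width must be 5 or 10")
  structure(
    list(
      method = method,
      representativeness = representativeness,
      age_band_width = age_band_width,
      pool_age = pool_age,
      report_sex = report_sex,
      report_education = report_education,
      report_urbanicity = report_urbanicity,
      household_level = method == "HBS",
      n_per_stratum = as.integer(n_per_stratum),
      days = as.integer(days),
      age_min = age_min, age_max = age_max,
      person_cv = person_cv, day_cv = day_cv, ffq_bias = ffq_bias,
      energy_cv = energy_cv, energy_coupling = energy_coupling
    ),
    class = "ssb_survey_design"
  )
}

# energy standard used when simulating reported energy, by age band index
energy_standard_for_band <- function(band_idx,
                                     standard = energy_standard()) {
  ifelse(band_idx < 7, 1500,
         ifelse(band_idx <= 17, standard$kcal_adults, standard$kcal_elderly))
}

#' Simulate one survey from a synthetic world
#'
#' Draws individual-level (or household-level for HBS) records from the
#' world's true intake surface under the design's error structure. With
#' all noise and bias parameters at their neutral values every
#' participant's mean equals the true stratum mean exactly.
#'
#' @param world An `ssb_world`.
#' @param design An [survey_design()].
#' @param country,year The surveyed country-year (must exist in the world).
#' @param seed Integer seed.
#' @param survey_id Identifier stamped on every record.
#' @return A tibble of raw records. Individual rows carry `intake`
#'   (servings/week; one row per day for 24HR) and `energy_kcal`;
#'   household-member rows carry `household_total` for the whole household
#'   and per-member demographics instead of individual intakes.
#' @export
simulate_survey <- function(world, design, country, year, seed = 1L,
                            survey_id = "S1") {
  stopifnot(inherits(world, "ssb_world"), inherits(design, "ssb_survey_design"))
  if (!country %in% world$countries$country) {
    stop("country not in world: ", country)
  }
  if (!year %in% world$years) stop("year not in world: ", year)
  lo <- age_band_index(design$age_min)
  hi <- age_band_index(design$age_max)
  if (lo > hi) stop("design covers no age bands")

  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)

  frame <- dplyr::filter(
    world$grid, .data$country == !!country, .data$year == !!year,
    age_band_index(.data$age_group) >= lo, age_band_index(.data$age_group) <= hi
  )
  if (design$representativeness != "national") {
    frame <- dplyr::filter(frame, .data$urbanicity == "urban")
  }
  if (nrow(frame) == 0) stop("design requests strata absent from world")

  if (design$method == "HBS") {
    return(simulate_hbs(world, design, frame, country, year, survey_id))
  }

  # allocate the per-cell sample across the fine strata each reported
  # cell covers, proportionally to population (representative sampling
  # within cells)
  band <- age_band_index(frame$age_group)
  cell <- reported_cell_key(band, frame$sex, frame$education,
                            frame$urbanicity, design)
  cell_id <- paste(cell$age_lo, cell$age_hi, cell$sex, cell$education,
                   cell$urbanicity)
  frame$n_alloc <- 0L
  for (cid in unique(cell_id)) {
    rows_c <- which(cell_id == cid)
    frame$n_alloc[rows_c] <-
      allocate_proportional(design$n_per_stratum, frame$population[rows_c])
  }

  sigma_p <- sqrt(log(1 + design$person_cv^2))
  rows <- lapply(which(frame$n_alloc > 0), function(s) {
    st <- frame[s, ]
    n <- st$n_alloc
    e_std <- energy_standard_for_band(age_band_index(st$age_group))
    usual <- st$true_mean *
      (if (sigma_p == 0) rep(1, n) else
        exp(stats::rnorm(n, 0, sigma_p) - sigma_p^2 / 2))
    energy <- if (design$energy_cv == 0) rep(e_std, n) else
      pmax(800, stats::rnorm(n, e_std, design$energy_cv * e_std))
    base <- usual * (energy / e_std)^design$energy_coupling
    if (design$method == "FFQ") {
      tibble::tibble(
        participant_id = sprintf("%s_%s_p%03d", survey_id, s, seq_len(n)),
        age_group = st$age_group, sex = st$sex, education = st$education,
        urbanicity = st$urbanicity, day = NA_integer_,
        intake = pmax(0, base * design$ffq_bias), energy_kcal = energy
      )
    } else { # 24HR: one row per assessment day, multiplicative day noise
      d <- design$days
      tibble::tibble(
        participant_id = rep(sprintf("%s_%s_p%03d", survey_id, s, seq_len(n)),
                             each = d),
        age_group = st$age_group, sex = st$sex, education = st$education,
        urbanicity = st$urbanicity, day = rep(seq_len(d), n),
        intake = pmax(0, rep(base, each = d) *
                        (1 + (if (design$day_cv == 0) 0 else
                          stats::rnorm(n * d, 0, design$day_cv)))),
        energy_kcal = rep(energy, each = d)
      )
    }
  })
  out <- dplyr::bind_rows(rows)
  tibble::tibble(
    survey_id = survey_id, record_type = "individual",
    household_id = NA_character_, participant_id = out$participant_id,
    country = country, year = as.integer(year),
    age_group = out$age_group, sex = out$sex, education = out$education,
    urbanicity = out$urbanicity, day = out$day, intake = out$intake,
    energy_kcal = out$energy_kcal, household_total = NA_real_
  )
}

simulate_hbs <- function(world, design, frame, country, year, survey_id) {
  sigma_p <- sqrt(log(1 + design$person_cv^2))
  cells <- dplyr::distinct(frame, .data$education, .data$urbanicity)
  lo <- age_band_index(design$age_min)
  hi <- age_band_index(design$age_max)
  # member age/sex distribution follows the country-year population
  agesex <- dplyr::summarise(
    dplyr::group_by(frame, .data$age_group, .data$sex),
    population = sum(.data$population), .groups = "drop"
  )
  rows <- list()
  hh_counter <- 0L
  for (ci in seq_len(nrow(cells))) {
    for (h in seq_len(design$n_per_stratum)) {
      hh_counter <- hh_counter + 1L
      hh_id <- sprintf("%s_h%04d", survey_id, hh_counter)
      size <- min(6L, 1L + stats::rpois(1, 1.5))
      pick <- sample.int(nrow(agesex), size, replace = TRUE,
                         prob = agesex$population)
      members <- tibble::tibble(
        age_group = agesex$age_group[pick], sex = agesex$sex[pick],
        education = cells$education[ci], urbanicity = cells$urbanicity[ci]
      )
      tm <- true_stratum_mean(world, tibble::tibble(
        country = country, year = as.integer(year),
        age_group = members$age_group, sex = members$sex,
        education = members$education, urbanicity = members$urbanicity
      ))
      usual <- tm * (if (sigma_p == 0) rep(1, size) else
        exp(stats::rnorm(size, 0, sigma_p) - sigma_p^2 / 2))
      rows[[hh_counter]] <- tibble::tibble(
        survey_id = survey_id, record_type = "household_member",
        household_id = hh_id,
        participant_id = sprintf("%s_m%d", hh_id, seq_len(size)),
        country = country, year = as.integer(year),
        age_group = members$age_group, sex = members$sex,
        education = members$education, urbanicity = members$urbanicity,
        day = NA_integer_, intake = NA_real_, energy_kcal = NA_real_,
        household_total = sum(usual)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Build the default survey scenario for a world
#'
#' Selects roughly `coverage` of all country-years for surveying (always
#' leaving at least one country with no surveys at all, so extrapolation
#' to unsurveyed countries is exercised) and assigns each selected
#' country-year one or two surveys drawn from a realistic design mix:
#' nationally representative multi-day 24HR surveys with full
#' stratification, coarser national FFQs with pooled education, urban-only
#' subnational FFQs, and an occasional household budget survey.
#'
#' @param world An `ssb_world`.
#' @param coverage Fraction of country-years receiving at least one survey.
#' @param seed Integer seed.
#' @param noise Multiplier applied to all noise parameters of the design
#'   mix (0 gives completely noiseless surveys).
#' @param n_per_stratum Participants per reported cell.
#' @param include_hbs Include household budget surveys in the mix.
#'   Noiseless-closure runs exclude them: the adult-male-equivalent
#'   disaggregation is an approximation whose allocation error is
#'   systematic and does not vanish as measurement noise goes to zero.
#' @return A tibble scenario: `survey_id`, `country`, `year` and a
#'   `design` list-column, usable with [simulate_survey_collection()].
#' @export
default_scenario <- function(world, coverage = 0.6, seed = 1L, noise = 1,
                             n_per_stratum = 50, include_hbs = noise > 0) {
  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, "scenario"))
  on.exit(restore_rng(old), add = TRUE)

  cys <- tidyr::expand_grid(country = world$countries$country,
                            year = world$years)
  holdout <- sample(world$countries$country, 1)
  eligible <- cys[cys$country != holdout, ]
  n_pick <- max(1L, round(coverage * nrow(cys)))
  pick <- eligible[sample.int(nrow(eligible), min(n_pick, nrow(eligible))), ]

  mk <- function(kind) {
    switch(kind,
      # multi-day recall, 5-year bands, education pooled (common in
      # practice; the pooling triggers the overdispersion rule)
      national_24hr = survey_design("24HR", "national", age_band_width = 5,
                                    report_education = FALSE,
                                    n_per_stratum = n_per_stratum, days = 2,
                                    person_cv = 0.5 * noise, day_cv = 0.5 * noise,
                                    energy_cv = 0.15 * noise),
      # fully jointly stratified FFQ at 10-year bands
      national_ffq = survey_design("FFQ", "national", age_band_width = 10,
                                   n_per_stratum = n_per_stratum,
                                   person_cv = 0.5 * noise, ffq_bias = 1,
                                   energy_cv = 0.15 * noise),
      subnational_ffq = survey_design("FFQ", "subnational", age_band_width = 10,
                                      n_per_stratum = n_per_stratum,
                                      person_cv = 0.5 * noise, ffq_bias = 1,
                                      energy_cv = 0.15 * noise),
      # household totals disaggregated by AME; reported per household
      # stratum only (age and sex pooled), as household budget surveys do
      hbs = survey_design("HBS", "national", pool_age = TRUE,
                          report_sex = FALSE,
                          n_per_stratum = max(10L, n_per_stratum %/% 2),
                          age_min = "<1",
                          person_cv = 0.5 * noise, energy_cv = 0)
    )
  }
  kinds <- c("national_24hr", "national_ffq", "subnational_ffq", "hbs")
  probs <- c(0.45, 0.3, 0.2, 0.05)
  if (!include_hbs) {
    kinds <- kinds[1:3]
    probs <- c(0.45, 0.35, 0.2)
  }

  specs <- list()
  sid <- 0L
  for (i in seq_len(nrow(pick))) {
    sid <- sid + 1L
    kind <- sample(kinds, 1, prob = probs)
    specs[[sid]] <- tibble::tibble(
      survey_id = sprintf("S%03d", sid),
      country = pick$country[i], year = pick$year[i],
      kind = kind, design = list(mk(kind))
    )
  }
  dplyr::bind_rows(specs)
}

#' Simulate a whole survey collection with coverage gaps
#'
#' @param world An `ssb_world`.
#' @param scenario A scenario tibble as returned by [default_scenario()]
#'   (columns `survey_id`, `country`, `year`, `design`).
#' @param seed Integer seed; each survey derives its own child seed.
#' @return A list with `manifest` (one row per survey with its metadata)
#'   and `records` (all raw records, stamped with `survey_id`).
#' @export
simulate_survey_collection <- function(world, scenario, seed = 1L) {
  if (is.null(scenario) || nrow(scenario) == 0) {
    stop("scenario is empty: at least one survey is required")
  }
  recs <- vector("list", nrow(scenario))
  man <- vector("list", nrow(scenario))
  for (i in seq_len(nrow(scenario))) {
    d <- scenario$design[[i]]
    recs[[i]] <- simulate_survey(
      world, d, scenario$country[i], scenario$year[i],
      seed = derive_seed(seed, scenario$survey_id[i]),
      survey_id = scenario$survey_id[i]
    )
    man[[i]] <- tibble::tibble(
      survey_id = scenario$survey_id[i],
      country = scenario$country[i], year = as.integer(scenario$year[i]),
      method = d$method, representativeness = d$representativeness,
      age_band_width = d$age_band_width,
      report_sex = d$report_sex, report_education = d$report_education,
      report_urbanicity = d$report_urbanicity,
      household_level = d$household_level,
      n_per_stratum = d$n_per_stratum
    )
  }
  list(manifest = dplyr::bind_rows(man), records = dplyr::bind_rows(recs),
       designs = stats::setNames(scenario$design, scenario$survey_id))
}
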