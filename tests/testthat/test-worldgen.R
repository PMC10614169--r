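test_that("world generation is deterministic and rejects bad configs", {
  cfg <- world_config(n_regions = 2, countries_per_region = 2,
                      years = c(2005, 2018))
  w1 <- generate_world(cfg, seed = 5)
  w2 <- generate_world(cfg, seed = 5)
  expect_identical(w1$grid, w2$grid)
  expect_identical(w1$effects, w2$effects)
  expect_identical(w1$covariate, w2$covariate)

  expect_error(world_config(n_regions = 0), "positive integer")
  expect_error(world_config(countries_per_region = -1), "positive integer")
  expect_error(world_config(years = numeric(0)), "at least one year")
})

test_that("degenerate config gives a constant surface; effects scale as configured", {
  flat <- world_config(n_regions = 2, countries_per_region = 2,
                       region_sd = 0, country_sd = 0, age_decline = 0,
                       child_rise = 0, sex_effect = 0,
                       education_effects = c(medium = 0, high = 0),
                       urban_effect = 0, covariate_slope = 0,
                       intercept = log(2.7))
  w <- generate_world(flat, seed = 3)
  expect_equal(unique(w$grid$true_mean), 2.7, tolerance = 1e-12)

  # with 30 countries at a 0.3 log-scale SD the empirical SD of country
  # effects lands near 0.3
  big <- world_config(n_regions = 1, countries_per_region = 30,
                      country_sd = 0.3)
  wb <- generate_world(big, seed = 3)
  expect_lt(abs(sd(wb$effects$country) - 0.3), 0.1)
})

test_that("the true surface matches an independent reimplementation", {
  w <- generate_world(world_config(), seed = 9)
  set.seed(99)
  keys <- w$grid[sample.int(nrow(w$grid), 10), 1:6]
  got <- true_stratum_mean(w, keys)
  ef <- w$effects
  for (i in 1:10) {
    k <- keys[i, ]
    region <- w$countries$region[w$countries$country == k$country]
    z <- w$covariate$z[w$covariate$country == k$country &
                         w$covariate$year == k$year]
    eta <- ef$intercept + ef$region[[region]] + ef$country[[k$country]] +
      ef$age[[k$age_group]] +
      (if (k$sex == "male") ef$sex_male else 0) +
      ef$education[[k$education]] +
      (if (k$urbanicity == "urban") ef$urban else 0) +
      ef$covariate_slope * z
    expect_equal(got[i], exp(eta), tolerance = 1e-12)
  }
  expect_error(true_stratum_mean(w, transform(keys[1, ], country = "XX")),
               "unknown country")
  expect_error(true_stratum_mean(w, transform(keys[1, ], year = 1800L)),
               "unknown year")
})

test_that("true surface is positive and monotone non-increasing beyond 20-24", {
  w <- generate_world(world_config(), seed = 11)
  expect_true(all(w$grid$true_mean > 0))
  a <- w$effects$age
  expect_true(all(diff(a[7:22]) <= 0))
  # population weights over any country-year normalize exactly
  pop <- w$grid[w$grid$country == "C01" & w$grid$year == 2018, ]
  expect_equal(sum(pop$population / sum(pop$population)), 1, tolerance = 1e-12)
})

test_that("noiseless surveys reproduce the truth; FFQ bias acts multiplicatively", {
  w <- generate_world(world_config(n_regions = 1, countries_per_region = 1,
                                   years = 2018), seed = 2)
  noiseless <- survey_design("FFQ", "national", n_per_stratum = 5,
                             person_cv = 0, energy_cv = 0, ffq_bias = 1)
  rec <- simulate_survey(w, noiseless, "C01", 2018, seed = 4)
  truth <- true_stratum_mean(w, rec[, c("country", "year", "age_group", "sex",
                                        "education", "urbanicity")])
  expect_equal(rec$intake, truth, tolerance = 1e-12)

  biased <- survey_design("FFQ", "national", n_per_stratum = 5,
                          person_cv = 0, energy_cv = 0, ffq_bias = 1.2)
  rec_b <- simulate_survey(w, biased, "C01", 2018, seed = 4)
  expect_equal(rec_b$intake / truth, rep(1.2, nrow(rec_b)), tolerance = 1e-12)

  expect_error(simulate_survey(w, noiseless, "C99", 2018), "not in world")
  expect_error(simulate_survey(w, noiseless, "C01", 1990), "not in world")
})

test_that("two-day recall halves the within-person variance of person means", {
  w <- generate_world(world_config(n_regions = 1, countries_per_region = 1,
                                   years = 2018), seed = 2)
  # one reported cell (single band, all else fixed by frame), many people
  d <- survey_design("24HR", "national", age_band_width = 5,
                     age_min = "45-49", age_max = "45-49",
                     report_education = FALSE, report_urbanicity = FALSE,
                     report_sex = FALSE,
                     n_per_stratum = 4000, days = 2,
                     person_cv = 0, day_cv = 0.2, energy_cv = 0)
  rec <- simulate_survey(w, d, "C01", 2018, seed = 8)
  pm <- tapply(rec$intake, rec$participant_id, mean)
  # persons in the pooled cell span several fine strata with different
  # true means; check the variance within the largest single stratum
  key <- paste(rec$age_group, rec$sex, rec$education, rec$urbanicity)
  one <- names(sort(table(key), decreasing = TRUE))[1]
  sel <- rec[key == one & rec$day == 1, ]
  pm1 <- pm[sel$participant_id]
  mu <- true_stratum_mean(w, sel[1, c("country", "year", "age_group", "sex",
                                      "education", "urbanicity")])
  sigma_w <- 0.2 * mu
  expect_lt(abs(var(pm1) - sigma_w^2 / 2) / (sigma_w^2 / 2), 0.2)
})

test_that("survey collections honor the scenario manifest and coverage gaps", {
  w <- generate_world(world_config(), seed = 13)
  sc <- default_scenario(w, coverage = 0.6, seed = 13)
  col <- simulate_survey_collection(w, sc, seed = 13)
  expect_identical(nrow(col$manifest), nrow(sc))
  expect_identical(col$manifest$survey_id, sc$survey_id)
  # at least one country has no surveys at all
  unsurveyed <- setdiff(w$countries$country, col$manifest$country)
  expect_gte(length(unsurveyed), 1)
  expect_false(any(col$records$country %in% unsurveyed))
  expect_error(simulate_survey_collection(w, sc[0, ], seed = 1), "empty")

  # household totals are conserved by AME disaggregation
  hbs_ids <- col$manifest$survey_id[col$manifest$household_level]
  if (length(hbs_ids) == 0) {
    d <- survey_design("HBS", "national", pool_age = TRUE, age_min = "<1",
                       n_per_stratum = 5)
    rec <- simulate_survey(w, d, "C01", 2018, seed = 3, survey_id = "H1")
  } else {
    rec <- col$records[col$records$survey_id == hbs_ids[1], ]
  }
  h <- rec[rec$household_id == rec$household_id[1], ]
  shares <- ame_disaggregate(h$household_total[1],
                             h[, c("age_group", "sex")])
  expect_equal(sum(shares), h$household_total[1], tolerance = 1e-12)
  expect_true(all(col$records$intake >= 0 | is.na(col$records$intake)))
})
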