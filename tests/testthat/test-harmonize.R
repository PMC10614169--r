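test_that("serving-unit conversion is exact arithmetic", {
  expect_equal(convert_serving_units(248), 1)
  expect_equal(convert_serving_units(0), 0)
  # two request-time 236.5 g servings expressed in 248 g reporting servings
  expect_equal(convert_serving_units(473), 473 / 248, tolerance = 1e-12)
  expect_equal(round(convert_serving_units(473), 4), 1.9073)
  expect_error(convert_serving_units(-1), ">= 0")
  expect_error(serving_definition(0), "> 0")
})

test_that("residual energy adjustment matches its closed form", {
  # everyone exactly at the standard: identity (degenerate slope path)
  intakes <- c(1.2, 3.4, 0.8, 2.2)
  expect_equal(suppressWarnings(energy_residual_adjust(intakes, rep(2000, 4))),
               intakes, tolerance = 1e-12)

  # exact linear dependence on energy collapses to the value at standard
  energy <- c(1700, 1900, 2100, 2300)
  intake <- 1.0 + 0.001 * (energy - 2000)
  expect_equal(energy_residual_adjust(intake, energy, age_group = "20-74"),
               rep(1, 4), tolerance = 1e-12)
  # elderly standard evaluates the same line at 1700 kcal
  expect_equal(energy_residual_adjust(intake, energy, age_group = "75+"),
               rep(1 + 0.001 * (1700 - 2000), 4), tolerance = 1e-12)

  # constant energy: slope undefined, warn and return unchanged
  expect_warning(out <- energy_residual_adjust(intakes, rep(2000, 4)),
                 "constant energy")
  expect_identical(out, intakes)

  expect_error(energy_residual_adjust(1:2, 1:3), "equal length")
  expect_error(energy_residual_adjust(1:2, c(2000, 2100)), "at least 3")
  expect_error(energy_residual_adjust(intakes, c(-1, 2000, 2100, 2200)), "> 0")

  # mean of adjusted values equals the prediction at standard energy
  set.seed(1)
  e <- rnorm(50, 2000, 250)
  y <- 3 + 0.002 * e + rnorm(50, 0, 0.5)
  adj <- energy_residual_adjust(y, e, age_group = "20-74")
  fit <- lm(y ~ e)
  expect_equal(mean(adj), unname(predict(fit, data.frame(e = 2000))),
               tolerance = 1e-9)

  # when intake is uncorrelated with energy the ranking is untouched
  y0 <- residuals(lm(rnorm(50, 4) ~ e)) + 4
  adj0 <- energy_residual_adjust(y0, e, age_group = "20-74")
  expect_identical(order(adj0), order(y0))
})

test_that("AME disaggregation is proportional and conserving", {
  one <- tibble::tibble(age_group = "30-34", sex = "male")
  expect_equal(ame_disaggregate(7, one), 7)

  req <- tibble::tibble(age_group = c("30-34", "10-14"),
                        sex = c("male", "female"),
                        kcal_day = c(2000, 1000))
  two <- tibble::tibble(age_group = c("30-34", "10-14"),
                        sex = c("male", "female"))
  expect_equal(ame_disaggregate(9, two, req), c(6, 3), tolerance = 1e-12)

  expect_error(ame_disaggregate(-1, one), ">= 0")
  expect_error(ame_disaggregate(5, one[0, ]), "non-empty")
  missing <- tibble::tibble(age_group = "30-34", sex = "other")
  expect_error(ame_disaggregate(5, missing), "no energy requirement")
})

test_that("stratum summarization averages days first, then participants", {
  d5 <- survey_design("24HR", "national", n_per_stratum = 1, days = 2)
  rec <- tibble::tibble(
    survey_id = "S1", record_type = "individual", household_id = NA_character_,
    participant_id = c("p1", "p1"), country = "C01", year = 2018L,
    age_group = "20-24", sex = "female", education = "low",
    urbanicity = "rural", day = 1:2, intake = c(0, 14),
    energy_kcal = NA_real_, household_total = NA_real_
  )
  obs <- summarize_to_strata(rec, d5)
  expect_equal(obs$mean, 7)
  expect_identical(obs$n, 1L)

  rec2 <- dplyr::bind_rows(rec, transform(rec, participant_id = "p2",
                                          intake = c(2, 6)))
  obs2 <- summarize_to_strata(rec2, d5)
  expect_equal(obs2$mean, (7 + 4) / 2)
  expect_equal(obs2$sd, sd(c(7, 4)), tolerance = 1e-12)
  expect_identical(obs2$n, 2L)

  # two participants with means 2 and 4: sd = sqrt(2)
  rec3 <- rec2
  rec3$intake <- c(2, 2, 4, 4)
  obs3 <- summarize_to_strata(rec3, d5)
  expect_equal(obs3$mean, 3)
  expect_equal(obs3$sd, sqrt(2), tolerance = 1e-12)

  expect_error(summarize_to_strata(rec[0, ], d5), "zero participants")
})

test_that("pooled dimensions are carried as flagged coarse cells", {
  w <- generate_world(world_config(n_regions = 1, countries_per_region = 1,
                                   years = 2018), seed = 2)
  d <- survey_design("FFQ", "national", report_sex = FALSE,
                     n_per_stratum = 4, person_cv = 0, energy_cv = 0)
  rec <- simulate_survey(w, d, "C01", 2018, seed = 4)
  obs <- summarize_to_strata(rec, d)
  expect_true(all(obs$sex == "all"))
  expect_true(all(obs$pooled_sex))
  expect_false(any(obs$pooled_education))
  # one reported cell per (band x education x urbanicity)
  expect_identical(nrow(obs), 16L * 3L * 2L)
})

test_that("plausibility screening partitions with reason codes", {
  obs <- toy_obs(sprintf("S%d", 1:10), "C01", 2018, mean = rep(3, 10))
  obs$mean[c(2, 5)] <- c(-1, 80)
  obs$n[9] <- 0L
  out <- qc_screen(obs)
  expect_identical(nrow(out$kept) + nrow(out$rejected), 10L)
  expect_identical(nrow(out$rejected), 3L)
  expect_setequal(out$rejected$reason,
                  c("negative_mean", "implausible_mean", "invalid_n"))
  clean <- qc_screen(toy_obs("S1", "C01", 2018, 3))
  expect_identical(nrow(clean$rejected), 0L)
})

test_that("85+ collapse is a draw-wise weighted mean", {
  expect_equal(collapse_85plus(c(3.9, 3.9, 3.9), c(1, 1, 1)), 3.9)
  expect_equal(collapse_85plus(c(4, 2, 1), c(0.6, 0.3, 0.1)), 3.1,
               tolerance = 1e-12)
  expect_error(collapse_85plus(c(1, 2, 3), c(0, 0, 0)), "positive sum")

  set.seed(7)
  draws <- matrix(rexp(3 * 100), 3, 100)
  wts <- c(0.5, 0.3, 0.2)
  got <- collapse_85plus(draws, wts)
  expect_equal(got, as.numeric(wts %*% draws), tolerance = 1e-12)
  # collapsing then summarizing equals summarizing then collapsing only
  # for draw-wise constant inputs
  const <- matrix(rep(c(4, 2, 1), 100), 3, 100)
  med_after <- summarize_draws(collapse_85plus(const, wts))[["median"]]
  med_before <- collapse_85plus(apply(const, 1, median), wts)
  expect_equal(med_after, med_before, tolerance = 1e-12)
})

test_that("noiseless harmonization reproduces the true surface", {
  w <- generate_world(world_config(n_regions = 1, countries_per_region = 1,
                                   years = 2018), seed = 6)
  d <- survey_design("FFQ", "national", n_per_stratum = 3, person_cv = 0,
                     energy_cv = 0)
  scen <- tibble::tibble(survey_id = "S1", country = "C01", year = 2018L,
                         kind = "ffq", design = list(d))
  col <- simulate_survey_collection(w, scen, seed = 6)
  obs <- harmonize_surveys(col)$kept
  truth <- true_stratum_mean(w, tibble::tibble(
    country = obs$country, year = obs$year,
    age_group = age_bands()[obs$age_lo], sex = obs$sex,
    education = obs$education, urbanicity = obs$urbanicity
  ))
  expect_lt(max(abs(obs$mean - truth)), 1e-9)
})
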