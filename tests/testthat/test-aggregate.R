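mk_draws <- function(idx, draws) {
  structure(list(index = idx, draws = draws, n_draws = ncol(draws)),
            class = "posterior_draws")
}

two_strata <- function() {
  idx <- tibble::tibble(country = "C01", year = 2018L, age_group = "20-24",
                        sex = c("female", "male"), education = "low",
                        urbanicity = "rural")
  list(idx = idx, pd = mk_draws(idx, rbind(rep(2, 100), rep(4, 100))))
}

test_that("population weighting renormalizes within scope", {
  ts <- two_strata()
  wts <- ts$idx
  wts$population <- c(1, 1)
  expect_equal(aggregate_weighted(ts$pd, wts), rep(3, 100))
  wts$population <- c(0.75, 0.25)
  expect_equal(aggregate_weighted(ts$pd, wts), rep(2.5, 100))
  wts$population <- c(0, 0)
  expect_error(aggregate_weighted(ts$pd, wts), "zero")
  expect_error(aggregate_weighted(ts$pd, ts$idx[1, ] |>
                                    dplyr::mutate(population = 1)),
               "do not cover")
})

test_that("aggregation is linear: region-of-country equals direct global", {
  set.seed(3)
  idx <- stratum_grid(c("C01", "C02", "C03"), 2018L)
  draws <- matrix(rexp(nrow(idx) * 30), nrow(idx), 30)
  pd <- mk_draws(idx, draws)
  wts <- idx
  wts$population <- runif(nrow(idx), 1, 100)
  direct <- aggregate_weighted(pd, wts)
  by_country <- sapply(c("C01", "C02", "C03"), function(ct) {
    aggregate_weighted(pd, wts, list(country = ct))
  })
  pop_c <- sapply(c("C01", "C02", "C03"), function(ct) {
    sum(wts$population[wts$country == ct])
  })
  composed <- as.numeric(by_country %*% (pop_c / sum(pop_c)))
  expect_lt(max(abs(direct - composed)), 1e-10)
})

test_that("draw summaries use interpolated percentiles with ordered bounds", {
  expect_equal(summarize_draws(rep(2.5, 10)),
               c(median = 2.5, lo95 = 2.5, hi95 = 2.5))
  s <- summarize_draws(1:4000)
  expect_equal(unname(s["median"]), 2000.5)
  expect_equal(unname(s["lo95"]), unname(quantile(1:4000, 0.025)))
  set.seed(1)
  x <- rnorm(4000)
  s2 <- summarize_draws(x)
  expect_lt(abs(s2[["median"]]), 0.1)
  expect_true(s2[["lo95"]] <= s2[["median"]] &
                s2[["median"]] <= s2[["hi95"]])
  expect_error(summarize_draws(numeric(0)), "2 finite")
  expect_error(summarize_draws(c(1, NA)), "2 finite")
})

test_that("temporal changes are additive under fixed standardization weights", {
  idx <- stratum_grid("C01", 1990L)
  S <- nrow(idx)
  set.seed(5)
  d90 <- matrix(rexp(S * 40), S, 40)
  d05 <- d90 + matrix(rnorm(S * 40, 0.2, 0.1), S, 40)
  d18 <- d05 + matrix(rnorm(S * 40, 0.15, 0.1), S, 40)
  wts <- stratum_grid("C01", 2018L)
  wts$population <- runif(S, 1, 50)
  mk_y <- function(d, yr) {
    ix <- idx
    ix$year <- yr
    mk_draws(ix, d)
  }
  c_90_05 <- change_estimate(mk_y(d90, 1990L), mk_y(d05, 2005L), wts)
  c_05_18 <- change_estimate(mk_y(d05, 2005L), mk_y(d18, 2018L), wts)
  c_90_18 <- change_estimate(mk_y(d90, 1990L), mk_y(d18, 2018L), wts)
  # draw-wise additivity of chained changes under fixed weights
  expect_lt(max(abs(attr(c_90_05, "draws") + attr(c_05_18, "draws") -
                      attr(c_90_18, "draws"))), 1e-12)

  same <- change_estimate(mk_y(d90, 1990L), mk_y(d90, 2018L), wts)
  expect_equal(unname(same$absolute), 0)
  expect_equal(unname(same$percent), 0)
  expect_false(same$significant)

  mism <- mk_y(d05[S:1, ], 2005L)
  mism$index$sex <- rev(mism$index$sex)
  expect_error(change_estimate(mk_y(d90, 1990L), mism, wts), "do not match")
})

test_that("subgroup differences are symmetric and match brute force", {
  idx <- stratum_grid("C01", 2018L)
  set.seed(6)
  draws <- matrix(rexp(nrow(idx) * 60), nrow(idx), 60)
  pd <- mk_draws(idx, draws)
  wts <- idx
  wts$population <- runif(nrow(idx), 1, 10)
  male <- posterior_predict(pd, idx[idx$sex == "male", ])
  female <- posterior_predict(pd, idx[idx$sex == "female", ])
  diff_mf <- subgroup_difference(male, female, wts)
  diff_fm <- subgroup_difference(female, male, wts)
  expect_equal(diff_mf$absolute, -diff_fm$absolute, tolerance = 1e-12)
  expect_identical(diff_mf$significant, diff_fm$significant)

  vm <- aggregate_weighted(male, wts)
  vf <- aggregate_weighted(female, wts)
  expect_equal(unname(diff_mf$absolute),
               unname(summarize_draws(vm - vf)["median"]), tolerance = 1e-12)

  ident <- subgroup_difference(male, male, wts)
  expect_equal(unname(ident$absolute), 0)
  expect_false(ident$significant)

  shifted <- male
  shifted$draws <- male$draws + 1
  d1 <- subgroup_difference(shifted, male, wts)
  expect_equal(unname(d1$absolute), 1, tolerance = 1e-12)
  expect_true(d1$significant)

  partial <- posterior_predict(pd, idx[c(1:10, which(idx$sex == "male")[1:5]), ])
  expect_error(subgroup_difference(partial, male, wts), "overlap")
})

test_that("threshold counting reports percentages at one decimal", {
  est <- tibble::tibble(country = c("A", "B", "C", "D"),
                        median = c(8, 9, 1, 2))
  pops <- tibble::tibble(country = est$country, population = rep(1, 4))
  th <- threshold_countries(est, pops)
  expect_identical(th$count, 2L)
  expect_equal(th$pct_of_countries, 50.0)
  expect_equal(th$population_share, 0.5)
  expect_identical(threshold_countries(est, pops, threshold = 0)$count, 4L)
  expect_error(threshold_countries(est, pops[3:4, ]), "missing population")
})

test_that("SDI correlation handles perfect and degenerate relations", {
  expect_equal(sdi_correlation(1:5, 2 * (1:5) + 3)$r, 1, tolerance = 1e-12)
  expect_equal(sdi_correlation(1:5, -(1:5))$r, -1, tolerance = 1e-12)
  expect_error(sdi_correlation(1:5, rep(1, 5)), "zero variance")
  expect_error(sdi_correlation(1:2, 1:2), "length >= 3")
  set.seed(2)
  x <- rnorm(10)
  y <- rnorm(10)
  ct <- cor.test(x, y)
  got <- sdi_correlation(x, y)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(got$p, ct$p.value, tolerance = 1e-12)
})

test_that("the adult reporting grid collapses 85+ by population, draw-wise", {
  idx <- stratum_grid("C01", 2018L)
  set.seed(4)
  draws <- matrix(rexp(nrow(idx) * 30), nrow(idx), 30)
  pd <- mk_draws(idx, draws)
  wts <- idx
  wts$population <- runif(nrow(idx), 1, 100)
  rd <- collapse_reporting_grid(pd, wts)
  expect_setequal(unique(rd$index$age_group), reporting_age_bands())
  expect_identical(nrow(rd$index), 14L * 12L)
  # check one collapsed cell against a direct weighted mean
  sel <- which(idx$sex == "male" & idx$education == "high" &
                 idx$urbanicity == "urban" &
                 idx$age_group %in% c("85-89", "90-94", "95+"))
  out_row <- which(rd$index$age_group == "85+" & rd$index$sex == "male" &
                     rd$index$education == "high" &
                     rd$index$urbanicity == "urban")
  w <- wts$population[sel] / sum(wts$population[sel])
  expect_equal(rd$draws[out_row, ], as.numeric(w %*% draws[sel, ]),
               tolerance = 1e-12)
  pop_out <- attr(rd, "population")
  expect_equal(pop_out$population[out_row], sum(wts$population[sel]))
})
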