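#' Fit the varying-slopes covariate trend model
#'
#' Hierarchical regression of log country-year mean intake on a
#' standardized beverage-availability covariate, with country-specific
#' intercepts and slopes drawn from a pooled bivariate distribution whose
#' correlation is estimated across countries (two-dimensional partial
#' pooling). Time is captured only through the covariate's variation; no
#' explicit time term is included. Countries present in the covariate
#' table but without an observed series still receive intercept/slope
#' draws from the pooled distribution, so trends can be predicted for
#' them with appropriately wider uncertainty.
#'
#' @param country_series Tibble with `country`, `year`, `mean` (observed
#'   country-year mean intake, servings/week). At least one country must
#'   contribute two or more time points, otherwise the slope is
#'   unidentifiable and the fit errors.
#' @param covariate_series Complete tibble with `country`, `year`,
#'   `availability` (> 0); z-scored on the log scale before fitting.
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @param slope_sd_scale Scale of the half-Normal prior on the pooled
#'   slope SD; shrinking it toward zero drives all country slopes to the
#'   common slope.
#' @param max_retries On a convergence failure, refit up to this many
#'   times with doubled chain lengths.
#' @return A `trend_fit` object with per-country `alpha` (intercept) and
#'   `slope` draw matrices, pooled `rho` draws, and the covariate table.
#' @export
fit_trend_model <- function(country_series, covariate_series,
                            config = model_config(), seed = 1L,
                            slope_sd_scale = 1, max_retries = 0L) {
  # the trend model is tiny (one point per country-year), so generous
  # chain lengths cost little and keep sparse countries well mixed
  config <- model_config(
    n_draws = config$n_draws, chains = config$chains,
    adapt = max(config$adapt, 1000), burnin = max(config$burnin, 5000),
    min_iter_per_chain = max(config$min_iter_per_chain, 5000),
    prior_sd = config$prior_sd, rhat_threshold = config$rhat_threshold,
    rel_se_floor = config$rel_se_floor
  )
  if (max_retries > 0) {
    return(retry_convergence(
      function(cfg) fit_trend_model(country_series, covariate_series, cfg,
                                    seed, slope_sd_scale, max_retries = 0L),
      config, max_retries
    ))
  }
  tp <- table(country_series$country)
  if (all(tp < 2)) {
    stop("every country has a single time point: slope unidentifiable")
  }
  covariate_series <- covariate_series[, c("country", "year", "availability")]
  lc <- log(covariate_series$availability)
  center <- mean(lc)
  scale <- if (length(lc) > 1 && stats::sd(lc) > 0) stats::sd(lc) else 1
  covariate_series$z <- (lc - center) / scale

  countries <- sort(unique(covariate_series$country))
  i <- match(paste(country_series$country, country_series$year),
             paste(covariate_series$country, covariate_series$year))
  if (anyNA(i)) stop("covariate series incomplete for observed country-years")

  data <- list(
    y = log(pmax(country_series$mean, 1e-6)),
    x = covariate_series$z[i],
    ctry = match(country_series$country, countries),
    N = nrow(country_series), C = length(countries),
    slope_sd_scale = slope_sd_scale,
    sigma_floor = config$rel_se_floor
  )
  params <- c("mu_a", "mu_b", "sigma_a", "sigma_b", "rho", "sigma_e",
              "alpha", "slope")
  sims <- run_jags(jags_file("trend_model.jags"), data, params, config, seed)
  pd <- sims$draws
  structure(
    list(
      countries = countries,
      alpha = node_matrix(pd, "alpha", length(countries)),
      slope = node_matrix(pd, "slope", length(countries)),
      rho = pd[, "rho"],
      pooled = pd[, c("mu_a", "mu_b", "sigma_a", "sigma_b", "sigma_e")],
      covariates = covariate_series,
      covariate_scaling = c(center = center, scale = scale),
      n_draws = nrow(pd)
    ),
    class = "trend_fit", diagnostics = sims$rhat, seed = as.integer(seed)
  )
}

#' Project a trend fit onto the stratum grid
#'
#' The trend model lives at the country-year level; to compare and
#' combine it with the primary model's stratum draws, each country-year's
#' trend level `exp(alpha + slope * z)` is distributed over strata using
#' the primary model's (draw-wise) demographic pattern: stratum draws are
#' the primary draws rescaled so the population-weighted country-year
#' level matches the trend model's level.
#'
#' The projected level is a prediction for the country-year's actual
#' level, so it includes the regression's residual SD (draw-wise): without
#' it the trend draws would claim regression-line precision and dominate
#' the inverse-variance combination.
#'
#' @param fit A `trend_fit`.
#' @param primary A `posterior_draws` object from [fit_intake_model()]
#'   with the same number of draws.
#' @param population A population table covering the grid (key columns +
#'   `population`).
#' @param seed Integer seed for the residual prediction draws.
#' @return A `posterior_draws` object on the same index as `primary`.
#' @export
trend_stratum_draws <- function(fit, primary, population, seed = 1L) {
  stopifnot(inherits(fit, "trend_fit"), inherits(primary, "posterior_draws"))
  if (fit$n_draws != primary$n_draws) {
    stop("trend and primary fits carry different numbers of draws")
  }
  idx <- primary$index
  pop <- population$population[match(
    do.call(paste, idx[, stratum_key_cols()]),
    do.call(paste, population[, stratum_key_cols()])
  )]
  if (anyNA(pop)) stop("population table does not cover the draw index")

  cy <- paste(idx$country, idx$year)
  groups <- split(seq_len(nrow(idx)), cy)
  zt <- fit$covariates$z[match(names(groups),
                               paste(fit$covariates$country, fit$covariates$year))]
  if (anyNA(zt)) stop("covariate series does not cover the draw index")
  ci <- match(sub(" .*", "", names(groups)), fit$countries)

  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, "trend_project"))
  on.exit(restore_rng(old), add = TRUE)
  sigma_e <- fit$pooled[, "sigma_e"]
  out <- primary$draws
  adult <- age_band_index(idx$age_group) >= 7
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    # the observed series is an adult survey mean, so the primary level
    # is matched on the adult (20+) slice; the rescaling then applies to
    # the whole country-year
    arows <- rows[adult[rows]]
    if (!length(arows)) arows <- rows
    w <- pop[arows]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(arows), length(arows))
    level_primary <- as.numeric(crossprod(w, primary$draws[arows, , drop = FALSE]))
    eps <- stats::rnorm(fit$n_draws, 0, sigma_e)
    level_trend <- exp(fit$alpha[ci[g], ] + fit$slope[ci[g], ] * zt[g] + eps)
    ratio <- level_trend / pmax(level_primary, 1e-12)
    out[rows, ] <- sweep(primary$draws[rows, , drop = FALSE], 2, ratio, `*`)
  }
  structure(list(index = idx, draws = out, n_draws = primary$n_draws),
            class = "posterior_draws")
}

#' Combine the primary and trend models' draws
#'
#' Draw-wise convex combination of the two models' stratum means. The
#' default rule weights each model per stratum by the inverse of its draw
#' variance; an equal-weight rule is available behind the `rule` flag.
#' Degenerate cases: a model with zero draw variance for a stratum takes
#' all the weight there; if both variances are zero the models are
#' averaged equally.
#'
#' @param primary,trend `posterior_draws` objects with identical stratum
#'   indices and draw counts.
#' @param rule `"inverse_variance"` (default) or `"equal"`.
#' @return A `posterior_draws` object; each combined draw lies between
#'   the two input draws.
#' @export
combine_draws <- function(primary, trend,
                          rule = c("inverse_variance", "equal")) {
  rule <- match.arg(rule)
  stopifnot(inherits(primary, "posterior_draws"),
            inherits(trend, "posterior_draws"))
  if (primary$n_draws != trend$n_draws ||
      !identical(do.call(paste, primary$index), do.call(paste, trend$index))) {
    stop("primary and trend draws have mismatched indices or draw counts")
  }
  if (rule == "equal") {
    w1 <- rep(0.5, nrow(primary$draws))
  } else {
    v1 <- apply(primary$draws, 1, stats::var)
    v2 <- apply(trend$draws, 1, stats::var)
    w1 <- ifelse(v1 <= 0 & v2 <= 0, 0.5,
                 ifelse(v1 <= 0, 1, ifelse(v2 <= 0, 0, (1 / v1) / (1 / v1 + 1 / v2))))
  }
  comb <- primary$draws * w1 + trend$draws * (1 - w1)
  structure(list(index = primary$index, draws = comb,
                 n_draws = primary$n_draws),
            class = "posterior_draws", weights_primary = w1, rule = rule)
}

#' Observed country-year mean series for the trend model
#'
#' Builds the country-year series the trend model is fitted to: the
#' sample-size-weighted mean of a country-year's screened survey-stratum
#' observations.
#'
#' @param observations A screened observation tibble.
#' @return Tibble with `country`, `year`, `mean`, `n_obs`.
#' @export
country_year_series <- function(observations) {
  dplyr::summarise(
    dplyr::group_by(observations, .data$country, .data$year),
    mean = stats::weighted.mean(.data$mean, .data$n),
    n_obs = dplyr::n(), .groups = "drop"
  )
}
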