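#' Configuration of the hierarchical intake model
#'
#' @param n_draws Total posterior draws returned (default 4000). Test and
#'   scaled-down configurations may reduce this.
#' @param chains Number of MCMC chains.
#' @param adapt,burnin Adaptation and burn-in iterations per chain.
#' @param min_iter_per_chain Minimum sampling iterations per chain (the
#'   returned draws are an even thinning of these); keeping this above
#'   the per-chain share of `n_draws` stabilizes the convergence
#'   diagnostic.
#' @param prior_sd SD of the weakly-informative Normal priors on
#'   log-scale fixed effects (sex, education, urbanicity, covariate).
#' @param rhat_threshold Maximum allowed split-chain potential scale
#'   reduction factor; the fit errors above it.
#' @param rel_se_floor Floor on an observation's relative standard
#'   error, guarding against degenerate zero-variance likelihoods (e.g.
#'   noiseless simulations).
#' @return A list of class `ssb_model_config`.
#' @export
model_config <- function(n_draws = 4000, chains = 2, adapt = 500,
                         burnin = 2000, min_iter_per_chain = 2000,
                         prior_sd = 1, rhat_threshold = 1.05,
                         rel_se_floor = 0.01) {
  structure(
    list(n_draws = as.integer(n_draws), chains = as.integer(chains),
         adapt = as.integer(adapt), burnin = as.integer(burnin),
         min_iter_per_chain = as.integer(min_iter_per_chain),
         prior_sd = prior_sd, rhat_threshold = rhat_threshold,
         rel_se_floor = rel_se_floor),
    class = "ssb_model_config"
  )
}

#' Assemble model inputs from screened observations
#'
#' Links every observation to the set of fine grid strata it covers
#' (coarse observations are matched against the population-weighted
#' average of the fine strata they span rather than being split), tags
#' each observation with its overdispersion class, and standardizes the
#' country-year covariate.
#'
#' An observation is flagged for variance inflation if it is not
#' nationally representative, reports age bands wider than 10 years, or
#' pools any of sex, education, or urbanicity.
#'
#' @param observations Screened survey-stratum observations (see
#'   [summarize_to_strata()] and [qc_screen()]).
#' @param grid The full stratum grid: key columns plus `population` and
#'   `region`.
#' @param covariates A complete country-year covariate table with a
#'   positive `availability` column (z-scored on the log scale here).
#' @param config A [model_config()].
#' @return A list of class `ssb_model_inputs`.
#' @export
assemble_inputs <- function(observations, grid, covariates,
                            config = model_config()) {
  stopifnot(all(c("region", "population") %in% names(grid)))
  bad <- setdiff(unique(observations$country), unique(grid$country))
  if (length(bad)) {
    stop("observation references country absent from grid: ",
         paste(bad, collapse = ", "))
  }
  miss <- dplyr::anti_join(dplyr::distinct(grid, .data$country, .data$year),
                           covariates, by = c("country", "year"))
  if (nrow(miss)) {
    stop("covariates incomplete: missing ",
         paste(paste(miss$country, miss$year), collapse = ", "))
  }
  covariates <- covariates[, c("country", "year", "availability")]
  lc <- log(covariates$availability)
  center <- mean(lc)
  scale <- if (length(lc) > 1 && stats::sd(lc) > 0) stats::sd(lc) else 1
  covariates$z <- (lc - center) / scale

  grid <- stratum_arrange(grid)

  observations$overdispersed <-
    observations$representativeness != "national" |
    age_range_width(observations$age_lo, observations$age_hi) > 10 |
    observations$pooled_sex | observations$pooled_education |
    observations$pooled_urbanicity

  coverage <- vector("list", nrow(observations))
  for (j in seq_len(nrow(observations))) {
    o <- observations[j, ]
    band <- age_band_index(grid$age_group)
    sel <- which(
      grid$country == o$country & grid$year == o$year &
        band >= o$age_lo & band <= o$age_hi &
        (o$sex == "all" | grid$sex == o$sex) &
        (o$education == "all" | grid$education == o$education) &
        (o$urbanicity == "all" | grid$urbanicity == o$urbanicity)
    )
    if (!length(sel)) {
      stop("observation ", j, " covers no grid strata")
    }
    w <- grid$population[sel]
    w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(sel), length(sel))
    coverage[[j]] <- list(idx = sel, w = w)
  }

  structure(
    list(observations = observations, coverage = coverage, grid = grid,
         countries = dplyr::distinct(grid, .data$country, .data$region),
         covariates = covariates,
         covariate_scaling = c(center = center, scale = scale),
         config = config),
    class = "ssb_model_inputs"
  )
}

# Observation variances for the likelihood. Weighting each cell by its
# own estimated sd biases pooled means downward on skewed intake data
# (sample mean and sd are positively correlated), so each survey's cells
# share the survey's pooled per-participant relative variance, referenced
# to a smoothed plug-in cell mean (a per-survey additive log-linear OLS
# fit) rather than the cell's own noisy mean.
observation_variances <- function(obs, config) {
  rel2_obs <- ifelse(obs$mean > 0, (obs$sd / obs$mean)^2, NA_real_)
  rel2_surv <- tapply(rel2_obs, obs$survey_id, stats::median, na.rm = TRUE)
  rel2_surv[!is.finite(rel2_surv)] <- 0
  smoothed <- obs$mean
  for (sid in unique(obs$survey_id)) {
    sel <- which(obs$survey_id == sid)
    if (length(sel) >= 8) {
      d <- obs[sel, ]
      d$ly <- log(pmax(d$mean, 1e-3))
      fit <- try(stats::lm(ly ~ factor(age_lo) + sex + education + urbanicity,
                           data = d), silent = TRUE)
      if (!inherits(fit, "try-error")) {
        smoothed[sel] <- exp(stats::fitted(fit))
      }
    } else if (any(obs$mean[sel] > 0)) {
      smoothed[sel] <- mean(obs$mean[sel])
    }
  }
  pmax(unname(rel2_surv[obs$survey_id]) / obs$n * smoothed^2,
       (config$rel_se_floor * pmax(smoothed, 1e-3))^2)
}

jags_file <- function(name) {
  f <- system.file("jags", name, package = "ssbpool")
  if (!nzchar(f)) f <- file.path("inst", "jags", name) # pre-install fallback
  f
}

#' Fit the nested hierarchical Bayesian intake model
#'
#' Pools all survey-stratum observations into posterior draws of mean
#' intake for every stratum of every country-year in the grid, including
#' countries with no surveys (their country effects are drawn from the
#' region-level distribution, so they borrow strength from the hierarchy
#' and carry wider uncertainty). The observed stratum mean is modeled as
#' Normal around the model mean of the covered cell(s) with variance
#' `sd^2/n`, inflated by `exp(overdispersion effect)` for flagged
#' observations; the model mean is log-additive with no demographic
#' interactions. Split-chain R-hat must stay below the configured
#' threshold or the fit errors with diagnostics attached.
#'
#' @param inputs An [assemble_inputs()] object.
#' @param config A [model_config()]; defaults to the configuration stored
#'   in `inputs`.
#' @param seed Integer seed; together with the backend it fully
#'   determines the draws.
#' @param max_retries On a convergence failure, refit up to this many
#'   times with doubled burn-in and sampling lengths (deterministic for
#'   a fixed seed) before giving up.
#' @return A `posterior_draws` object: `index` (the full stratum grid),
#'   `draws` (strata x draws matrix, servings/week), `n_draws`, plus
#'   parameter draws and convergence diagnostics in attributes.
#' @export
fit_intake_model <- function(inputs, config = NULL, seed = 1L,
                             max_retries = 0L) {
  stopifnot(inherits(inputs, "ssb_model_inputs"))
  config <- config %||% inputs$config
  if (max_retries > 0) {
    return(retry_convergence(
      function(cfg) fit_intake_model(inputs, cfg, seed, max_retries = 0L),
      config, max_retries
    ))
  }
  obs <- inputs$observations
  if (nrow(obs) == 0) stop("no observations: the model requires at least one")

  grid <- inputs$grid
  countries <- inputs$countries
  regions <- sort(unique(countries$region))

  # strata actually referenced by observations (the likelihood support)
  need <- sort(unique(unlist(lapply(inputs$coverage, `[[`, "idx"))))
  smap <- match(seq_len(nrow(grid)), need) # grid row -> needed index
  zcov <- inputs$covariates$z[match(
    paste(grid$country, grid$year),
    paste(inputs$covariates$country, inputs$covariates$year)
  )]

  maxk <- max(vapply(inputs$coverage, function(cv) length(cv$idx), integer(1)))
  J <- nrow(obs)
  idx <- matrix(1L, J, maxk)
  w <- matrix(0, J, maxk)
  for (j in seq_len(J)) {
    k <- length(inputs$coverage[[j]]$idx)
    idx[j, seq_len(k)] <- smap[inputs$coverage[[j]]$idx]
    w[j, seq_len(k)] <- inputs$coverage[[j]]$w
  }

  se2 <- observation_variances(obs, config)
  data <- list(
    y = obs$mean,
    prec_base = 1 / se2,
    infl = as.numeric(obs$overdispersed),
    w = w, idx = idx,
    J = J, S = length(need), A = 22L,
    R = length(regions), C = nrow(countries),
    region_of = match(countries$region, regions),
    ctry_s = match(grid$country[need], countries$country),
    age_s = age_band_index(grid$age_group[need]),
    male_s = as.numeric(grid$sex[need] == "male") - 0.5,
    edu_m_s = as.numeric(grid$education[need] == "medium") - 1 / 3,
    edu_h_s = as.numeric(grid$education[need] == "high") - 1 / 3,
    urban_s = as.numeric(grid$urbanicity[need] == "urban") - 0.5,
    z_s = zcov[need],
    prior_sd = config$prior_sd
  )

  params <- c("b0", "beta_cov", "b_sex", "b_urb", "b_edu_m", "b_edu_h",
              "sigma_r", "sigma_c", "sigma_a", "gamma_od",
              "r_eff", "c_eff", "a_age")
  inits <- moment_inits(obs, countries, regions, data$region_of)
  sims <- run_jags(jags_file("intake_model.jags"), data, params, config, seed,
                   inits_extra = inits)

  draws <- reconstruct_stratum_draws(sims$draws, grid, countries, regions, zcov)
  structure(
    list(index = grid[, stratum_key_cols()], draws = draws,
         n_draws = ncol(draws)),
    class = "posterior_draws",
    params = sims$draws, diagnostics = sims$rhat, seed = as.integer(seed),
    config = config
  )
}

# rerun a fit with progressively longer chains after convergence failures
retry_convergence <- function(fit_fun, config, max_retries) {
  for (try in 0:max_retries) {
    out <- tryCatch(fit_fun(config), ssbpool_convergence_error = identity)
    if (!inherits(out, "condition")) return(out)
    if (try == max_retries) stop(out)
    config <- utils::modifyList(config, list(
      burnin = 2L * config$burnin,
      min_iter_per_chain = 2L * config$min_iter_per_chain
    ))
    class(config) <- "ssb_model_config"
  }
}

# crude moment-based starting values: a pooled age curve from fine-band
# observations and per-country levels adjusted by it. Keeping all chains
# (with per-chain jitter) in the basin of the data-consistent mode
# matters because the overdispersion effect admits a spurious local mode
# in which the inflated class of surveys is ignored entirely.
moment_inits <- function(obs, countries, regions, region_of) {
  mid <- pmin(22L, (obs$age_lo + obs$age_hi) %/% 2L)
  a_init <- rep(NA_real_, 22)
  fine <- obs$age_lo == obs$age_hi
  if (any(fine)) {
    t_k <- tapply(obs$mean[fine], obs$age_lo[fine], mean)
  } else {
    t_k <- tapply(obs$mean, mid, mean)
  }
  a_init[as.integer(names(t_k))] <- log(pmax(t_k, 1e-3))
  ref <- if (is.finite(a_init[7])) a_init[7] else mean(a_init, na.rm = TRUE)
  a_init <- a_init - ref
  for (k in 8:22) if (!is.finite(a_init[k])) a_init[k] <- a_init[k - 1]
  for (k in 6:1) if (!is.finite(a_init[k])) a_init[k] <- a_init[k + 1]
  a_init[!is.finite(a_init)] <- 0

  adj <- log(pmax(obs$mean, 1e-3)) - a_init[mid]
  c_init <- rep(NA_real_, nrow(countries))
  cl <- tapply(adj, obs$country, mean)
  c_init[match(names(cl), countries$country)] <- cl
  c_init[!is.finite(c_init)] <- mean(cl)
  r_init <- as.numeric(tapply(c_init, region_of, mean))

  list(b0 = mean(r_init), r_eff = r_init, c_eff = c_init,
       a_age = replace(a_init, 7, NA), # anchored node carries no init
       b_sex = 0, b_urb = 0, b_edu_m = 0, b_edu_h = 0, beta_cov = 0,
       sigma_r = 0.3, sigma_c = 0.3, sigma_a = 0.3, gamma_od = 0.05)
}

# shared JAGS driver: compile, adapt, burn in, sample, check split R-hat,
# thin the kept chains to exactly n_draws rows
run_jags <- function(file, data, params, config, seed, inits_extra = NULL) {
  n_iter <- max(config$min_iter_per_chain,
                ceiling(config$n_draws / config$chains))
  inits <- lapply(seq_len(config$chains), function(ch) {
    base <- list(.RNG.name = "base::Mersenne-Twister",
                 .RNG.seed = derive_seed(seed, paste0("chain", ch)))
    if (is.null(inits_extra)) return(base)
    jit <- inits_extra
    set.seed(derive_seed(seed, paste0("jitter", ch)))
    for (nm in c("b0", "r_eff", "c_eff", "a_age")) {
      jit[[nm]] <- jit[[nm]] + stats::rnorm(length(jit[[nm]]), 0, 0.05)
    }
    jit$a_age[7] <- NA # deterministic anchor
    c(base, jit)
  })
  m <- rjags::jags.model(file, data = data, inits = inits,
                         n.chains = config$chains, n.adapt = config$adapt,
                         quiet = TRUE)
  stats::update(m, n.iter = config$burnin, progress.bar = "none")
  samp <- rjags::coda.samples(m, variable.names = params, n.iter = n_iter,
                              progress.bar = "none")
  chains <- lapply(samp, as.matrix)
  rhat <- split_rhat(chains)
  if (max(rhat, na.rm = TRUE) > config$rhat_threshold) {
    worst <- sort(rhat, decreasing = TRUE)[seq_len(min(5, length(rhat)))]
    rlang::abort(
      paste0("MCMC did not converge: max split R-hat ",
             sprintf("%.3f", max(rhat, na.rm = TRUE)), " > ",
             config$rhat_threshold, " (worst: ",
             paste(names(worst), sprintf("%.3f", worst), collapse = ", "), ")"),
      class = "ssbpool_convergence_error", diagnostics = rhat
    )
  }
  per_chain <- ceiling(config$n_draws / config$chains)
  kept <- lapply(chains, function(ch) {
    ch[floor(seq(1, nrow(ch), length.out = per_chain)), , drop = FALSE]
  })
  all <- do.call(rbind, kept)
  all <- all[seq_len(min(config$n_draws, nrow(all))), , drop = FALSE]
  list(draws = all, rhat = rhat)
}

# JAGS drops the bracket suffix for length-1 vector nodes
node_matrix <- function(pd, name, k) {
  cols <- if (k == 1 && name %in% colnames(pd)) name else
    sprintf("%s[%d]", name, seq_len(k))
  t(pd[, cols, drop = FALSE])
}

# rebuild mean-intake draws for the FULL grid from parameter draws
reconstruct_stratum_draws <- function(pd, grid, countries, regions, zcov) {
  D <- nrow(pd)
  col <- function(nm) pd[, nm]
  ci <- match(grid$country, countries$country)
  ai <- age_band_index(grid$age_group)
  male <- as.numeric(grid$sex == "male") - 0.5
  edu_m <- as.numeric(grid$education == "medium") - 1 / 3
  edu_h <- as.numeric(grid$education == "high") - 1 / 3
  urb <- as.numeric(grid$urbanicity == "urban") - 0.5

  c_eff <- node_matrix(pd, "c_eff", nrow(countries))
  a_age <- node_matrix(pd, "a_age", 22)

  eta <- c_eff[ci, , drop = FALSE] + a_age[ai, , drop = FALSE] +
    outer(male, col("b_sex")) + outer(edu_m, col("b_edu_m")) +
    outer(edu_h, col("b_edu_h")) +
    outer(urb, col("b_urb")) +
    outer(zcov, col("beta_cov"))
  exp(eta)
}

#' Subset posterior draws by stratum keys
#'
#' @param draws A `posterior_draws` object.
#' @param keys A data frame of stratum keys (a subset of `draws$index`);
#'   row order is preserved in the output.
#' @return A `posterior_draws` object restricted to `keys`.
#' @export
posterior_predict <- function(draws, keys) {
  stopifnot(inherits(draws, "posterior_draws"))
  ik <- do.call(paste, draws$index)
  kk <- do.call(paste, keys[, stratum_key_cols()])
  i <- match(kk, ik)
  if (anyNA(i)) {
    stop("unknown stratum key(s): ", paste(utils::head(kk[is.na(i)], 3), collapse = "; "))
  }
  structure(
    list(index = draws$index[i, , drop = FALSE],
         draws = draws$draws[i, , drop = FALSE], n_draws = draws$n_draws),
    class = "posterior_draws"
  )
}

#' Per-stratum posterior summaries
#'
#' @param draws A `posterior_draws` object.
#' @return The stratum index tibble with `median`, `lo95`, `hi95`
#'   columns (50th, 2.5th and 97.5th percentiles of the draws).
#' @export
stratum_estimates <- function(draws) {
  stopifnot(inherits(draws, "posterior_draws"))
  q <- t(apply(draws$draws, 1, stats::quantile,
               probs = c(0.5, 0.025, 0.975), names = FALSE))
  out <- tibble::as_tibble(draws$index)
  out$median <- q[, 1]
  out$lo95 <- q[, 2]
  out$hi95 <- q[, 3]
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("<posterior_draws> ", nrow(x$draws), " strata x ", x$n_draws,
      " draws\n", sep = "")
  invisible(x)
}

#' Sample stratum means from the hierarchical prior
#'
#' Draws from the model's prior predictive distribution of stratum mean
#' intake (no data involved), used to check that the posterior reduces to
#' the prior in the absence of informative observations.
#'
#' @param inputs An [assemble_inputs()] object (only the grid, covariates
#'   and config are used).
#' @param n Number of prior draws.
#' @param seed Integer seed.
#' @return A `posterior_draws` object over the grid.
#' @export
sample_prior <- function(inputs, n = 2000, seed = 1L) {
  stopifnot(inherits(inputs, "ssb_model_inputs"))
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_rng(old), add = TRUE)
  grid <- inputs$grid
  countries <- inputs$countries
  regions <- sort(unique(countries$region))
  ps <- inputs$config$prior_sd
  hn <- function(k) abs(stats::rnorm(k))
  b0 <- stats::rnorm(n, 0, 2)
  beta <- stats::rnorm(n, 0, ps)
  b_sex <- stats::rnorm(n, 0, ps)
  b_urb <- stats::rnorm(n, 0, ps)
  b_edu_m <- stats::rnorm(n, 0, ps)
  b_edu_h <- stats::rnorm(n, 0, ps)
  sigma_r <- hn(n); sigma_c <- hn(n); sigma_a <- hn(n)
  r_eff <- matrix(b0, length(regions), n, byrow = TRUE) +
    matrix(stats::rnorm(length(regions) * n, 0,
                        rep(sigma_r, each = length(regions))),
           length(regions), n)
  ri <- match(countries$region, regions)
  c_eff <- r_eff[ri, , drop = FALSE] +
    matrix(stats::rnorm(nrow(countries) * n, 0,
                        rep(sigma_c, each = nrow(countries))),
           nrow(countries), n)
  # RW1 age curve anchored at the 20-24 reference band
  a_age <- matrix(0, 22, n)
  for (k in 8:22) a_age[k, ] <- a_age[k - 1, ] + stats::rnorm(n, 0, sigma_a)
  for (k in 6:1) a_age[k, ] <- a_age[k + 1, ] + stats::rnorm(n, 0, sigma_a)

  zcov <- inputs$covariates$z[match(
    paste(grid$country, grid$year),
    paste(inputs$covariates$country, inputs$covariates$year)
  )]
  ci <- match(grid$country, countries$country)
  ai <- age_band_index(grid$age_group)
  eta <- c_eff[ci, , drop = FALSE] + a_age[ai, , drop = FALSE] +
    outer(as.numeric(grid$sex == "male") - 0.5, b_sex) +
    outer(as.numeric(grid$education == "medium") - 1 / 3, b_edu_m) +
    outer(as.numeric(grid$education == "high") - 1 / 3, b_edu_h) +
    outer(as.numeric(grid$urbanicity == "urban") - 0.5, b_urb) +
    outer(zcov, beta)
  structure(
    list(index = grid[, stratum_key_cols()], draws = exp(eta), n_draws = n),
    class = "posterior_draws"
  )
}
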