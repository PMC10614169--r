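#' Survey-level k-fold split
#'
#' Assigns whole surveys to folds (one survey's strata are never split
#' across folds), producing disjoint, exhaustive folds whose sizes differ
#' by at most one. Deterministic for a fixed seed.
#'
#' @param surveys Character vector of survey identifiers.
#' @param k Number of folds (default 5, i.e. omitting 20% of the surveys
#'   per fold).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments (1..k) named by survey.
#' @export
kfold_split <- function(surveys, k = 5, seed = 1L) {
  surveys <- unique(surveys)
  if (k < 2) stop("k must be at least 2")
  if (length(surveys) < k) stop("need at least k surveys")
  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, "kfold"))
  on.exit(restore_rng(old), add = TRUE)
  perm <- sample(surveys)
  folds <- rep(seq_len(k), length.out = length(perm))
  stats::setNames(folds[order(match(surveys, perm))], surveys)
}

#' Held-out prediction metrics
#'
#' @param predicted,observed Paired numeric vectors.
#' @return A list with `bias` (mean predicted minus observed), `rmse`,
#'   and Pearson `r` (reported as 1 when either vector is constant and
#'   the vectors are equal; `NA` when constant but unequal).
#' @export
cv_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  d <- predicted - observed
  r <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    if (all(abs(d) < 1e-12)) 1 else NA_real_
  } else {
    stats::cor(predicted, observed)
  }
  list(bias = mean(d), rmse = sqrt(mean(d^2)), r = r, n = length(d))
}

#' Five-fold survey-holdout cross-validation of the intake model
#'
#' For each fold, the model is refitted on the remaining surveys and used
#' to predict the held-out survey-stratum means (the population-weighted
#' model mean of the cells each held-out observation covers, at the
#' posterior median). Predictions outside the plausibility bounds are
#' excluded and counted. Metrics are reported per fold and pooled over
#' all held-out pairs. A fold whose removal would leave a region with no
#' observations at all is skipped with a warning and reported.
#'
#' @param observations Screened survey-stratum observations.
#' @param folds Fold assignments from [kfold_split()].
#' @param grid,covariates As for [assemble_inputs()].
#' @param config A [model_config()]; cross-validation typically runs in a
#'   scaled-down configuration (fewer draws per fold), which is recorded
#'   in the report.
#' @param seed Integer seed (per-fold child seeds are derived).
#' @param bounds Plausibility bounds for predictions, from [qc_rules()].
#' @return A `cv_report` list: per-fold metrics, pooled metrics, the
#'   excluded-implausible count, fold assignments and the configuration
#'   used.
#' @export
cv_evaluate <- function(observations, folds, grid, covariates,
                        config = model_config(n_draws = 500),
                        seed = 1L, bounds = qc_rules()) {
  k <- max(folds)
  per_fold <- vector("list", k)
  pooled_pred <- numeric(0)
  pooled_obs <- numeric(0)
  excluded <- 0L
  skipped <- integer(0)

  region_of_obs <- grid$region[match(observations$country, grid$country)]
  for (f in seq_len(k)) {
    hold_ids <- names(folds)[folds == f]
    train <- observations[!observations$survey_id %in% hold_ids, ]
    test <- observations[observations$survey_id %in% hold_ids, ]
    if (nrow(test) == 0) next
    train_regions <- unique(grid$region[match(train$country, grid$country)])
    if (!all(unique(region_of_obs) %in% train_regions)) {
      warning(sprintf("fold %d removal empties a region; fold skipped", f))
      skipped <- c(skipped, f)
      next
    }
    inp <- assemble_inputs(train, grid, covariates, config)
    fit <- fit_intake_model(inp, config,
                            seed = derive_seed(seed, paste0("cv", f)),
                            max_retries = 2L)
    med <- apply(fit$draws, 1, stats::median)
    gkey <- do.call(paste, fit$index)

    test_inp <- assemble_inputs(test, grid, covariates, config)
    pred <- vapply(seq_len(nrow(test)), function(j) {
      cv <- test_inp$coverage[[j]]
      rows <- match(do.call(paste, test_inp$grid[cv$idx, stratum_key_cols()]), gkey)
      sum(cv$w * med[rows])
    }, numeric(1))

    ok <- pred >= bounds$mean_min & pred <= bounds$mean_max
    excluded <- excluded + sum(!ok)
    m <- cv_metrics(pred[ok], test$mean[ok])
    per_fold[[f]] <- tibble::tibble(
      fold = f, n_heldout = nrow(test), n_used = sum(ok),
      bias = m$bias, rmse = m$rmse, r = m$r
    )
    pooled_pred <- c(pooled_pred, pred[ok])
    pooled_obs <- c(pooled_obs, test$mean[ok])
  }

  pooled <- cv_metrics(pooled_pred, pooled_obs)
  structure(
    list(per_fold = dplyr::bind_rows(per_fold), pooled = pooled,
         excluded_implausible = excluded, folds = folds,
         skipped_folds = skipped, n_draws = config$n_draws),
    class = "cv_report"
  )
}

#' Parameter-recovery report against a synthetic world
#'
#' Compares posterior estimates with the generator's known true surface:
#' stratum-level bias, RMSE, Pearson correlation and empirical 95% UI
#' coverage over the adult grid, and the same metrics for
#' population-weighted country-year adult means.
#'
#' @param world An `ssb_world`.
#' @param estimates Stratum estimates from [stratum_estimates()]
#'   covering the world's grid.
#' @return A `recovery_report` list with `stratum` and `country_year`
#'   metric blocks.
#' @export
recovery_report <- function(world, estimates) {
  truth <- world$grid
  key_t <- do.call(paste, truth[, stratum_key_cols()])
  key_e <- do.call(paste, estimates[, stratum_key_cols()])
  i <- match(key_t, key_e)
  if (anyNA(i)) stop("estimates do not cover the world's grid")
  est <- estimates[i, ]

  adult <- age_band_index(truth$age_group) >= 7
  s_bias <- mean(est$median[adult] - truth$true_mean[adult])
  s_rmse <- sqrt(mean((est$median[adult] - truth$true_mean[adult])^2))
  s_cor <- stats::cor(est$median[adult], truth$true_mean[adult])
  s_cov <- mean(truth$true_mean[adult] >= est$lo95[adult] &
                  truth$true_mean[adult] <= est$hi95[adult])

  cy <- dplyr::summarise(
    dplyr::group_by(
      tibble::tibble(country = truth$country[adult], year = truth$year[adult],
                     w = truth$population[adult],
                     true = truth$true_mean[adult], est = est$median[adult]),
      .data$country, .data$year
    ),
    true = stats::weighted.mean(.data$true, .data$w),
    est = stats::weighted.mean(.data$est, .data$w),
    .groups = "drop"
  )

  structure(
    list(
      stratum = list(bias = s_bias, rmse = s_rmse, correlation = s_cor,
                     coverage95 = s_cov, n = sum(adult)),
      country_year = list(
        bias = mean(cy$est - cy$true),
        rmse = sqrt(mean((cy$est - cy$true)^2)),
        correlation = stats::cor(cy$est, cy$true),
        n = nrow(cy)
      )
    ),
    class = "recovery_report"
  )
}

#' Check the uncertainty ordering between unsurveyed and well-surveyed countries
#'
#' Countries without any survey should carry wider uncertainty than
#' countries informed by two or more national surveys: this compares the
#' mean 95% UI width over adult strata between the two groups.
#'
#' @param estimates Stratum estimates from [stratum_estimates()].
#' @param manifest A survey manifest (columns `survey_id`, `country`,
#'   `representativeness`).
#' @return A list: `status` (`"ok"` when both groups exist, else
#'   `"inconclusive"`), `holds` (TRUE iff unsurveyed width strictly
#'   exceeds the well-surveyed width), and the two mean widths.
#' @export
uncertainty_ordering_check <- function(estimates, manifest) {
  n_national <- table(manifest$country[manifest$representativeness == "national"])
  surveyed_any <- unique(manifest$country)
  well <- names(n_national)[n_national >= 2]
  unsurveyed <- setdiff(unique(estimates$country), surveyed_any)
  adult <- age_band_index(estimates$age_group) >= 7
  width <- estimates$hi95 - estimates$lo95
  if (!length(unsurveyed) || !length(well)) {
    return(list(status = "inconclusive", holds = NA,
                width_unsurveyed = NA_real_, width_surveyed = NA_real_))
  }
  wu <- mean(width[adult & estimates$country %in% unsurveyed])
  ws <- mean(width[adult & estimates$country %in% well])
  list(status = "ok", holds = wu > ws,
       width_unsurveyed = wu, width_surveyed = ws)
}
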