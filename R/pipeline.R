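#' Pipeline configuration
#'
#' Bundles every constant and knob of an end-to-end run: the synthetic
#' world and scenario, the serving and energy conventions, the model
#' configuration, the model-combination rule, and the plausibility
#' bounds. The seed recorded here drives every stage.
#'
#' @param seed Master seed.
#' @param world A [world_config()].
#' @param coverage Fraction of country-years surveyed in the default
#'   scenario.
#' @param noise Noise multiplier for the scenario's survey designs.
#' @param n_per_stratum Participants per reported survey cell.
#' @param model A [model_config()].
#' @param serving A [serving_definition()] (reporting convention,
#'   248 g per 8 oz serving; 236.5 g request-time servings are accepted
#'   on input via [convert_serving_units()]).
#' @param energy An [energy_standard()].
#' @param combination_rule Rule for [combine_draws()].
#' @param rules Plausibility bounds from [qc_rules()].
#' @param scenario_name Free-text label recorded in the run log.
#' @return A list of class `ssb_pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            world = world_config(),
                            coverage = 0.6,
                            noise = 1,
                            n_per_stratum = 50,
                            model = model_config(n_draws = 500),
                            serving = serving_definition(),
                            energy = energy_standard(),
                            combination_rule = "inverse_variance",
                            rules = qc_rules(),
                            scenario_name = "default") {
  structure(
    list(seed = as.integer(seed), world = world, coverage = coverage,
         noise = noise, n_per_stratum = n_per_stratum, model = model,
         serving = serving, energy = energy,
         combination_rule = combination_rule, rules = rules,
         scenario_name = scenario_name),
    class = "ssb_pipeline_config"
  )
}

#' Run the full estimation pipeline
#'
#' Executes generate -> harmonize -> fit -> trend -> combine -> aggregate
#' -> validate on a synthetic world, writing every stage's table as CSV
#' with a provenance entry (stage, input checksums, seed) in the run log.
#' A failure in any stage halts the run with the stage name and cause.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results and the
#'   paths written.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("ssbrun")) {
  stopifnot(inherits(config, "ssb_pipeline_config"))
  for (field in c("seed", "world", "model", "serving", "energy", "rules")) {
    if (is.null(config[[field]])) {
      stop("pipeline config is missing required input: ", field)
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_line <- function(stage, msg) {
    cat(sprintf("[%s] %s: %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                stage, msg), file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  log_line("config", sprintf("seed=%d scenario=%s n_draws=%d rule=%s",
                             config$seed, config$scenario_name,
                             config$model$n_draws, config$combination_rule))

  world <- stage("generate", generate_world(config$world, config$seed))
  scenario <- stage("generate", default_scenario(
    world, coverage = config$coverage, seed = config$seed,
    noise = config$noise, n_per_stratum = config$n_per_stratum
  ))
  collection <- stage("generate",
                      simulate_survey_collection(world, scenario, config$seed))

  world_csv <- file.path(out_dir, "world.csv")
  write_table(world$grid, world_csv, schema_world())
  write_table(collection$manifest, file.path(out_dir, "manifest.csv"),
              schema_manifest())
  log_line("generate", sprintf("world %d strata, %d surveys; wrote %s",
                               nrow(world$grid), nrow(collection$manifest),
                               checksum(world_csv)))

  screened <- stage("harmonize",
                    harmonize_surveys(collection, config$energy, config$rules))
  obs <- screened$kept
  if (nrow(obs) == 0) stop("pipeline stage 'harmonize' failed: no observations kept")
  write_table(obs, file.path(out_dir, "observations.csv"), schema_observations())
  rej <- screened$rejected
  readr::write_csv(rej, file.path(out_dir, "rejections.csv"))
  log_line("harmonize", sprintf("%d observations kept, %d rejected",
                                nrow(obs), nrow(rej)))

  grid <- dplyr::left_join(world$grid, world$countries, by = "country")
  if (is.null(grid$population)) stop("pipeline config missing population table")
  inputs <- stage("fit", assemble_inputs(obs, grid, world$covariate,
                                         config$model))
  fit <- stage("fit", fit_intake_model(inputs, config$model, config$seed,
                                       max_retries = 2L))
  log_line("fit", sprintf("max split R-hat %.3f",
                          max(attr(fit, "diagnostics"), na.rm = TRUE)))

  trend <- stage("trend", fit_trend_model(
    country_year_series(obs), world$covariate, config$model, config$seed,
    max_retries = 2L
  ))
  trend_draws <- stage("trend",
                       trend_stratum_draws(trend, fit, world$grid,
                                           seed = config$seed))
  combined <- stage("combine",
                    combine_draws(fit, trend_draws, config$combination_rule))
  log_line("combine", sprintf("rule=%s", config$combination_rule))

  est <- stratum_estimates(combined)
  write_table(est, file.path(out_dir, "estimates.csv"), schema_estimates())

  report <- stage("aggregate", report_tables(combined, world))
  readr::write_csv(report$levels, file.path(out_dir, "report_levels.csv"))
  readr::write_csv(report$changes, file.path(out_dir, "report_changes.csv"))
  log_line("aggregate", sprintf("%d level rows, %d change rows",
                                nrow(report$levels), nrow(report$changes)))

  rec <- stage("validate", recovery_report(world, est))
  ord <- stage("validate",
               uncertainty_ordering_check(est, collection$manifest))
  log_line("validate", sprintf(
    "stratum rmse=%.3f cor=%.3f coverage=%.3f; uncertainty ordering=%s",
    rec$stratum$rmse, rec$stratum$correlation, rec$stratum$coverage95,
    ifelse(isTRUE(ord$holds), "holds", "violated/inconclusive")
  ))

  invisible(list(
    world = world, collection = collection, observations = obs,
    fit = fit, trend = trend, combined = combined, estimates = est,
    report = report, recovery = rec, uncertainty = ord, out_dir = out_dir
  ))
}

checksum <- function(path) unname(tools::md5sum(path))

#' Report tables for the adult grid
#'
#' Population-weighted adult (20+) estimates overall and by sex, age
#' band, education and residence for each region and year, plus a
#' changes table between consecutive and overall year pairs,
#' standardized to the latest year's demographics.
#'
#' @param draws A `posterior_draws` object over the full grid.
#' @param world The `ssb_world` providing populations and the
#'   country-region map.
#' @return A list with `levels` and `changes` tibbles.
#' @export
report_tables <- function(draws, world) {
  pop <- world$grid
  rep_draws <- collapse_reporting_grid(draws, pop)
  rep_pop <- attr(rep_draws, "population")
  region_of <- function(ctry) world$countries$region[
    match(ctry, world$countries$country)]

  scopes <- list(list())
  for (s in .SEXES) scopes <- c(scopes, list(list(sex = s)))
  for (a in reporting_age_bands()) scopes <- c(scopes, list(list(age_group = a)))
  for (e in .EDUCATIONS) scopes <- c(scopes, list(list(education = e)))
  for (u in .URBANICITIES) scopes <- c(scopes, list(list(urbanicity = u)))

  lev <- list()
  for (yr in world$years) {
    areas <- c(list(global = NULL),
               stats::setNames(lapply(world$regions, function(r) {
                 world$countries$country[world$countries$region == r]
               }), world$regions))
    for (an in names(areas)) {
      for (sc in scopes) {
        scope <- c(sc, list(year = yr), if (!is.null(areas[[an]]))
          list(country = areas[[an]]))
        est <- aggregate_estimate(rep_draws, rep_pop, scope)
        est$year <- yr
        est$area <- an
        lev[[length(lev) + 1]] <- est
      }
    }
  }

  y_std <- max(world$years)
  pop_std <- rep_pop[rep_pop$year == y_std, ]
  pairs <- list()
  ys <- world$years
  if (length(ys) >= 2) {
    for (i in seq_len(length(ys) - 1)) pairs <- c(pairs, list(c(ys[i], ys[i + 1])))
    if (length(ys) > 2) pairs <- c(pairs, list(c(ys[1], ys[length(ys)])))
  }
  chg <- list()
  for (p in pairs) {
    d1 <- year_slice(rep_draws, p[1])
    d2 <- year_slice(rep_draws, p[2])
    for (an in c("global", world$regions)) {
      scope <- if (an == "global") list() else
        list(country = world$countries$country[world$countries$region == an])
      ce <- change_estimate(d1, d2, pop_std, scope)
      ce$period <- sprintf("%d-%d", p[1], p[2])
      ce$area <- an
      chg[[length(chg) + 1]] <- ce
    }
  }
  list(levels = dplyr::bind_rows(lev), changes = dplyr::bind_rows(chg))
}

#' Slice posterior draws to one year
#'
#' @param draws A `posterior_draws` object.
#' @param year The year to keep.
#' @return A `posterior_draws` object restricted to that year, in
#'   canonical stratum order.
#' @export
year_slice <- function(draws, year) {
  keep <- draws$index$year == year
  structure(
    list(index = draws$index[keep, , drop = FALSE],
         draws = draws$draws[keep, , drop = FALSE], n_draws = draws$n_draws),
    class = "posterior_draws"
  )
}

# ---- schema-validated CSV I/O ------------------------------------------

schema_world <- function() {
  c(country = "c", year = "i", age_group = "c", sex = "c", education = "c",
    urbanicity = "c", true_mean = "d", population = "d")
}
schema_manifest <- function() {
  c(survey_id = "c", country = "c", year = "i", method = "c",
    representativeness = "c", age_band_width = "d", report_sex = "l",
    report_education = "l", report_urbanicity = "l", household_level = "l",
    n_per_stratum = "i")
}
schema_observations <- function() {
  c(survey_id = "c", country = "c", year = "i", age_lo = "i", age_hi = "i",
    sex = "c", education = "c", urbanicity = "c", mean = "d", sd = "d",
    n = "i", method = "c", representativeness = "c", pooled_sex = "l",
    pooled_education = "l", pooled_urbanicity = "l")
}
schema_estimates <- function() {
  c(country = "c", year = "i", age_group = "c", sex = "c", education = "c",
    urbanicity = "c", median = "d", lo95 = "d", hi95 = "d")
}

#' Schema-validated table I/O
#'
#' `write_table()` writes exactly the schema's columns as CSV;
#' `read_table()` parses with the schema's column types and rejects
#' missing or extra required columns with a column-level message.
#' Round-tripping a table through write/read preserves numeric fields to
#' full precision.
#'
#' @param x A data frame.
#' @param path CSV path.
#' @param schema Named character vector mapping column names to readr
#'   short types (`c`, `i`, `d`, `l`).
#' @return `read_table()` returns a tibble; `write_table()` returns the
#'   path invisibly.
#' @export
write_table <- function(x, path, schema) {
  missing <- setdiff(names(schema), names(x))
  if (length(missing)) {
    stop("cannot write: missing column(s) ", paste(missing, collapse = ", "))
  }
  readr::write_csv(x[, names(schema)], path)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  missing <- setdiff(names(schema), hdr)
  extra <- setdiff(hdr, names(schema))
  if (length(missing) || length(extra)) {
    stop("schema mismatch in ", basename(path),
         if (length(missing)) paste0("; missing column(s): ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")))
  }
  types <- paste(unname(schema[hdr]), collapse = "")
  out <- readr::read_csv(path, col_types = types, progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs)) {
    stop("type violations in ", basename(path), " at row(s) ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "))
  }
  out
}
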