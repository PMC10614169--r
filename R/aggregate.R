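#' Population-weighted aggregation of posterior draws
#'
#' Computes the draw-wise population-weighted mean over all strata in a
#' scope, preserving the full posterior so that every reported quantity
#' (medians, uncertainty intervals, contrasts, changes) is derived from
#' the same draws. Weights are renormalized within the scope.
#'
#' @param draws A `posterior_draws` object.
#' @param weights A population table (stratum key columns + `population`)
#'   covering the scope's strata.
#' @param scope Named list of index filters, e.g.
#'   `list(year = 2018, sex = "male", country = c("C01","C02"))`; `NULL`
#'   entries and omitted columns are unrestricted. An `age_min` entry
#'   (band label) restricts to ages at or above that band (use
#'   `"20-24"` for the adult scope).
#' @return A numeric draw vector of length `n_draws`.
#' @export
aggregate_weighted <- function(draws, weights, scope = list()) {
  stopifnot(inherits(draws, "posterior_draws"))
  keep <- scope_rows(draws$index, scope)
  if (!any(keep)) stop("scope selects no strata")
  idx <- draws$index[keep, , drop = FALSE]
  w <- weights$population[match(
    do.call(paste, idx[, stratum_key_cols()]),
    do.call(paste, weights[, stratum_key_cols()])
  )]
  if (anyNA(w)) stop("weights do not cover the scope's strata")
  if (sum(w) <= 0) stop("all weights in scope are zero")
  w <- w / sum(w)
  as.numeric(crossprod(w, draws$draws[keep, , drop = FALSE]))
}

scope_rows <- function(index, scope) {
  keep <- rep(TRUE, nrow(index))
  for (nm in names(scope)) {
    if (is.null(scope[[nm]])) next
    if (nm == "age_min") {
      keep <- keep & age_band_index(index$age_group) >= age_band_index(scope[[nm]])
    } else if (nm == "region") {
      next # handled by caller via country filter
    } else {
      keep <- keep & index[[nm]] %in% scope[[nm]]
    }
  }
  keep
}

#' Summarize a draw vector into median and 95% uncertainty interval
#'
#' Percentiles use linear interpolation between order statistics
#' (R's default quantile type 7), so for draws 1..4000 the median is
#' 2000.5.
#'
#' @param x Numeric draw vector with at least 2 finite values.
#' @return Named numeric vector `median`, `lo95`, `hi95` (2.5th and
#'   97.5th percentiles).
#' @export
summarize_draws <- function(x) {
  if (length(x) < 2 || !all(is.finite(x))) {
    stop("at least 2 finite draws are required")
  }
  q <- stats::quantile(x, c(0.5, 0.025, 0.975), names = FALSE)
  c(median = q[1], lo95 = q[2], hi95 = q[3])
}

#' Aggregate estimate for a scope
#'
#' @inheritParams aggregate_weighted
#' @return A one-row tibble: the scope description plus `median`, `lo95`,
#'   `hi95` (servings/week) and the population covered.
#' @export
aggregate_estimate <- function(draws, weights, scope = list()) {
  v <- aggregate_weighted(draws, weights, scope)
  keep <- scope_rows(draws$index, scope)
  idx <- draws$index[keep, , drop = FALSE]
  pop <- sum(weights$population[match(
    do.call(paste, idx[, stratum_key_cols()]),
    do.call(paste, weights[, stratum_key_cols()])
  )])
  s <- summarize_draws(v)
  tibble::tibble(
    scope = scope_label(scope), median = s["median"], lo95 = s["lo95"],
    hi95 = s["hi95"], population = pop
  )
}

scope_label <- function(scope) {
  if (!length(scope)) return("all")
  paste(vapply(names(scope), function(nm) {
    paste0(nm, "=", paste(scope[[nm]], collapse = "|"))
  }, character(1)), collapse = ",")
}

#' Temporal change estimate standardized to fixed-year demographics
#'
#' Stratum-level draw-wise differences between two years, aggregated with
#' a fixed population table (by convention the 2018 table), so estimated
#' changes reflect intake change rather than demographic change. With
#' fixed weights, changes are additive over consecutive periods
#' draw-wise. The percent change divides the absolute change by the
#' baseline level reconstructed on the same weighted pathway (both at
#' their posterior medians).
#'
#' @param draws_y1,draws_y2 `posterior_draws` for the two years, sharing
#'   the stratum index apart from the `year` column.
#' @param weights_std The standardization population table (e.g. 2018).
#' @param scope Scope filters applied to both years (must not filter on
#'   `year`).
#' @return A one-row tibble with `absolute`, `lo95`, `hi95`, `percent`,
#'   and `significant` (95% UI of the absolute change excludes zero).
#' @export
change_estimate <- function(draws_y1, draws_y2, weights_std, scope = list()) {
  k1 <- nonyear_key(draws_y1$index)
  k2 <- nonyear_key(draws_y2$index)
  if (!identical(k1, k2)) {
    stop("the two years' stratum indices do not match")
  }
  diff <- structure(
    list(index = strip_year(draws_y1$index, weights_std),
         draws = draws_y2$draws - draws_y1$draws,
         n_draws = draws_y1$n_draws),
    class = "posterior_draws"
  )
  base <- structure(
    list(index = diff$index, draws = draws_y1$draws, n_draws = draws_y1$n_draws),
    class = "posterior_draws"
  )
  dv <- aggregate_weighted(diff, weights_std, scope)
  bv <- aggregate_weighted(base, weights_std, scope)
  s <- summarize_draws(dv)
  level_y1 <- unname(summarize_draws(bv)["median"])
  out <- tibble::tibble(
    scope = scope_label(scope),
    absolute = s["median"], lo95 = s["lo95"], hi95 = s["hi95"],
    percent = 100 * s["median"] / level_y1,
    level_y1 = level_y1,
    significant = s["lo95"] > 0 | s["hi95"] < 0
  )
  # the aggregated change draws themselves are additive over chained
  # periods under fixed weights; summaries of them are not exactly so
  attr(out, "draws") <- dv
  out
}

nonyear_key <- function(index) {
  cols <- setdiff(stratum_key_cols(), "year")
  do.call(paste, index[, cols])
}

# re-key a draw index to the standardization table's year so weights match
strip_year <- function(index, weights_std) {
  yr <- unique(weights_std$year)
  if (length(yr) != 1) stop("standardization weights must be a single year")
  index$year <- yr
  index
}

#' Subgroup difference with significance flag
#'
#' Draw-wise weighted difference between two disjoint demographic slices
#' of the same scope (e.g. male minus female, high minus low education,
#' urban minus rural). Slices that overlap partially are rejected;
#' identical slices are allowed as the degenerate zero contrast.
#'
#' @param draws_a,draws_b `posterior_draws` restricted to the two slices;
#'   their indices must match after dropping the contrast column(s).
#' @param weights Population table covering both slices.
#' @param scope Additional filters applied to both slices.
#' @return One-row tibble with `absolute` (A minus B), `lo95`, `hi95`,
#'   `relative` (% of B's level), and `significant`.
#' @export
subgroup_difference <- function(draws_a, draws_b, weights, scope = list()) {
  ka <- do.call(paste, draws_a$index[, stratum_key_cols()])
  kb <- do.call(paste, draws_b$index[, stratum_key_cols()])
  identical_slices <- identical(ka, kb)
  if (!identical_slices && length(intersect(ka, kb))) {
    stop("slices overlap partially: contrasts require disjoint slices")
  }
  va <- aggregate_weighted(draws_a, weights, scope)
  vb <- aggregate_weighted(draws_b, weights, scope)
  d <- va - vb
  s <- summarize_draws(d)
  tibble::tibble(
    scope = scope_label(scope),
    absolute = s["median"], lo95 = s["lo95"], hi95 = s["hi95"],
    relative = 100 * s["median"] / unname(summarize_draws(vb)["median"]),
    significant = s["lo95"] > 0 | s["hi95"] < 0
  )
}

#' Count countries above an intake threshold
#'
#' @param country_estimates Tibble with one `median` (servings/week) per
#'   `country`.
#' @param populations Tibble with adult `population` per `country`.
#' @param threshold Intake threshold (servings/week), default 7.
#' @return A list: `count`, `pct_of_countries` (1 decimal place,
#'   half-away-from-zero), `population_share` (fraction of the summed
#'   adult population).
#' @export
threshold_countries <- function(country_estimates, populations, threshold = 7) {
  qual <- country_estimates$country[country_estimates$median >= threshold]
  pop <- populations$population[match(qual, populations$country)]
  if (anyNA(pop)) {
    stop("missing population for qualifying country: ",
         paste(qual[is.na(pop)], collapse = ", "))
  }
  list(
    count = length(qual),
    pct_of_countries = round_half_away(100 * length(qual) /
                                         nrow(country_estimates), 1),
    population_share = sum(pop) / sum(populations$population)
  )
}

#' Pearson correlation between country intakes and SDI
#'
#' Product-moment correlation with a two-sided p-value from the t
#' transform, for relating country-level mean intakes to the
#' sociodemographic development index (0-1).
#'
#' @param country_medians Numeric vector of country median intakes.
#' @param sdi_values Numeric vector of SDI values, same order.
#' @return A list with `r` and `p`.
#' @export
sdi_correlation <- function(country_medians, sdi_values) {
  if (length(country_medians) != length(sdi_values) ||
      length(country_medians) < 3) {
    stop("paired vectors of length >= 3 required")
  }
  if (!all(is.finite(country_medians)) || !all(is.finite(sdi_values))) {
    stop("inputs must be finite")
  }
  if (stats::sd(country_medians) == 0 || stats::sd(sdi_values) == 0) {
    stop("zero variance: correlation undefined")
  }
  ct <- stats::cor.test(country_medians, sdi_values, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Collapse posterior draws to the adult reporting grid
#'
#' Restricts draws to ages 20+ and merges the 85-89, 90-94 and 95+ bands
#' into a single population-weighted 85+ band, draw-wise, yielding the
#' 14-band adult reporting grid.
#'
#' @param draws A `posterior_draws` object over the full grid.
#' @param weights Population table covering the grid.
#' @return A `posterior_draws` object on the reporting grid, with the
#'   matching collapsed population table in attribute `"population"`.
#' @export
collapse_reporting_grid <- function(draws, weights) {
  stopifnot(inherits(draws, "posterior_draws"))
  idx <- draws$index
  band <- age_band_index(idx$age_group)
  keep <- band >= 7
  idx <- idx[keep, , drop = FALSE]
  dm <- draws$draws[keep, , drop = FALSE]
  band <- band[keep]
  pop <- weights$population[match(
    do.call(paste, idx[, stratum_key_cols()]),
    do.call(paste, weights[, stratum_key_cols()])
  )]
  if (anyNA(pop)) stop("weights do not cover the adult grid")

  grp <- idx
  grp$age_group[band >= 20] <- "85+"
  gk <- do.call(paste, grp[, stratum_key_cols()])
  first <- !duplicated(gk)
  gi <- match(gk, gk[first])

  out_d <- matrix(0, sum(first), ncol(dm))
  out_p <- numeric(sum(first))
  for (r in seq_along(gi)) {
    out_d[gi[r], ] <- out_d[gi[r], ] + pop[r] * dm[r, ]
    out_p[gi[r]] <- out_p[gi[r]] + pop[r]
  }
  zero <- out_p <= 0
  out_d[!zero, ] <- out_d[!zero, , drop = FALSE] / out_p[!zero]
  if (any(zero)) { # unweighted mean when a collapsed cell has no population
    for (g in which(zero)) {
      rows <- which(gi == g)
      out_d[g, ] <- colMeans(dm[rows, , drop = FALSE])
    }
  }
  new_idx <- grp[first, , drop = FALSE]
  new_pop <- new_idx
  new_pop$population <- out_p
  structure(list(index = new_idx, draws = out_d, n_draws = draws$n_draws),
            class = "posterior_draws", population = new_pop)
}
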