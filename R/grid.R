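#' The demographic stratum grid
#'
#' All estimates in ssbpool are indexed by the joint demographic cell
#' (country, year, age band, sex, education, urbanicity). There are 22
#' ordered age bands, 2 sexes, 3 education levels and 2 urbanicity levels,
#' i.e. 264 strata per country-year. Reporting for adults collapses the
#' three oldest bands (85-89, 90-94, 95+) into a single 85+ band, giving
#' the 14-band adult reporting grid (20-24 ... 85+).
#'
#' @name stratum-grid
NULL

# 22 ordered age bands; widths in years are used by the overdispersion rule
.AGE_BANDS <- c(
  "<1", "1-2", "3-4", "5-9", "10-14", "15-19",
  "20-24", "25-29", "30-34", "35-39", "40-44", "45-49", "50-54",
  "55-59", "60-64", "65-69", "70-74", "75-79", "80-84", "85-89",
  "90-94", "95+"
)
.AGE_WIDTHS <- c(1, 2, 2, 5, rep(5, 18))
.AGE_LOWER <- c(0, 1, 3, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50,
                55, 60, 65, 70, 75, 80, 85, 90, 95)
.SEXES <- c("female", "male")
.EDUCATIONS <- c("low", "medium", "high") # <=6y, >6-12y, >12y of schooling
.URBANICITIES <- c("rural", "urban")

#' Age band labels
#'
#' @param adult If `TRUE`, return only the 16 bands covering ages 20+;
#'   otherwise all 22 bands (from `<1` to `95+`).
#' @return Character vector of ordered age band labels.
#' @export
age_bands <- function(adult = FALSE) {
  if (adult) .AGE_BANDS[7:22] else .AGE_BANDS
}

#' Adult reporting age bands (85+ collapsed)
#'
#' @return The 14 age-band labels used in adult report tables:
#'   `20-24` through `80-84` plus `85+`.
#' @export
reporting_age_bands <- function() c(.AGE_BANDS[7:19], "85+")

#' Index of an age band label
#' @param band Character vector of age band labels.
#' @return Integer positions in the ordered 22-band grid.
#' @keywords internal
age_band_index <- function(band) {
  idx <- match(band, .AGE_BANDS)
  if (anyNA(idx)) {
    stop("unknown age band(s): ", paste(unique(band[is.na(idx)]), collapse = ", "))
  }
  idx
}

#' Width in years of an age range spanning bands `lo` to `hi`
#' @param lo,hi Integer band indices (1-22).
#' @return Numeric width in years; the open-ended 95+ band counts as 5.
#' @keywords internal
age_range_width <- function(lo, hi) {
  mapply(function(l, h) sum(.AGE_WIDTHS[l:h]), lo, hi)
}

#' Build the full stratum grid for a set of country-years
#'
#' @param countries Character vector of country identifiers.
#' @param years Integer vector of calendar years.
#' @return A tibble with one row per stratum: `country`, `year`,
#'   `age_group`, `sex`, `education`, `urbanicity`; 264 rows per
#'   country-year.
#' @export
stratum_grid <- function(countries, years) {
  tidyr::expand_grid(
    country = countries,
    year = as.integer(years),
    age_group = .AGE_BANDS,
    sex = .SEXES,
    education = .EDUCATIONS,
    urbanicity = .URBANICITIES
  )
}

# canonical sort order for stratum tables (kept stable across the package)
stratum_arrange <- function(df) {
  dplyr::arrange(
    df, .data$country, .data$year,
    match(.data$age_group, .AGE_BANDS),
    match(.data$sex, .SEXES),
    match(.data$education, .EDUCATIONS),
    match(.data$urbanicity, .URBANICITIES)
  )
}

stratum_key_cols <- function() {
  c("country", "year", "age_group", "sex", "education", "urbanicity")
}

# reported-cell key of each fine stratum under a design's granularity:
# 10-year designs merge adjacent 5-year bands pairwise from the design's
# lowest covered band; pooled dimensions collapse to "all"
reported_cell_key <- function(band, sex, education, urbanicity, design) {
  lo0 <- age_band_index(design$age_min)
  if (isTRUE(design$pool_age)) {
    lo <- rep(lo0, length(band))
    hi <- rep(age_band_index(design$age_max), length(band))
  } else if (design$age_band_width == 10) {
    lo <- lo0 + ((band - lo0) %/% 2L) * 2L
    hi <- pmin(lo + 1L, 22L)
  } else {
    lo <- band
    hi <- band
  }
  list(
    age_lo = lo, age_hi = hi,
    sex = if (design$report_sex) sex else rep("all", length(band)),
    education = if (design$report_education) education else rep("all", length(band)),
    urbanicity = if (design$report_urbanicity) urbanicity else rep("all", length(band))
  )
}

# deterministic largest-remainder allocation of n units over weights w
allocate_proportional <- function(n, w) {
  if (sum(w) <= 0) w <- rep(1, length(w))
  q <- n * w / sum(w)
  f <- floor(q)
  r <- n - sum(f)
  if (r > 0) {
    o <- order(q - f, decreasing = TRUE)
    f[o[seq_len(r)]] <- f[o[seq_len(r)]] + 1
  }
  as.integer(f)
}
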