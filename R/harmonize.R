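#' Serving and energy conventions
#'
#' Intakes are standardized to 8 oz servings per week. Data providers are
#' asked for servings of 8 oz = 236.5 g; reporting uses the FoodData
#' Central equivalence of 8 oz = 248 g for SSBs. Energy adjustment targets
#' 2000 kcal/day for ages 20-74 and 1700 kcal/day for ages 75+.
#'
#' @param grams_per_serving Grams in one 8 oz serving.
#' @return `serving_definition()`: a list with `grams_per_serving`.
#' @export
serving_definition <- function(grams_per_serving = 248) {
  if (!is.numeric(grams_per_serving) || grams_per_serving <= 0) {
    stop("grams_per_serving must be > 0")
  }
  list(grams_per_serving = grams_per_serving)
}

#' @rdname serving_definition
#' @param kcal_adults Standard energy (kcal/day) for ages 20-74.
#' @param kcal_elderly Standard energy (kcal/day) for ages 75+.
#' @return `energy_standard()`: a list with both standards.
#' @export
energy_standard <- function(kcal_adults = 2000, kcal_elderly = 1700) {
  if (kcal_adults <= 0 || kcal_elderly <= 0) stop("energy standards must be > 0")
  list(kcal_adults = kcal_adults, kcal_elderly = kcal_elderly)
}

#' Convert an intake in grams/week to servings/week
#'
#' @param amount Intake in grams per week (>= 0).
#' @param serving A [serving_definition()].
#' @return Intake in servings per week (`amount / grams_per_serving`).
#' @export
convert_serving_units <- function(amount, serving = serving_definition()) {
  if (any(amount < 0, na.rm = TRUE)) stop("amount must be >= 0")
  amount / serving$grams_per_serving
}

#' Residual-method energy adjustment
#'
#' Regresses intake on reported total energy (ordinary least squares) and
#' replaces each observation with its residual plus the predicted intake
#' at the age-appropriate standard energy (2000 kcal/day for ages 20-74,
#' 1700 kcal/day for 75+). This removes variation in intake that merely
#' tracks total consumption while preserving each person's relative
#' position. Adjusted values are floored at zero (intake is nonnegative
#' by definition). When the energy vector is constant the slope is
#' undefined and intakes are returned unchanged with a warning.
#'
#' @param intakes Numeric vector of intakes (servings/week).
#' @param energies Numeric vector of reported energies (kcal/day), > 0.
#' @param standard An [energy_standard()].
#' @param age_group Either a single age-band label or `"20-74"` /
#'   `"75+"`; decides which standard energy is used.
#' @return Numeric vector of adjusted intakes; its mean equals the
#'   regression prediction at the standard energy (before flooring).
#' @export
energy_residual_adjust <- function(intakes, energies,
                                   standard = energy_standard(),
                                   age_group = "20-74") {
  if (length(intakes) != length(energies)) {
    stop("intakes and energies must have equal length")
  }
  if (length(intakes) < 3) stop("at least 3 observations are required")
  if (any(energies <= 0)) stop("energies must be > 0")
  e_std <- standard_energy_for(age_group, standard)
  if (stats::sd(energies) == 0) {
    warning("constant energy vector: slope undefined, intakes returned unchanged")
    return(intakes)
  }
  fit <- stats::lm.fit(cbind(1, energies), intakes)
  pred_std <- fit$coefficients[1] + fit$coefficients[2] * e_std
  pmax(0, unname(fit$residuals + pred_std))
}

standard_energy_for <- function(age_group, standard = energy_standard()) {
  if (age_group %in% c("20-74", "adult")) return(standard$kcal_adults)
  if (age_group %in% c("75+", "elderly")) return(standard$kcal_elderly)
  idx <- age_band_index(age_group)
  if (idx >= 18) standard$kcal_elderly else standard$kcal_adults
}

#' Adult-male-equivalent disaggregation of a household total
#'
#' Allocates a household's weekly intake to its members in proportion to
#' their age- and sex-specific energy requirements. Shares sum to one, so
#' member intakes always sum to the household total exactly.
#'
#' @param household_total Household intake (servings/week, >= 0).
#' @param members A data frame with `age_group` and `sex` per member.
#' @param requirements A data frame mapping `(age_group, sex)` to
#'   `kcal_day`; defaults to [ame_requirements()].
#' @return Numeric vector of per-member intakes (servings/week).
#' @export
ame_disaggregate <- function(household_total, members,
                             requirements = ame_requirements()) {
  if (household_total < 0) stop("household_total must be >= 0")
  if (nrow(members) == 0) stop("members must be non-empty")
  i <- match(paste(members$age_group, members$sex),
             paste(requirements$age_group, requirements$sex))
  if (anyNA(i)) {
    bad <- which(is.na(i))[1]
    stop(sprintf("no energy requirement for member %d (%s, %s)",
                 bad, members$age_group[bad], members$sex[bad]))
  }
  req <- requirements$kcal_day[i]
  if (any(req <= 0)) stop("energy requirements must be positive")
  household_total * req / sum(req)
}

#' Synthetic energy-requirement table for AME disaggregation
#'
#' Plausible daily energy requirements (kcal/day) by age band and sex,
#' rising through childhood, peaking in early adulthood (higher for
#' males), and declining with age. This table is a synthetic convention
#' of the package, not a published reference standard.
#'
#' @return A tibble with `age_group`, `sex`, `kcal_day`.
#' @export
ame_requirements <- function() {
  mid <- .AGE_LOWER + .AGE_WIDTHS / 2
  base <- 800 + 1900 * (1 - exp(-mid / 9)) # rises to ~2700 by adulthood
  decline <- pmax(0, (mid - 40) * 8)       # gentle decline after 40
  male <- pmax(900, base - decline)
  female <- pmax(800, 0.8 * base - 0.8 * decline)
  tibble::tibble(
    age_group = rep(.AGE_BANDS, 2),
    sex = rep(c("male", "female"), each = 22),
    kcal_day = c(male, female)
  )
}

#' Summarize raw survey records to stratum-level observations
#'
#' Per participant, all assessment days are averaged first; participant
#' means are then summarized (mean, SD, n) within each cell the survey
#' reports. Cells keep the survey's granularity: coarse age bands are
#' carried as a band range (`age_lo`/`age_hi` indices) and pooled
#' dimensions as `"all"`, with granularity flags preserved for the
#' model's overdispersion rule. Household-member records are first
#' disaggregated with [ame_disaggregate()].
#'
#' @param records A raw record tibble from [simulate_survey()] (or any
#'   table with the same columns).
#' @param design The [survey_design()] describing reporting granularity.
#' @param standard An [energy_standard()] used for residual energy
#'   adjustment of individual records (fitted per survey and broad age
#'   class, 20-74 vs 75+).
#' @param energy_adjust Apply the residual energy adjustment before
#'   summarizing (skipped automatically when reported energy is missing
#'   or constant).
#' @return A tibble of survey-stratum observations: `survey_id`,
#'   `country`, `year`, `age_lo`, `age_hi`, `sex`, `education`,
#'   `urbanicity`, `mean`, `sd`, `n`, plus `method`,
#'   `representativeness`, and granularity flags.
#' @export
summarize_to_strata <- function(records, design,
                                standard = energy_standard(),
                                energy_adjust = TRUE) {
  if (nrow(records) == 0) stop("survey has zero participants")
  if (any(records$record_type == "household_member")) {
    records <- disaggregate_households(records)
  }
  # average all assessment days per participant
  part <- dplyr::summarise(
    dplyr::group_by(records, .data$survey_id, .data$participant_id,
                    .data$country, .data$year, .data$age_group, .data$sex,
                    .data$education, .data$urbanicity),
    intake = mean(.data$intake), energy_kcal = mean(.data$energy_kcal),
    .groups = "drop"
  )
  if (energy_adjust && any(is.finite(part$energy_kcal))) {
    band <- age_band_index(part$age_group)
    cls <- ifelse(band >= 18, "75+", "20-74")
    for (cl in unique(cls)) {
      sel <- which(cls == cl & is.finite(part$energy_kcal))
      if (length(sel) >= 3 && stats::sd(part$energy_kcal[sel]) > 0) {
        part$intake[sel] <- energy_residual_adjust(
          part$intake[sel], part$energy_kcal[sel], standard, cl
        )
      }
    }
  }

  band <- age_band_index(part$age_group)
  cell <- reported_cell_key(band, part$sex, part$education,
                            part$urbanicity, design)
  part$age_lo <- cell$age_lo
  part$age_hi <- cell$age_hi
  part$sex_r <- cell$sex
  part$edu_r <- cell$education
  part$urb_r <- cell$urbanicity

  obs <- dplyr::summarise(
    dplyr::group_by(part, .data$survey_id, .data$country, .data$year,
                    .data$age_lo, .data$age_hi,
                    sex = .data$sex_r, education = .data$edu_r,
                    urbanicity = .data$urb_r),
    mean = mean(.data$intake),
    sd = if (dplyr::n() > 1) stats::sd(.data$intake) else 0,
    n = dplyr::n(),
    .groups = "drop"
  )
  obs$method <- design$method
  obs$representativeness <- design$representativeness
  obs$pooled_sex <- !design$report_sex
  obs$pooled_education <- !design$report_education
  obs$pooled_urbanicity <- !design$report_urbanicity
  obs
}

disaggregate_households <- function(records, requirements = ame_requirements()) {
  hh <- records[records$record_type == "household_member", ]
  other <- records[records$record_type != "household_member", ]
  parts <- lapply(split(hh, hh$household_id), function(h) {
    h$intake <- ame_disaggregate(h$household_total[1],
                                 h[, c("age_group", "sex")], requirements)
    h$record_type <- "individual"
    h
  })
  dplyr::bind_rows(other, dplyr::bind_rows(parts))
}

#' Harmonize a whole survey collection
#'
#' Applies [summarize_to_strata()] to every survey of a collection and
#' screens the resulting observations with [qc_screen()].
#'
#' @param collection Output of [simulate_survey_collection()].
#' @param standard An [energy_standard()].
#' @param rules Plausibility rules for [qc_screen()].
#' @return A list with `observations` (kept) and `rejected` (with reason
#'   codes).
#' @export
harmonize_surveys <- function(collection, standard = energy_standard(),
                              rules = qc_rules()) {
  obs <- lapply(collection$manifest$survey_id, function(sid) {
    summarize_to_strata(
      collection$records[collection$records$survey_id == sid, ],
      collection$designs[[sid]], standard
    )
  })
  qc_screen(dplyr::bind_rows(obs), rules)
}

#' Plausibility rules for observation screening
#'
#' @param mean_min,mean_max Plausible bounds on a stratum mean
#'   (servings/week). The 70 servings/week (~10/day) ceiling is this
#'   package's implementable screening convention and is configurable.
#' @param n_min Minimum participants per observation.
#' @return A list of rule bounds.
#' @export
qc_rules <- function(mean_min = 0, mean_max = 70, n_min = 1) {
  list(mean_min = mean_min, mean_max = mean_max, n_min = n_min)
}

#' Screen observations for plausibility
#'
#' Partitions an observation table into kept and rejected rows; every
#' rejection carries a machine-readable reason code. The partition is
#' exhaustive and disjoint and screening never errors on data values.
#'
#' @param observations A survey-stratum observation tibble.
#' @param rules A [qc_rules()] list.
#' @return A list with `kept` and `rejected` (the latter with a `reason`
#'   column: `negative_mean`, `implausible_mean`, `negative_sd`,
#'   `invalid_n`).
#' @export
qc_screen <- function(observations, rules = qc_rules()) {
  reason <- rep(NA_character_, nrow(observations))
  reason[is.na(reason) & observations$mean < rules$mean_min] <- "negative_mean"
  reason[is.na(reason) & observations$mean > rules$mean_max] <- "implausible_mean"
  reason[is.na(reason) & observations$sd < 0] <- "negative_sd"
  reason[is.na(reason) &
           (observations$n < rules$n_min | !is.finite(observations$n))] <- "invalid_n"
  keep <- is.na(reason)
  rejected <- observations[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep] else rejected$reason <- character(0)
  list(kept = observations[keep, , drop = FALSE], rejected = rejected)
}

#' Collapse the three oldest age bands into a single 85+ value
#'
#' Applies a population-weighted mean over the 85-89, 90-94 and 95+
#' values; when the input is a draws matrix (3 rows x draws) the weighted
#' mean is taken draw-wise, preserving uncertainty propagation.
#'
#' @param values Numeric vector of length 3, or a 3-row matrix of
#'   posterior draws, ordered 85-89, 90-94, 95+.
#' @param weights Nonnegative population weights for the three bands;
#'   must not all be zero.
#' @return A single value, or a draw vector when `values` is a matrix.
#' @export
collapse_85plus <- function(values, weights) {
  if (length(weights) != 3 || any(weights < 0) || sum(weights) <= 0) {
    stop("weights must be 3 nonnegative values with positive sum")
  }
  w <- weights / sum(weights)
  if (is.matrix(values)) {
    stopifnot(nrow(values) == 3)
    as.numeric(crossprod(w, values))
  } else {
    stopifnot(length(values) == 3)
    sum(w * values)
  }
}
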