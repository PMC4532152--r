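#' Smoking-category weighting factors
#'
#' Weights converting smoking-category headcounts into "weighted
#' smoker-equivalents", the exposure denominator of the projection:
#' 1 for active smokers and for ex-smokers who quit 1-3 years ago,
#' 0.75 for those who quit 3-5 years ago, 0.5 for those who quit 5-10
#' years ago.
#'
#' @param active,quit_1_3,quit_3_5,quit_5_10 weights in `[0, 1]`;
#'   `active` must be at least each quitter weight.
#' @return a named numeric vector of class `smoking_weights`.
#' @export
#' @examples
#' smoking_weights()
smoking_weights <- function(active = 1, quit_1_3 = 1,
                            quit_3_5 = 0.75, quit_5_10 = 0.5) {
  w <- c(active = active, quit_1_3 = quit_1_3,
         quit_3_5 = quit_3_5, quit_5_10 = quit_5_10)
  validate_weights(w)
}

validate_weights <- function(w) {
  if (!all(SMOKING_CATEGORIES %in% names(w))) {
    abort("field 'weights': must be named %s",
          paste(SMOKING_CATEGORIES, collapse = ", "))
  }
  w <- w[SMOKING_CATEGORIES]
  check_fraction(w, "weights")
  if (any(w[["active"]] < w[c("quit_1_3", "quit_3_5", "quit_5_10")])) {
    abort("field 'weights': 'active' must be >= each quitter weight")
  }
  structure(w, class = "smoking_weights")
}

#' Weighted smoker-equivalents of one stratum-year
#'
#' `population * sum(fraction_c * weight_c)` over the four smoking
#' categories.
#'
#' @param fractions named numeric vector with entries
#'   [SMOKING_CATEGORIES] (missing categories count as 0).
#' @param population inhabitant count of the stratum (>= 0).
#' @param weights a [smoking_weights()] vector.
#' @return scalar equivalent count.
#' @export
#' @examples
#' weighted_equivalents(
#'   c(active = 0.10, quit_1_3 = 0.04, quit_3_5 = 0.02, quit_5_10 = 0.01),
#'   1000)  # 160
weighted_equivalents <- function(fractions, population,
                                 weights = smoking_weights()) {
  check_nonneg(population, "population")
  weights <- validate_weights(weights)
  f <- setNames(numeric(4), SMOKING_CATEGORIES)
  f[names(fractions)] <- fractions
  check_fraction(f, "fractions")
  population * sum(f * unclass(weights)[SMOKING_CATEGORIES])
}

## equivalents per year x stratum from long smoking + population tables
equivalents_table <- function(smoking, population,
                              weights = smoking_weights()) {
  weights <- validate_weights(weights)
  sm <- as.data.table(smoking)[category %in% SMOKING_CATEGORIES]
  sm[, weight := unclass(weights)[category]]
  eqf <- sm[, .(wf = sum(fraction * weight)), by = .(year, age_group, sex)]
  eq <- merge(eqf, as.data.table(population),
              by = c("year", "age_group", "sex"))
  eq[, equivalents := wf * count]
  eq[, .(year, age_group, sex, equivalents)]
}

#' Smoking-standardised base-year costs per stratum
#'
#' Divides each stratum's base-year COPD cost, separately for the
#' direct and indirect channels, by the stratum's weighted
#' smoker-equivalents, yielding EUR per equivalent.  A stratum with
#' positive cost but zero equivalents is a hard error (the
#' standardisation is undefined there); zero cost with zero
#' equivalents standardises to 0.
#'
#' @param base_costs `data.table` with columns `age_group`, `sex`,
#'   `direct_eur`, `indirect_eur` (base-year EUR per stratum).
#' @param equivalents `data.table` with columns `age_group`, `sex`,
#'   `equivalents`.
#' @param base_year calendar year the costs refer to.
#' @return a `data.table` of class `standardised_cost` with columns
#'   `age_group`, `sex`, `direct_per_eq`, `indirect_per_eq` and
#'   attribute `base_year`.
#' @export
standardise_costs <- function(base_costs, equivalents, base_year = 2006) {
  bc <- as.data.table(base_costs)
  eq <- as.data.table(equivalents)
  check_nonneg(bc$direct_eur, "direct_eur")
  check_nonneg(bc$indirect_eur, "indirect_eur")
  std <- merge(bc, eq[, .(age_group, sex, equivalents)],
               by = c("age_group", "sex"), all.x = TRUE)
  std[is.na(equivalents), equivalents := 0]
  bad <- std[(direct_eur > 0 | indirect_eur > 0) & equivalents <= 0]
  if (nrow(bad)) {
    abort("positive cost with zero smoker-equivalents in stratum %s",
          paste(sprintf("%s/%s", bad$age_group, bad$sex), collapse = ", "))
  }
  std[, direct_per_eq := fifelse(equivalents > 0, direct_eur / equivalents, 0)]
  std[, indirect_per_eq := fifelse(equivalents > 0, indirect_eur / equivalents, 0)]
  out <- stratum_order(std[, .(age_group, sex, direct_per_eq, indirect_per_eq)])
  setattr(out, "base_year", as.integer(base_year))
  setattr(out, "class", c("standardised_cost", class(out)))
  out[]
}

## per-group OLS fit of fraction ~ year (exact closed form)
ols_line <- function(year, fraction) {
  mx <- mean(year); my <- mean(fraction)
  sl <- sum((year - mx) * (fraction - my)) / sum((year - mx)^2)
  list(intercept = my - sl * mx, slope = sl)
}

#' Extrapolate smoking fractions linearly from their history
#'
#' Per stratum and smoking category, fits an ordinary-least-squares
#' line (percentage points per year) through the history window and
#' continues it to the target years — the "fractions keep changing at
#' the rate they changed historically" assumption.  Predictions are
#' clamped to `[0, 1]` and the four-category sum is capped at 1 by
#' truncating the largest category.  A proportional mode (log-linear
#' fit, i.e. constant relative decay) is available for sensitivity
#' analysis.
#'
#' @param history `data.table` (`year`, `age_group`, `sex`,
#'   `category`, `fraction`) with at least two distinct years per
#'   stratum-category.
#' @param target_years integer vector of years to predict.
#' @param method `"linear"` (default) or `"proportional"`.
#' @return a `data.table` in the same long format covering
#'   `target_years`.
#' @export
extrapolate_fractions <- function(history, target_years,
                                  method = c("linear", "proportional")) {
  method <- match.arg(method)
  history <- as.data.table(history)
  check_fraction(history$fraction, "fraction")
  target_years <- as.integer(target_years)
  ny <- history[, .(n = uniqueN(year)), by = .(age_group, sex, category)]
  if (any(ny$n < 2)) {
    abort("insufficient history: need >= 2 years per stratum-category")
  }
  if (method == "proportional" && any(history$fraction <= 0)) {
    abort("proportional extrapolation requires strictly positive history fractions")
  }
  fits <- history[, {
    y <- if (method == "linear") fraction else log(fraction)
    ols_line(year, y)
  }, by = .(age_group, sex, category)]
  grid <- fits[, .(year = target_years), by = .(age_group, sex, category,
                                                intercept, slope)]
  if (method == "linear") {
    grid[, fraction := intercept + slope * year]
  } else {
    grid[, fraction := exp(intercept + slope * year)]
  }
  grid[, fraction := pmin(1, pmax(0, fraction))]
  grid[, c("intercept", "slope") := NULL]
  cap_fraction_sum(grid)
}

#' Project annual COPD costs from standardised costs
#'
#' For every projection year: weighted smoker-equivalents per stratum
#' (extrapolated fractions x projected population x weights) are
#' multiplied by the base-year standardised cost per equivalent.  The
#' direct channel is summed over all strata; the indirect channel only
#' over working-age strata (band lower bound below `retirement_age`),
#' since morbidity after retirement causes no productivity loss.
#' Nominal series apply a constant annual inflation factor relative to
#' the base year; the real (uninflated) series is retained alongside.
#'
#' @param std a [standardise_costs()] table.
#' @param fractions extrapolated smoking fractions (long format)
#'   covering every projection year and stratum.
#' @param population `data.table` (`year`, `age_group`, `sex`,
#'   `count`): the population projection.
#' @param weights a [smoking_weights()] vector.
#' @param inflation annual inflation fraction (default 0.02).
#' @param base_year inflation base year; defaults to the
#'   standardisation base year.
#' @param retirement_age years; strata at or above it contribute no
#'   indirect cost (default 65).
#' @return a `data.table` of class `projection_result` with columns
#'   `year`, `direct_real`, `indirect_real`, `total_real`,
#'   `direct_nominal`, `indirect_nominal`, `total_nominal`.
#' @export
project_costs <- function(std, fractions, population,
                          weights = smoking_weights(),
                          inflation = 0.02,
                          base_year = attr(std, "base_year"),
                          retirement_age = 65) {
  stopifnot(inherits(std, "standardised_cost"))
  if (!is.finite(inflation) || inflation <= -1) {
    abort("field 'inflation': must be > -1")
  }
  eq <- equivalents_table(fractions, population, weights)
  missing_strata <- setdiff(
    unique(paste(eq$age_group, eq$sex)),
    unique(paste(std$age_group, std$sex)))
  if (length(missing_strata)) {
    abort("standardised costs missing for stratum(s): %s",
          paste(missing_strata, collapse = ", "))
  }
  pop_keys <- as.data.table(population)[, .N, by = .(year, age_group, sex)]
  if (nrow(pop_keys) != nrow(eq)) {
    abort("smoking fractions and population projection cover different year-strata")
  }
  x <- merge(eq, std, by = c("age_group", "sex"))
  x[, working_age := is_working_age(age_group, retirement_age)]
  res <- x[, .(
    direct_real = sum(equivalents * direct_per_eq),
    indirect_real = sum(equivalents * indirect_per_eq * working_age)
  ), by = year]
  setorder(res, year)
  res[, total_real := direct_real + indirect_real]
  infl <- (1 + inflation)^(res$year - as.integer(base_year))
  res[, direct_nominal := direct_real * infl]
  res[, indirect_nominal := indirect_real * infl]
  res[, total_nominal := total_real * infl]
  setattr(res, "base_year", as.integer(base_year))
  setattr(res, "inflation", inflation)
  setattr(res, "class", c("projection_result", class(res)))
  res[]
}

#' Headline statistics of a cost projection
#'
#' First-year and last-year nominal totals and the percent change
#' between them (by the [percent_change()] reporting rule).  A
#' single-year projection has no change to report; the element is `NA`.
#'
#' @param result a [project_costs()] table.
#' @return a list: `first_year`, `last_year`, `first_total_eur`,
#'   `last_total_eur`, `pct_change`.
#' @export
summarise_projection <- function(result) {
  result <- as.data.table(result)
  if (nrow(result) == 0) abort("empty projection result")
  setorder(result, year)
  first <- result[1]; last <- result[.N]
  list(
    first_year = first$year,
    last_year = last$year,
    first_total_eur = first$total_nominal,
    last_total_eur = last$total_nominal,
    pct_change = if (nrow(result) > 1 && first$total_nominal > 0) {
      percent_change(first$total_nominal, last$total_nominal)
    } else NA_real_
  )
}
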