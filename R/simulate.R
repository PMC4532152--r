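#' Register event categories
#'
#' The six person-level event categories emitted by the synthetic
#' register generator and consumed by the accounting stage: hospital
#' days in primary (PHC) and secondary (SHC) health care, SHC
#' outpatient visits, pharmacy drug purchases, days on sickness
#' allowance and disability-pension records.
#'
#' @export
EVENT_CATEGORIES <- c(
  "phc_hospital_day", "shc_hospital_day", "shc_outpatient_visit",
  "drug_purchase", "sickness_allowance_day", "disability_pension"
)

#' Smoking categories
#'
#' Active smokers plus three recent-quitter categories by time since
#' quitting (1-3, 3-5 and 5-10 years).
#' @export
SMOKING_CATEGORIES <- c("active", "quit_1_3", "quit_3_5", "quit_5_10")

## ICD-10 codes used by the generator: true COPD rubrics (with some
## subcodes, to exercise prefix matching) and look-alike distractors
COPD_CODE_POOL <- c("J43", "J44", "J44.0", "J44.1", "J44.8")
COPD_CODE_PROBS <- c(0.25, 0.40, 0.15, 0.12, 0.08)

#' Simulation configuration for the synthetic registers
#'
#' Describes a stratified population (5-year age bands x sex), its
#' smoking-category fractions per year, and per-category annual event
#' rates per weighted smoker-equivalent.  Event counts per stratum-year
#' are Poisson with mean `rate * age_multiplier * weighted equivalents`;
#' see [generate_registers()].
#'
#' @param years integer vector of consecutive calendar years.
#' @param population `data.table` with columns `year`, `age_group`,
#'   `sex`, `count` covering every year x stratum.
#' @param smoking `data.table` with columns `year`, `age_group`, `sex`,
#'   `category`, `fraction`; categories are [SMOKING_CATEGORIES]; the
#'   four fractions must sum to at most 1 in every stratum-year.
#' @param event_rates named numeric vector: expected annual events per
#'   weighted smoker-equivalent for each of [EVENT_CATEGORIES] (missing
#'   names default to 0).
#' @param copd_diagnosis_share probability that a generated event
#'   carries a J43/J44 code as primary diagnosis (otherwise a
#'   distractor code).
#' @param distractor_codes ICD-10 codes used for non-COPD events.
#' @param age_multiplier optional `data.table` (`age_group`,
#'   `multiplier`) scaling event rates by age band; default 1
#'   everywhere.
#' @param entitled_share person-level probability of special
#'   reimbursement entitlement among drug purchasers.
#' @param anticholinergic_share person-level probability of inhaled
#'   anticholinergic use among drug purchasers.
#' @param mean_purchase_eur mean EUR amount of one drug purchase.
#' @param weights a [smoking_weights()] vector used to convert
#'   smoking fractions into weighted smoker-equivalents.
#' @param seed integer RNG seed; identical configs (including seed)
#'   generate identical registers.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(years, population, smoking, event_rates,
                       copd_diagnosis_share = 0.8,
                       distractor_codes = c("J18", "J45", "I50"),
                       age_multiplier = NULL,
                       entitled_share = 0.7,
                       anticholinergic_share = 0.8,
                       mean_purchase_eur = 120,
                       weights = smoking_weights(),
                       seed = 1L) {
  years <- as.integer(years)
  if (length(years) == 0 || any(diff(years) != 1L)) {
    abort("field 'years': must be a non-empty range of consecutive years")
  }
  population <- as.data.table(population)
  req <- c("year", "age_group", "sex", "count")
  if (!all(req %in% names(population))) {
    abort("field 'population': needs columns %s", paste(req, collapse = ", "))
  }
  check_nonneg(population$count, "population.count")
  validate_age_groups(unique(population$age_group),
                      from = min(age_band_lower(population$age_group)))

  smoking <- as.data.table(smoking)
  reqs <- c("year", "age_group", "sex", "category", "fraction")
  if (!all(reqs %in% names(smoking))) {
    abort("field 'smoking': needs columns %s", paste(reqs, collapse = ", "))
  }
  if (!all(smoking$category %in% SMOKING_CATEGORIES)) {
    abort("field 'smoking.category': unknown category; allowed: %s",
          paste(SMOKING_CATEGORIES, collapse = ", "))
  }
  check_fraction(smoking$fraction, "smoking.fraction")
  sums <- smoking[, .(s = sum(fraction)), by = .(year, age_group, sex)]
  if (any(sums$s > 1 + 1e-9)) {
    abort("field 'smoking.fraction': four-category sum exceeds 1 in %d stratum-year(s)",
          sum(sums$s > 1 + 1e-9))
  }

  rates <- setNames(numeric(length(EVENT_CATEGORIES)), EVENT_CATEGORIES)
  if (is.null(names(event_rates)) ||
      !all(names(event_rates) %in% EVENT_CATEGORIES)) {
    abort("field 'event_rates': must be named with categories among: %s",
          paste(EVENT_CATEGORIES, collapse = ", "))
  }
  check_nonneg(event_rates, "event_rates")
  rates[names(event_rates)] <- event_rates

  if (is.null(age_multiplier)) {
    age_multiplier <- data.table(age_group = unique(population$age_group),
                                 multiplier = 1)
  } else {
    age_multiplier <- as.data.table(age_multiplier)
    check_nonneg(age_multiplier$multiplier, "age_multiplier.multiplier")
  }
  check_fraction(copd_diagnosis_share, "copd_diagnosis_share")
  check_fraction(entitled_share, "entitled_share")
  check_fraction(anticholinergic_share, "anticholinergic_share")
  check_positive(mean_purchase_eur, "mean_purchase_eur")
  weights <- validate_weights(weights)

  structure(list(
    years = years, population = population, smoking = smoking,
    event_rates = rates, copd_diagnosis_share = copd_diagnosis_share,
    distractor_codes = distractor_codes, age_multiplier = age_multiplier,
    entitled_share = entitled_share,
    anticholinergic_share = anticholinergic_share,
    mean_purchase_eur = mean_purchase_eur,
    weights = weights, seed = as.integer(seed)
  ), class = "sim_config")
}

## equivalents per year x stratum implied by a config
config_equivalents <- function(config) {
  sm <- dcast(config$smoking, year + age_group + sex ~ category,
              value.var = "fraction", fill = 0)
  for (cat in SMOKING_CATEGORIES) if (!cat %in% names(sm)) sm[, (cat) := 0]
  eq <- merge(sm, config$population, by = c("year", "age_group", "sex"))
  w <- config$weights
  eq[, equivalents := count * (active * w[["active"]] +
                               quit_1_3 * w[["quit_1_3"]] +
                               quit_3_5 * w[["quit_3_5"]] +
                               quit_5_10 * w[["quit_5_10"]])]
  eq[, .(year, age_group, sex, count, equivalents)]
}

#' Generate synthetic register extracts
#'
#' Draws, for every stratum-year and event category, a Poisson number
#' of events with mean `event_rate * age_multiplier * weighted
#' smoker-equivalents`, and emits one row per event with diagnosis
#' codes, quantities and person identifiers.  Diagnosis codes are
#' J43/J44 (occasionally with subcodes) with probability
#' `copd_diagnosis_share`, else a distractor code.  Drug purchases
#' carry a EUR amount as `quantity`, an empty diagnosis code (the
#' medicines register holds no diagnoses) and person-level
#' reimbursement-entitlement / anticholinergic-use flags; all purchases
#' of a given person share the same flags.  Disability-pension records
#' are unique per person-year, with `quantity` in person-years.
#'
#' Identical configurations (including the seed) generate identical
#' tables; the caller's RNG state is left untouched.
#'
#' @param config a [sim_config()].
#' @return a `data.table` with columns `person_id`, `year`, `category`,
#'   `primary_icd10`, `quantity`, `reimbursement_entitled`,
#'   `uses_anticholinergic`, `age_group`, `sex`.
#' @export
generate_registers <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  eq <- stratum_order(config_equivalents(config))
  setorder(eq, year)
  strata <- stratum_order(unique(eq[, .(age_group, sex)]))
  mult <- setNames(config$age_multiplier$multiplier,
                   config$age_multiplier$age_group)

  with_seed(config$seed, {
    out <- vector("list", nrow(strata))
    for (si in seq_len(nrow(strata))) {
      ag <- strata$age_group[si]; sx <- strata$sex[si]
      sub <- eq[age_group == ag & sex == sx][order(year)]
      max_eq <- max(sub$equivalents, 0)
      pool_n <- max(100L, as.integer(ceiling(0.5 * max_eq)))
      entitled <- stats::runif(pool_n) < config$entitled_share
      antichol <- stats::runif(pool_n) < config$anticholinergic_share
      m <- unname(mult[ag]); if (is.na(m)) m <- 1
      chunks <- list()
      for (yi in seq_len(nrow(sub))) {
        yr <- sub$year[yi]; e <- sub$equivalents[yi]
        for (cat in EVENT_CATEGORIES) {
          lambda <- config$event_rates[[cat]] * m * e
          n <- if (lambda > 0) stats::rpois(1L, lambda) else 0L
          if (n == 0L) next
          if (cat == "drug_purchase") {
            idx <- sample.int(pool_n, n, replace = TRUE)
            rows <- data.table(
              person_id = sprintf("%s|%s|D%06d", ag, sx, idx),
              year = yr, category = cat, primary_icd10 = "",
              quantity = round(stats::rgamma(n, shape = 2,
                                             scale = config$mean_purchase_eur / 2), 2),
              reimbursement_entitled = entitled[idx],
              uses_anticholinergic = antichol[idx],
              age_group = ag, sex = sx
            )
          } else {
            is_copd <- stats::runif(n) < config$copd_diagnosis_share
            code <- character(n)
            if (any(is_copd)) {
              code[is_copd] <- sample(COPD_CODE_POOL, sum(is_copd),
                                      replace = TRUE, prob = COPD_CODE_PROBS)
            }
            if (any(!is_copd)) {
              code[!is_copd] <- sample(config$distractor_codes, sum(!is_copd),
                                       replace = TRUE)
            }
            if (cat == "disability_pension") {
              ## unique person per pension record within a year
              idx <- sample.int(max(pool_n, n), n, replace = FALSE)
              pid <- sprintf("%s|%s|P%06d", ag, sx, idx)
            } else {
              idx <- sample.int(pool_n, n, replace = TRUE)
              pid <- sprintf("%s|%s|C%06d", ag, sx, idx)
            }
            rows <- data.table(
              person_id = pid, year = yr, category = cat,
              primary_icd10 = code, quantity = 1,
              reimbursement_entitled = NA,
              uses_anticholinergic = NA,
              age_group = ag, sex = sx
            )
          }
          chunks[[length(chunks) + 1L]] <- rows
        }
      }
      out[[si]] <- if (length(chunks)) rbindlist(chunks) else NULL
    }
    ev <- rbindlist(out[!vapply(out, is.null, logical(1))])
    if (nrow(ev) == 0) ev <- empty_register_events()
    ev[]
  })
}

## zero-row event table with the full schema
empty_register_events <- function() {
  data.table(
    person_id = character(), year = integer(), category = character(),
    primary_icd10 = character(), quantity = numeric(),
    reimbursement_entitled = logical(), uses_anticholinergic = logical(),
    age_group = character(), sex = character()
  )
}

#' Validate a register-event table against its invariants
#'
#' Checks column presence and types, non-negative quantities, known
#' categories and uniqueness of disability-pension records per
#' person-year.
#'
#' @param events a `data.table` of register events.
#' @return invisibly `TRUE`; errors otherwise.
#' @export
validate_register_events <- function(events) {
  events <- as.data.table(events)
  need <- names(empty_register_events())
  miss <- setdiff(need, names(events))
  if (length(miss)) abort("events: missing column(s): %s", paste(miss, collapse = ", "))
  if (!all(events$category %in% EVENT_CATEGORIES)) {
    abort("field 'category': unknown event category")
  }
  check_nonneg(events$quantity, "quantity")
  dp <- events[category == "disability_pension"]
  if (nrow(dp) && anyDuplicated(dp[, .(person_id, year)])) {
    abort("field 'person_id': disability_pension records must be unique per person-year")
  }
  invisible(TRUE)
}

#' Synthetic price-index series at a constant annual rate
#'
#' `index(base_year) = 100`; `index(y) = 100 * (1 + rate)^(y - base)`.
#'
#' @param years integer vector of years to cover (must contain
#'   `base_year`).
#' @param annual_rate annual inflation fraction, > -1.
#' @param base_year reference year (default the first year).
#' @return a [price_index_series()].
#' @export
#' @examples
#' generate_price_index(2006:2030, 0.02)
generate_price_index <- function(years, annual_rate, base_year = min(years)) {
  years <- as.integer(years)
  if (length(years) == 0) abort("field 'years': empty year range")
  if (!is.finite(annual_rate) || annual_rate <= -1) {
    abort("field 'annual_rate': must be > -1")
  }
  idx <- 100 * (1 + annual_rate)^(years - as.integer(base_year))
  price_index_series(years, idx, base_year)
}

#' Synthetic smoking-prevalence series with linear drift
#'
#' Starting from base-year fractions, each stratum-category fraction
#' drifts linearly by a stated number of percentage points per year,
#' clamped to `[0, 1]`; the four-category sum is capped at 1 by
#' truncating the largest category (deterministically, ties broken in
#' [SMOKING_CATEGORIES] order).
#'
#' @param base `data.table` with columns `age_group`, `sex`,
#'   `category`, `fraction`: the fractions in the first year.
#' @param years integer vector of years; `years[1]` is the base year.
#' @param slope_pp_per_year drift in percentage points per year: a
#'   scalar, a vector named by smoking category, or a `data.table`
#'   (`age_group`, `sex`, `category`, `slope`).
#' @return a `data.table` with columns `year`, `age_group`, `sex`,
#'   `category`, `fraction`.
#' @export
generate_smoking_series <- function(base, years, slope_pp_per_year = 0) {
  base <- as.data.table(base)
  check_fraction(base$fraction, "fraction")
  years <- as.integer(years)
  if (length(years) == 0) abort("field 'years': empty year range")

  if (is.data.frame(slope_pp_per_year)) {
    sl <- as.data.table(slope_pp_per_year)
    base <- merge(base, sl, by = c("age_group", "sex", "category"),
                  all.x = TRUE)
    base[is.na(slope), slope := 0]
  } else if (!is.null(names(slope_pp_per_year))) {
    base[, slope := 0]
    for (cat in names(slope_pp_per_year)) {
      base[category == cat, slope := slope_pp_per_year[[cat]]]
    }
  } else {
    base[, slope := slope_pp_per_year]
  }

  grid <- base[, .(year = years), by = .(age_group, sex, category, fraction, slope)]
  grid[, fraction := pmin(1, pmax(0, fraction + slope / 100 * (year - years[1])))]
  grid[, slope := NULL]
  cap_fraction_sum(grid)
}

## cap the four-category sum at 1 by truncating the largest category;
## ties broken in SMOKING_CATEGORIES order; iterates in the pathological
## case where one truncation is not enough
cap_fraction_sum <- function(dt) {
  dt <- as.data.table(dt)
  dt[, category := factor(category, levels = SMOKING_CATEGORIES)]
  setorder(dt, year, age_group, sex, category)
  trim <- function(f) {
    for (i in 1:4) {
      excess <- sum(f) - 1
      if (excess <= 1e-12) break
      j <- which.max(f)  # first maximum = earliest category on ties
      f[j] <- max(0, f[j] - excess)
    }
    f
  }
  dt[, fraction := trim(fraction), by = .(year, age_group, sex)]
  dt[, category := as.character(category)]
  dt[]
}
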