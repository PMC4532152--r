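#' Top-down cost accounting
#'
#' The historical accounting stage: filter register events down to
#' those caused by COPD, price care utilisation with inflation-adjusted
#' unit costs, convert allowance days and pension records into lost
#' man-years, and assemble integer-Euro cost breakdowns.
#'
#' @name cost_accounting
NULL

## COPD = ICD-10 rubrics J43 (emphysema) and J44 (COPD); prefix match
## so that subcodes (J44.0, ...) qualify
is_copd_code <- function(code) {
  startsWith(code, "J43") | startsWith(code, "J44")
}

#' Filter register events to COPD-caused care and benefit events
#'
#' Keeps hospital-day, outpatient-visit, sickness-allowance and
#' disability-pension events whose primary (cause) ICD-10 code starts
#' with J43 or J44.  Drug purchases are never selected here: the
#' medicines register carries no diagnoses, see
#' [filter_copd_medication()].  Only the `primary_icd10` field is
#' consulted; episodes where COPD appears as a secondary diagnosis are
#' not attributed.
#'
#' Occurrences of J33 among allowance/pension cause codes are reported
#' with a warning (a known register-coding pitfall: J33 is a nasal
#' polyp rubric that is easily mistyped for J43) but are not retained.
#'
#' @param events register-event `data.table`.
#' @return the retained subset, same columns.
#' @export
filter_copd_events <- function(events) {
  events <- as.data.table(events)
  if (nrow(events) == 0) return(events)
  care <- events$category != "drug_purchase"
  j33 <- care & events$category %in%
    c("sickness_allowance_day", "disability_pension") &
    startsWith(events$primary_icd10, "J33")
  if (any(j33)) {
    warning(sprintf(
      "%d allowance/pension event(s) carry cause code J33 (nasal polyp); likely a miscoding of J43 -- not retained",
      sum(j33)), call. = FALSE)
  }
  events[care & is_copd_code(events$primary_icd10)]
}

#' Filter drug purchases attributable to COPD
#'
#' The medicines register holds no diagnoses, so COPD medication is
#' identified through two person-level flags: special-reimbursement
#' entitlement for obstructive pulmonary disease AND inhaled
#' anticholinergic use (which separates COPD from asthma within the
#' joint entitlement group).  All purchases of a qualifying person
#' qualify, whatever the individual product.
#'
#' @param events register-event `data.table`.
#' @return the retained drug-purchase subset.
#' @export
filter_copd_medication <- function(events) {
  events <- as.data.table(events)
  if (nrow(events) == 0) return(events)
  events[category == "drug_purchase" &
           reimbursement_entitled %in% TRUE &
           uses_anticholinergic %in% TRUE]
}

#' Summarise filtered utilisation
#'
#' Sums event quantities per year (optionally per stratum): hospital
#' days by sector, outpatient visits, sickness-allowance days,
#' disability-pension person-years, and the EUR total of retained drug
#' purchases.
#'
#' @param events already-filtered events (union of
#'   [filter_copd_events()] and [filter_copd_medication()] output).
#' @param by grouping columns, default `"year"`; use
#'   `c("year", "age_group", "sex")` for stratum-level summaries.
#' @param years optional integer vector; when given, the summary covers
#'   exactly these years, filling zeros where no events occurred.
#' @return a `data.table` keyed by `by` with columns
#'   `phc_hospital_days`, `shc_hospital_days`, `shc_outpatient_visits`,
#'   `sickness_allowance_days`, `disability_pension_subjects`,
#'   `medication_cost`.
#' @export
summarise_utilisation <- function(events, by = "year", years = NULL) {
  events <- as.data.table(events)
  sum_cat <- function(cat) {
    events[category == cat, .(v = sum(quantity)), by = by]
  }
  pieces <- list(
    phc_hospital_days = "phc_hospital_day",
    shc_hospital_days = "shc_hospital_day",
    shc_outpatient_visits = "shc_outpatient_visit",
    sickness_allowance_days = "sickness_allowance_day",
    disability_pension_subjects = "disability_pension",
    medication_cost = "drug_purchase"
  )
  keys <- unique(events[, ..by])
  if (!is.null(years)) {
    extra <- setdiff(by, "year")
    if (length(extra)) {
      strata <- unique(events[, ..extra])
      if (nrow(strata) > 0) {
        grid <- strata[, .(year = as.integer(years)), by = extra]
        setcolorder(grid, by)
        keys <- unique(rbind(grid, keys))
      }
    } else {
      keys <- unique(rbind(data.table(year = as.integer(years)), keys))
    }
  }
  out <- keys
  for (col in names(pieces)) {
    s <- sum_cat(pieces[[col]])
    out <- merge(out, s, by = by, all.x = TRUE)
    setnames(out, "v", col)
    out[is.na(get(col)), (col) := 0]
  }
  setorderv(out, by)
  out[]
}

#' Price utilisation into direct cost components
#'
#' Per year (and any extra grouping columns present): outpatient,
#' SHC-hospital and PHC-hospital costs are counts times the
#' price-index-adjusted unit cost for that year; medication cost is
#' passed through from the register EUR totals (the medicines
#' statistics already price drugs in each year's Euros).
#'
#' @param u a [summarise_utilisation()] table.
#' @param costs a [unit_cost_table()].
#' @param index a [price_index_series()] covering every year of `u`.
#' @return `data.table` with the grouping columns of `u` plus
#'   `outpatient_shc`, `hospital_shc`, `hospital_phc`, `medication`,
#'   `total_direct` (exact doubles; rounding happens only in
#'   [assemble_breakdown()]).
#' @export
compute_direct_costs <- function(u, costs, index) {
  stopifnot(inherits(costs, "unit_cost_table"))
  u <- as.data.table(u)
  out <- copy(u)
  out[, outpatient_shc := shc_outpatient_visits *
        adjust_unit_cost(costs$shc_outpatient_visit, year, index)]
  out[, hospital_shc := shc_hospital_days *
        adjust_unit_cost(costs$shc_hospital_day, year, index)]
  out[, hospital_phc := phc_hospital_days *
        adjust_unit_cost(costs$phc_hospital_day, year, index)]
  out[, medication := medication_cost]
  out[, total_direct := outpatient_shc + hospital_shc + hospital_phc + medication]
  drop <- intersect(names(out), c(
    "phc_hospital_days", "shc_hospital_days", "shc_outpatient_visits",
    "sickness_allowance_days", "disability_pension_subjects",
    "medication_cost"))
  out[, (drop) := NULL]
  out[]
}

#' Convert lost productivity into indirect cost components
#'
#' Sickness-allowance days are divided by a working-days-per-year
#' divisor to yield lost man-years; disability-pension person-years are
#' taken as-is.  Both are valued at the (optionally index-adjusted)
#' lost-man-year unit cost.
#'
#' @param u a [summarise_utilisation()] table.
#' @param costs a [unit_cost_table()].
#' @param days_per_man_year working days per man-year (> 0); default
#'   260.
#' @param index optional [price_index_series()]; when supplied the
#'   man-year cost is restated in each year's Euros, otherwise the
#'   reference-year cost is applied to every year.
#' @return `data.table` with grouping columns plus
#'   `sickness_allowance`, `disability_pension`, `total_indirect`.
#' @export
compute_indirect_costs <- function(u, costs, days_per_man_year = 260,
                                   index = NULL) {
  stopifnot(inherits(costs, "unit_cost_table"))
  check_positive(days_per_man_year, "days_per_man_year")
  u <- as.data.table(u)
  out <- copy(u)
  my_cost <- if (is.null(index)) costs$lost_man_year else
    adjust_unit_cost(costs$lost_man_year, out$year, index)
  out[, sickness_allowance :=
        sickness_allowance_days / days_per_man_year * my_cost]
  out[, disability_pension := disability_pension_subjects * my_cost]
  out[, total_indirect := sickness_allowance + disability_pension]
  drop <- intersect(names(out), c(
    "phc_hospital_days", "shc_hospital_days", "shc_outpatient_visits",
    "sickness_allowance_days", "disability_pension_subjects",
    "medication_cost"))
  out[, (drop) := NULL]
  out[]
}

#' Assemble an integer-Euro cost breakdown
#'
#' Joins direct and indirect components by year, rounds every component
#' half-up to integer Euros, and recomputes the three totals from the
#' rounded components, so that additivity (`total_direct` = sum of its
#' four components; `total_indirect` = sum of its two; `total` = both)
#' holds exactly in the published integer-Euro representation.
#' Rounding happens here and nowhere earlier.
#'
#' @param direct output of [compute_direct_costs()] (per year).
#' @param indirect output of [compute_indirect_costs()] (same years).
#' @return a `data.table` of class `cost_breakdown` with columns
#'   `year`, `outpatient_shc`, `hospital_shc`, `hospital_phc`,
#'   `medication`, `total_direct`, `sickness_allowance`,
#'   `disability_pension`, `total_indirect`, `total`.
#' @export
assemble_breakdown <- function(direct, indirect) {
  direct <- as.data.table(direct); indirect <- as.data.table(indirect)
  if (!setequal(direct$year, indirect$year) ||
      nrow(direct) != nrow(indirect)) {
    abort("direct and indirect cost tables cover different years")
  }
  b <- merge(direct[, .(year, outpatient_shc, hospital_shc, hospital_phc,
                        medication)],
             indirect[, .(year, sickness_allowance, disability_pension)],
             by = "year")
  comp <- c("outpatient_shc", "hospital_shc", "hospital_phc", "medication",
            "sickness_allowance", "disability_pension")
  b[, (comp) := lapply(.SD, round_half_up), .SDcols = comp]
  b[, total_direct := outpatient_shc + hospital_shc + hospital_phc + medication]
  b[, total_indirect := sickness_allowance + disability_pension]
  b[, total := total_direct + total_indirect]
  setcolorder(b, c("year", "outpatient_shc", "hospital_shc", "hospital_phc",
                   "medication", "total_direct", "sickness_allowance",
                   "disability_pension", "total_indirect", "total"))
  setattr(b, "class", c("cost_breakdown", class(b)))
  b[]
}

#' Normalise a value per 100,000 inhabitants
#'
#' `value * 100000 / population`, rounded half-up to integer, the
#' convention of national per-capita cost tables.
#'
#' @param value EUR amounts or counts (vectorised).
#' @param population inhabitant count (> 0), recycled.
#' @return integer-valued numeric vector.
#' @export
#' @examples
#' per_capita(110119638, 5132320)  # 2145611
per_capita <- function(value, population) {
  check_positive(population, "population")
  round_half_up(value * 1e5 / population)
}

#' Signed percent change, rounded for reporting
#'
#' `100 * (after - before) / before`, rounded half-up to integer by
#' default (the convention used for narrative statements such as "a 17%
#' increase").
#'
#' @param before baseline value (> 0).
#' @param after comparison value.
#' @param digits decimal places to keep (default 0).
#' @return numeric vector.
#' @export
#' @examples
#' percent_change(58986, 69021)   # +17
#' percent_change(68231, 32446)   # -52
percent_change <- function(before, after, digits = 0) {
  check_positive(before, "before")
  round_half_up(100 * (after - before) / before, digits)
}
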