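#' Unit-cost table for health-care services and lost man-years
#'
#' Reference-year unit costs driving the top-down costing: Euros per
#' hospital day in primary health care (PHC) and secondary health care
#' (SHC), per SHC outpatient visit, and per lost man-year of
#' productivity.  Defaults are the published Finnish 2006 unit costs
#' (142 / 590 / 200 / 24,600 EUR).  Unit costs for other years are
#' derived by price-index adjustment, see [adjust_unit_cost()].
#'
#' @param phc_hospital_day EUR per day in hospital, primary care.
#' @param shc_hospital_day EUR per day in hospital, secondary care.
#' @param shc_outpatient_visit EUR per secondary-care outpatient visit.
#' @param lost_man_year EUR per lost man-year (sickness allowance or
#'   disability pension).
#' @param reference_year calendar year the costs are quoted in.
#' @return an object of class `unit_cost_table`.
#' @export
#' @examples
#' unit_cost_table()
unit_cost_table <- function(phc_hospital_day = 142,
                            shc_hospital_day = 590,
                            shc_outpatient_visit = 200,
                            lost_man_year = 24600,
                            reference_year = 2006) {
  x <- list(
    phc_hospital_day = as.numeric(phc_hospital_day),
    shc_hospital_day = as.numeric(shc_hospital_day),
    shc_outpatient_visit = as.numeric(shc_outpatient_visit),
    lost_man_year = as.numeric(lost_man_year),
    reference_year = as.integer(reference_year)
  )
  for (f in c("phc_hospital_day", "shc_hospital_day",
              "shc_outpatient_visit", "lost_man_year")) {
    check_positive(x[[f]], f)
  }
  structure(x, class = "unit_cost_table")
}

#' @export
print.unit_cost_table <- function(x, ...) {
  cat(sprintf("Unit costs (EUR, %d):\n", x$reference_year))
  cat(sprintf("  hospital day, primary care   %8.0f\n", x$phc_hospital_day))
  cat(sprintf("  hospital day, secondary care %8.0f\n", x$shc_hospital_day))
  cat(sprintf("  outpatient visit, SHC        %8.0f\n", x$shc_outpatient_visit))
  cat(sprintf("  lost man-year                %8.0f\n", x$lost_man_year))
  invisible(x)
}

#' Read a unit-cost table from JSON
#'
#' @param path JSON file with the fields of [unit_cost_table()].
#' @return a `unit_cost_table`.
#' @export
read_unit_costs <- function(path) {
  if (!file.exists(path)) abort("unit-cost file not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(unit_cost_table, x)
}

#' Price-index series
#'
#' A deflator series (reference year = 100) used to restate
#' reference-year unit costs in other years' nominal Euros, emulating a
#' price index on public expenditure.
#'
#' @param years integer vector of calendar years.
#' @param index numeric vector of index values, same length as `years`;
#'   must include a value of 100 at `reference_year`.
#' @param reference_year the base year of the index.
#' @return a `data.table` of class `price_index_series` with columns
#'   `year`, `index` and attribute `reference_year`.
#' @seealso [generate_price_index()] for the synthetic constant-rate
#'   series.
#' @export
price_index_series <- function(years, index, reference_year) {
  years <- as.integer(years)
  if (length(years) == 0) abort("field 'years': empty year range")
  if (length(years) != length(index)) {
    abort("field 'index': length must match 'years'")
  }
  if (anyDuplicated(years)) abort("field 'years': duplicated years")
  check_positive(index, "index")
  reference_year <- as.integer(reference_year)
  if (!reference_year %in% years) {
    abort("field 'reference_year': year %d absent from the series",
          reference_year)
  }
  dt <- data.table(year = years, index = as.numeric(index))
  setkey(dt, year)
  setattr(dt, "reference_year", reference_year)
  setattr(dt, "class", c("price_index_series", class(dt)))
  dt[]
}

## index value lookup; missing years are an error, never extrapolated
index_value <- function(series, year) {
  year <- as.integer(year)
  i <- match(year, series$year)
  if (anyNA(i)) {
    abort("price index has no value for year(s): %s",
          paste(year[is.na(i)], collapse = ", "))
  }
  series$index[i]
}

#' Restate a reference-year unit cost in another year's Euros
#'
#' `cost * index(target_year) / index(reference_year)`.  Missing index
#' years raise an explicit lookup error; the series is never silently
#' extrapolated or interpolated.
#'
#' @param cost unit cost in reference-year Euros.
#' @param target_year year (vector) to restate the cost in.
#' @param index a [price_index_series()].
#' @return numeric vector of adjusted costs.
#' @export
#' @examples
#' idx <- generate_price_index(2000:2006, 0.02, base_year = 2006)
#' adjust_unit_cost(590, 2006, idx)  # identity at the reference year
adjust_unit_cost <- function(cost, target_year, index) {
  stopifnot(inherits(index, "price_index_series"))
  ref <- index_value(index, attr(index, "reference_year"))
  cost * index_value(index, target_year) / ref
}

#' Read a price-index series from a delimited file
#'
#' The file must have columns `year` and `index`; the reference year is
#' the (unique) year whose index value equals 100.
#'
#' @param path tab-separated file.
#' @return a [price_index_series()].
#' @export
read_price_index <- function(path) {
  dt <- read_table(path, schema_price_index())
  ref <- dt$year[abs(dt$index - 100) < 1e-9]
  if (length(ref) != 1) {
    abort("price-index file must contain exactly one year with index 100 (the reference year); found %d", length(ref))
  }
  price_index_series(dt$year, dt$index, ref)
}
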