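#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run: where the registers come
#' from (a directory of files, or the seeded synthetic generator),
#' unit costs, price index, smoking and population series, and the
#' projection parameters.
#'
#' @param sim a [sim_config()]; default [default_sim_config()] with
#'   `seed`.  Ignored when `registers_dir` is given.
#' @param registers_dir optional directory of register files (see
#'   [read_registers()]); when given, `smoking` and `population` must
#'   also be supplied.
#' @param unit_costs a [unit_cost_table()] or path to its JSON file.
#' @param price_index a [price_index_series()], a path to a price-index
#'   file, or `NULL` to generate a constant-rate series at
#'   `historical_inflation`.
#' @param smoking,population historical series (`data.table`s or file
#'   paths); default: taken from `sim`.
#' @param population_projection projected population per year-stratum
#'   (`data.table` or path); `NULL` extrapolates the historical
#'   population linearly per stratum.
#' @param base_year standardisation / inflation base year (default
#'   2006; must be a simulated/observed year).
#' @param projection_years years to project (default 2007:2030).
#' @param inflation annual inflation fraction applied to projected
#'   costs (default 0.02).
#' @param historical_inflation annual rate of the generated price index
#'   when none is supplied (default 0.02).
#' @param retirement_age cutoff for indirect-cost strata (default 65).
#' @param weights a [smoking_weights()] vector.
#' @param days_per_man_year sickness-day to man-year divisor (default
#'   260).
#' @param extrapolation `"linear"` or `"proportional"` smoking-trend
#'   mode.
#' @param seed integer seed for every source of randomness.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = NULL, registers_dir = NULL,
                            unit_costs = unit_cost_table(),
                            price_index = NULL,
                            smoking = NULL, population = NULL,
                            population_projection = NULL,
                            base_year = 2006,
                            projection_years = 2007:2030,
                            inflation = 0.02,
                            historical_inflation = 0.02,
                            retirement_age = 65,
                            weights = smoking_weights(),
                            days_per_man_year = 260,
                            extrapolation = c("linear", "proportional"),
                            seed = 1L) {
  extrapolation <- match.arg(extrapolation)
  projection_years <- as.integer(projection_years)
  if (length(projection_years) && is.unsorted(projection_years)) {
    abort("field 'projection_years': years must be ordered")
  }
  if (is.character(unit_costs)) unit_costs <- read_unit_costs(unit_costs)
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  if (is.character(price_index)) price_index <- read_price_index(price_index)
  if (is.character(smoking)) smoking <- read_table(smoking, schema_smoking())
  if (is.character(population)) {
    population <- read_table(population, schema_population())
  }
  if (is.character(population_projection)) {
    population_projection <- read_table(population_projection,
                                        schema_population())
  }
  if (!is.null(registers_dir)) {
    if (!dir.exists(registers_dir)) {
      abort("field 'registers_dir': directory not found: %s", registers_dir)
    }
    if (is.null(smoking) || is.null(population)) {
      abort("field 'registers_dir': supplying registers requires 'smoking' and 'population' series")
    }
  }
  if (is.null(sim) && is.null(registers_dir)) {
    sim <- default_sim_config(seed = seed)
  }
  structure(list(
    sim = sim, registers_dir = registers_dir, unit_costs = unit_costs,
    price_index = price_index, smoking = smoking, population = population,
    population_projection = population_projection,
    base_year = as.integer(base_year),
    projection_years = projection_years,
    inflation = inflation, historical_inflation = historical_inflation,
    retirement_age = retirement_age, weights = validate_weights(weights),
    days_per_man_year = days_per_man_year,
    extrapolation = extrapolation, seed = as.integer(seed)
  ), class = "pipeline_config")
}

## linear per-stratum extrapolation of population counts, clamped at 0
extrapolate_population <- function(history, target_years) {
  history <- as.data.table(history)
  fits <- history[, ols_line(year, count), by = .(age_group, sex)]
  grid <- fits[, .(year = as.integer(target_years)),
               by = .(age_group, sex, intercept, slope)]
  grid[, count := pmax(0, intercept + slope * year)]
  grid[, c("intercept", "slope") := NULL]
  setcolorder(grid, c("year", "age_group", "sex", "count"))
  grid[]
}

## melt a cost_breakdown into the tidy (year, component, euros) format
tidy_breakdown <- function(breakdown, population_by_year = NULL) {
  long <- melt(as.data.table(breakdown), id.vars = "year",
               variable.name = "component", value.name = "euros",
               variable.factor = FALSE)
  if (!is.null(population_by_year)) {
    long <- merge(long, population_by_year, by = "year")
    long[, euros_per_100k := per_capita(euros, population)]
    long[, population := NULL]
  }
  setorder(long, year)
  long[]
}

#' Run the full accounting + projection pipeline
#'
#' Stages: (1) obtain register events (simulate with the configured
#' seed, or read files); (2) filter COPD care events and COPD
#' medication purchases, logging record counts in and out of each
#' filter; (3) summarise utilisation and assemble the historical cost
#' breakdown; (4) standardise base-year stratum costs per weighted
#' smoker-equivalent; (5) extrapolate smoking fractions and population,
#' and project future costs with inflation; (6) summarise and
#' optionally write every table plus a JSON summary.  Identical
#' configuration (including seed) yields byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory; when given, all tables are
#'   written there as tab-separated text plus `summary.json`.
#' @param quiet suppress stage logging (default `FALSE`).
#' @return (invisibly) a list: `events`, `utilisation`, `breakdown`,
#'   `costs_tidy`, `standardised`, `smoking_projection`,
#'   `population_projection`, `projection`, `summary`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(fmt, ...) if (!quiet) message(sprintf(paste0("[copdcosts] ", fmt), ...))

  ## stage 1: registers
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  events <- stage("registers", {
    if (!is.null(config$registers_dir)) {
      ev <- read_registers(config$registers_dir)
      say("read %d register events from %s", nrow(ev), config$registers_dir)
      ev
    } else {
      ev <- generate_registers(config$sim)
      say("simulated %d register events (seed %d)", nrow(ev), config$sim$seed)
      ev
    }
  })
  smoking <- config$smoking %||% config$sim$smoking
  population <- config$population %||% config$sim$population
  hist_years <- sort(unique(as.data.table(population)$year))
  if (!config$base_year %in% hist_years) {
    abort("stage 'registers' failed: base year %d not covered by the historical series",
          config$base_year)
  }

  ## stage 2: filters (auditable in/out counts)
  care <- stage("diagnosis-filter", filter_copd_events(events))
  say("diagnosis filter: %d events in, %d retained",
      sum(events$category != "drug_purchase"), nrow(care))
  med <- stage("medication-filter", filter_copd_medication(events))
  say("medication filter: %d purchases in, %d retained",
      sum(events$category == "drug_purchase"), nrow(med))
  kept <- rbind(care, med)

  ## stage 3: historical accounting
  index <- config$price_index %||% generate_price_index(
    seq(min(hist_years), max(c(hist_years, config$projection_years))),
    config$historical_inflation, base_year = config$base_year)
  acct <- stage("accounting", {
    u <- summarise_utilisation(kept, years = hist_years)
    direct <- compute_direct_costs(u, config$unit_costs, index)
    indirect <- compute_indirect_costs(u, config$unit_costs,
                                       config$days_per_man_year, index)
    breakdown <- assemble_breakdown(direct, indirect)
    pop_year <- as.data.table(population)[, .(population = sum(count)),
                                          by = year]
    list(u = u, breakdown = breakdown,
         tidy = tidy_breakdown(breakdown, pop_year))
  })
  say("accounting: %d year(s), total %d EUR in %d",
      nrow(acct$breakdown), acct$breakdown[year == config$base_year]$total,
      config$base_year)

  ## accounting-only runs skip standardisation and projection
  if (length(config$projection_years) == 0) {
    bundle <- list(events = events, utilisation = acct$u,
                   breakdown = acct$breakdown, costs_tidy = acct$tidy,
                   standardised = NULL, smoking_projection = NULL,
                   population_projection = NULL, projection = NULL,
                   summary = NULL)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_registers(events, file.path(out_dir, "registers"))
      write_table(acct$u, file.path(out_dir, "utilisation.tsv"))
      write_table(acct$breakdown, file.path(out_dir, "cost_breakdown.tsv"))
      write_table(acct$tidy, file.path(out_dir, "costs.tsv"))
      say("wrote accounting bundle to %s", out_dir)
    }
    return(invisible(bundle))
  }

  ## stage 4: standardisation at the base year
  std <- stage("standardisation", {
    u_s <- summarise_utilisation(
      kept[year == config$base_year],
      by = c("year", "age_group", "sex"), years = config$base_year)
    d_s <- compute_direct_costs(u_s, config$unit_costs, index)
    i_s <- compute_indirect_costs(u_s, config$unit_costs,
                                  config$days_per_man_year, index)
    base_costs <- merge(
      d_s[, .(age_group, sex, direct_eur = total_direct)],
      i_s[, .(age_group, sex, indirect_eur = total_indirect)],
      by = c("age_group", "sex"))
    ## strata with no base-year events have zero cost, not missing cost
    all_strata <- unique(as.data.table(population)[, .(age_group, sex)])
    base_costs <- merge(all_strata, base_costs,
                        by = c("age_group", "sex"), all.x = TRUE)
    base_costs[is.na(direct_eur), direct_eur := 0]
    base_costs[is.na(indirect_eur), indirect_eur := 0]
    eq <- equivalents_table(
      as.data.table(smoking)[year == config$base_year],
      as.data.table(population)[year == config$base_year],
      config$weights)
    standardise_costs(base_costs, eq, base_year = config$base_year)
  })

  ## stage 5: projection
  proj <- stage("projection", {
    frac <- extrapolate_fractions(smoking, config$projection_years,
                                  method = config$extrapolation)
    pop_proj <- config$population_projection %||%
      extrapolate_population(population, config$projection_years)
    res <- project_costs(std, frac, pop_proj, config$weights,
                         config$inflation, config$base_year,
                         config$retirement_age)
    list(frac = frac, pop = pop_proj, res = res)
  })
  summary <- stage("summary", summarise_projection(proj$res))
  say("projection: %d-%d, %+.0f%% total change",
      summary$first_year, summary$last_year, summary$pct_change)

  bundle <- list(
    events = events, utilisation = acct$u, breakdown = acct$breakdown,
    costs_tidy = acct$tidy, standardised = std,
    smoking_projection = proj$frac, population_projection = proj$pop,
    projection = proj$res, summary = summary
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_registers(events, file.path(out_dir, "registers"))
    write_table(acct$u, file.path(out_dir, "utilisation.tsv"))
    write_table(acct$breakdown, file.path(out_dir, "cost_breakdown.tsv"))
    write_table(acct$tidy, file.path(out_dir, "costs.tsv"))
    write_table(std, file.path(out_dir, "standardised_costs.tsv"))
    write_table(proj$frac, file.path(out_dir, "smoking_projection.tsv"))
    write_table(proj$pop, file.path(out_dir, "population_projection.tsv"))
    write_table(proj$res, file.path(out_dir, "projection.tsv"))
    jsonlite::write_json(
      list(
        historical = list(
          years = range(hist_years),
          total_eur_by_year = setNames(as.list(acct$breakdown$total),
                                       acct$breakdown$year)
        ),
        projection = summary
      ),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote report bundle to %s", out_dir)
  }
  invisible(bundle)
}

#' Historical accounting from an aggregate utilisation table
#'
#' Top-down costing straight from national utilisation totals (the
#' published-table route): no event filtering, just pricing.  Useful
#' when the register extracts themselves are unavailable but their
#' annual aggregates are published.
#'
#' @param u utilisation table with the columns of
#'   [summarise_utilisation()] output plus optionally `population`;
#'   `medication_cost` may be absent (treated as 0).
#' @param costs a [unit_cost_table()].
#' @param index a [price_index_series()].
#' @param days_per_man_year divisor for sickness-allowance days.
#' @return a `cost_breakdown`, with per-100,000 columns when
#'   `population` is present.
#' @export
accounting_from_utilisation <- function(u, costs = unit_cost_table(),
                                        index = NULL,
                                        days_per_man_year = 260) {
  u <- as.data.table(u)
  if (is.null(index)) {
    index <- price_index_series(u$year, rep(100, nrow(u)),
                                reference_year = u$year[1])
  }
  if (!"medication_cost" %in% names(u)) u[, medication_cost := 0]
  pop <- if ("population" %in% names(u)) u[, .(year, population)] else NULL
  u2 <- u[, setdiff(names(u), "population"), with = FALSE]
  direct <- compute_direct_costs(u2, costs, index)
  indirect <- compute_indirect_costs(u2, costs, days_per_man_year, index)
  b <- assemble_breakdown(direct, indirect)
  if (!is.null(pop)) {
    b <- merge(b, pop, by = "year")
    for (col in setdiff(names(b), c("year", "population"))) {
      b[, paste0(col, "_per_100k") := per_capita(get(col), population)]
    }
  }
  b[]
}

#' Path to a packaged example/fixture file
#'
#' @param file file name under `inst/extdata`; empty lists them.
#' @return a file path.
#' @export
#' @examples
#' copdcosts_example()
copdcosts_example <- function(file = "") {
  if (nzchar(file)) {
    system.file("extdata", file, package = "copdcosts", mustWork = TRUE)
  } else {
    list.files(system.file("extdata", package = "copdcosts"))
  }
}
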