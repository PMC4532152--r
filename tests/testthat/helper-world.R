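library(data.table)

## -- tiny synthetic worlds used across the suite ---------------------------

tiny_ages <- function() default_age_groups(from = 60, to = 70)  # 60-64, 65-69, 70+

tiny_smoking <- function(years = 1996:2006, ages = tiny_ages(),
                         active = 0.25) {
  base <- CJ(age_group = ages, sex = c("female", "male"))[
    , .(category = SMOKING_CATEGORIES,
        fraction = c(active, 0.02, 0.02, 0.04)),
    by = .(age_group, sex)]
  generate_smoking_series(base, years, 0)
}

tiny_population <- function(years = 1996:2006, ages = tiny_ages(),
                            count = 20000) {
  CJ(year = years, age_group = ages, sex = c("female", "male"))[
    , count := count][]
}

tiny_sim_config <- function(years = 1996:2006, seed = 1L,
                            rates = c(phc_hospital_day = 0.06,
                                      shc_hospital_day = 0.03,
                                      shc_outpatient_visit = 0.02,
                                      drug_purchase = 0.3,
                                      sickness_allowance_day = 0.06,
                                      disability_pension = 0.002),
                            ...) {
  sim_config(years = years,
             population = tiny_population(years),
             smoking = tiny_smoking(years),
             event_rates = rates, seed = seed, ...)
}

## single open-band stratum with an exact number of weighted equivalents
one_stratum_config <- function(equivalents = 1000, rate = 0.5,
                               category = "shc_hospital_day",
                               years = 2006L, seed = 1L, ...) {
  smoking <- data.table(year = rep(years, each = 4), age_group = "15+",
                        sex = "male", category = SMOKING_CATEGORIES,
                        fraction = c(1, 0, 0, 0))
  pop <- data.table(year = years, age_group = "15+", sex = "male",
                    count = equivalents)
  sim_config(years = years, population = pop, smoking = smoking,
             event_rates = setNames(rate, category), seed = seed, ...)
}

## hand-built event rows for filter / pricing tests
make_events <- function(category, primary_icd10 = "J44", quantity = 1,
                        year = 2006L, person_id = NULL,
                        reimbursement_entitled = NA,
                        uses_anticholinergic = NA,
                        age_group = "60-64", sex = "male") {
  if (length(category) == 0) return(copdcosts:::empty_register_events())
  n <- max(lengths(list(category, primary_icd10, quantity, year,
                        reimbursement_entitled, uses_anticholinergic)))
  if (is.null(person_id)) person_id <- sprintf("p%03d", seq_len(n))
  data.table(person_id = rep_len(person_id, n),
             year = as.integer(rep_len(year, n)),
             category = rep_len(category, n),
             primary_icd10 = rep_len(primary_icd10, n),
             quantity = as.numeric(rep_len(quantity, n)),
             reimbursement_entitled = rep_len(reimbursement_entitled, n),
             uses_anticholinergic = rep_len(uses_anticholinergic, n),
             age_group = rep_len(age_group, n),
             sex = rep_len(sex, n))
}

flat_index <- function(years = 1996:2006, reference_year = 2006) {
  price_index_series(years, rep(100, length(years)), reference_year)
}

## -- toy projection world: 2 strata, exact round numbers -------------------

toy_std <- function() {
  standardise_costs(
    data.table(age_group = c("60-64", "65+"), sex = "male",
               direct_eur = c(16000, 8000), indirect_eur = c(4000, 2000)),
    data.table(age_group = c("60-64", "65+"), sex = "male",
               equivalents = c(160, 80)),
    base_year = 2006)
}

toy_fractions <- function(years) {
  CJ(year = years, age_group = c("60-64", "65+"), sex = "male")[
    , .(category = SMOKING_CATEGORIES,
        fraction = c(0.10, 0.04, 0.02, 0.01)),
    by = .(year, age_group, sex)]
}

toy_population <- function(years) {
  CJ(year = years, age_group = c("60-64", "65+"), sex = "male")[
    , count := 1000][]
}

## -- published national fixtures (shipped under inst/extdata) --------------

fixture_utilisation <- function() {
  read_table(copdcosts_example("fi_copd_utilisation_1996_2006.tsv"),
             copdcosts:::schema_utilisation_fixture())
}

fixture_costs <- function() {
  read_table(copdcosts_example("fi_copd_costs_1996_2006.tsv"),
             copdcosts:::schema_cost_components())
}

## wide one-row-per-year view of the published cost components
fixture_costs_wide <- function() {
  dcast(fixture_costs(), year ~ component, value.var = "euros")
}
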