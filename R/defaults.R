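#' Default synthetic world
#'
#' A ready-made [sim_config()] emulating a small Nordic country over
#' 1996-2006: roughly 4.2 million inhabitants aged 15+, in 5-year
#' age-sex strata; smoking prevalence higher in men and declining by
#' about 0.3 percentage points per year; event rates per weighted
#' smoker-equivalent rising with age and scaled so that national event
#' totals land near the order of magnitude seen in published COPD
#' register studies (tens of thousands of hospital days and allowance
#' days, and roughly two thousand disability pensions, per year).
#'
#' The stratum-level rates are free parameters of the synthetic world:
#' no national statistics publish them, so they are stated once here
#' and never tuned against outputs.
#'
#' @param seed integer RNG seed.
#' @param years calendar years to simulate.
#' @return a [sim_config()].
#' @export
#' @examples
#' cfg <- default_sim_config(seed = 42)
#' ev <- generate_registers(cfg)
#' nrow(ev)
default_sim_config <- function(seed = 1L, years = 1996:2006) {
  ages <- default_age_groups()               # 15-19 ... 85+
  n_bands <- length(ages)
  ## population per sex in thousands, young to old (peaked mid-age,
  ## thinning towards 85+); totals ~2.1 M per sex
  per_band <- c(160, 160, 165, 165, 185, 190, 195, 190,
                185, 165, 130, 105, 90, 70, 45)[seq_len(n_bands)] * 1000
  pop0 <- data.table(
    age_group = rep(ages, times = 2),
    sex = rep(c("female", "male"), each = n_bands),
    count = rep(per_band, 2)
  )
  ## population drifts mildly older: +0.4 %/yr in 60+ bands, flat below
  pop <- pop0[, .(year = years), by = .(age_group, sex, count)]
  old <- age_band_lower(pop$age_group) >= 60
  pop[old, count := count * (1 + 0.004)^(year - years[1])]
  pop[, count := round(count)]

  ## base-year smoking fractions by age and sex
  lower <- age_band_lower(ages)
  male_active <- pmax(0.08, 0.34 - 0.0028 * (lower - 15))
  female_active <- pmax(0.04, 0.22 - 0.0022 * (lower - 15))
  base <- rbind(
    data.table(age_group = ages, sex = "male", category = "active",
               fraction = male_active),
    data.table(age_group = ages, sex = "female", category = "active",
               fraction = female_active),
    CJ(age_group = ages, sex = c("female", "male"))[
      , .(category = c("quit_1_3", "quit_3_5", "quit_5_10"),
          fraction = c(0.02, 0.02, 0.04)), by = .(age_group, sex)]
  )
  smoking <- generate_smoking_series(
    base, years,
    slope_pp_per_year = c(active = -0.3, quit_1_3 = 0.02,
                          quit_3_5 = 0.02, quit_5_10 = 0.05)
  )

  ## hospitalisation risk grows steeply with age
  age_mult <- data.table(
    age_group = ages,
    multiplier = pmin(3, pmax(0.25, (lower / 55)^1.5))
  )

  sim_config(
    years = years,
    population = pop,
    smoking = smoking,
    event_rates = c(
      phc_hospital_day = 0.066,
      shc_hospital_day = 0.031,
      shc_outpatient_visit = 0.019,
      drug_purchase = 0.33,
      sickness_allowance_day = 0.061,
      disability_pension = 0.0018
    ),
    age_multiplier = age_mult,
    copd_diagnosis_share = 0.8,
    entitled_share = 0.7,
    anticholinergic_share = 0.8,
    mean_purchase_eur = 120,
    seed = seed
  )
}
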