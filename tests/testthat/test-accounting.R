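test_that("diagnosis filter keeps exactly prefix-J43/J44 primary events and is idempotent", {
  expect_identical(nrow(filter_copd_events(make_events(character(0)))), 0L)

  ev <- make_events("shc_hospital_day",
                    primary_icd10 = c("J44", "J43.1", "J45", "J18", "I50"))
  kept <- filter_copd_events(ev)
  expect_identical(nrow(kept), 2L)
  expect_setequal(kept$primary_icd10, c("J44", "J43.1"))
  ## prefix match includes subcodes, excludes look-alikes
  sub <- make_events("phc_hospital_day",
                     primary_icd10 = c("J44.0", "J44.8", "J43", "J4", "J440x", "J33"))
  expect_identical(nrow(filter_copd_events(sub)), 4L)
  ## idempotence
  expect_identical(filter_copd_events(kept), kept)
  ## drug purchases never pass the diagnosis filter, even with a COPD code
  dr <- make_events("drug_purchase", primary_icd10 = "J44",
                    reimbursement_entitled = TRUE, uses_anticholinergic = TRUE)
  expect_identical(nrow(filter_copd_events(dr)), 0L)
})

test_that("J33 cause codes on allowance/pension events warn and are dropped", {
  ev <- make_events("sickness_allowance_day", primary_icd10 = c("J33", "J44"))
  expect_warning(kept <- filter_copd_events(ev), "J33")
  expect_identical(kept$primary_icd10, "J44")
})

test_that("medication filter is the (entitled AND anticholinergic) truth table, person-level", {
  expect_identical(nrow(filter_copd_medication(make_events(character(0)))), 0L)
  ev <- make_events("drug_purchase", primary_icd10 = "", quantity = 10,
                    reimbursement_entitled = c(TRUE, TRUE, FALSE, FALSE),
                    uses_anticholinergic = c(TRUE, FALSE, TRUE, FALSE))
  kept <- filter_copd_medication(ev)
  expect_identical(nrow(kept), 1L)
  expect_true(kept$reimbursement_entitled && kept$uses_anticholinergic)
  ## person-level rule: any purchase by a qualifying person qualifies,
  ## whatever the product; flags carry the person, not the drug
  person <- make_events("drug_purchase", primary_icd10 = "", quantity = c(55, 12),
                        person_id = "p1",
                        reimbursement_entitled = TRUE,
                        uses_anticholinergic = TRUE)
  expect_identical(nrow(filter_copd_medication(person)), 2L)
  ## idempotence
  expect_identical(filter_copd_medication(kept), kept)
  ## NA flags (care events mixed in) never pass
  mixed <- rbind(ev, make_events("shc_hospital_day"))
  expect_identical(nrow(filter_copd_medication(mixed)), 1L)
})

test_that("unit-cost adjustment is a pure index ratio with strict year lookup", {
  idx <- flat_index()
  expect_equal(adjust_unit_cost(590, 2006, idx), 590)  # reference year identity
  idx2 <- price_index_series(c(2000, 2006), c(95, 100), 2006)
  expect_equal(adjust_unit_cost(590, 2000, idx2), 560.50)
  expect_error(adjust_unit_cost(590, 1999, idx2), "1999")
  ## reference-year costs are exactly the published 2006 unit costs
  uc <- read_unit_costs(copdcosts_example("unit_costs_2006.json"))
  expect_equal(
    unlist(uc[c("phc_hospital_day", "shc_hospital_day",
                "shc_outpatient_visit", "lost_man_year")]),
    c(phc_hospital_day = 142, shc_hospital_day = 590,
      shc_outpatient_visit = 200, lost_man_year = 24600))
})

test_that("utilisation summary sums quantities per year with no leakage", {
  empty <- summarise_utilisation(make_events(character(0)), years = 2006)
  expect_identical(nrow(empty), 1L)
  expect_true(all(unlist(empty[, -1]) == 0))

  ev <- make_events("shc_hospital_day", quantity = c(2, 3, 5))
  expect_equal(summarise_utilisation(ev)$shc_hospital_days, 10)

  ## disjoint-year construction: each year gets only its own events
  multi <- rbind(
    make_events("phc_hospital_day", quantity = 4, year = 1996),
    make_events("phc_hospital_day", quantity = 7, year = 2006),
    make_events("drug_purchase", primary_icd10 = "", quantity = 99, year = 2006,
                reimbursement_entitled = TRUE, uses_anticholinergic = TRUE)
  )
  u <- summarise_utilisation(multi)
  expect_equal(u[u$year == 1996]$phc_hospital_days, 4)
  expect_equal(u[u$year == 2006]$phc_hospital_days, 7)
  expect_equal(u[u$year == 1996]$medication_cost, 0)
  expect_equal(u[u$year == 2006]$medication_cost, 99)
  ## stratum-level grouping keeps the same totals
  us <- summarise_utilisation(multi, by = c("year", "age_group", "sex"))
  expect_equal(sum(us$phc_hospital_days), 11)
})

test_that("direct costs price utilisation at adjusted unit costs", {
  u <- data.table(year = 2006L, phc_hospital_days = 0, shc_hospital_days = 0,
                  shc_outpatient_visits = 20115, sickness_allowance_days = 0,
                  disability_pension_subjects = 0, medication_cost = 0)
  d <- compute_direct_costs(u, unit_cost_table(), flat_index())
  expect_equal(d$outpatient_shc, 4023000)  # the published 2006 outpatient cell
  expect_equal(d$total_direct, 4023000)

  zero <- copy(u)[, shc_outpatient_visits := 0]
  expect_equal(compute_direct_costs(zero, unit_cost_table(), flat_index())$total_direct, 0)
})

test_that("indirect costs convert days and person-years into man-year Euros", {
  u <- data.table(year = 2006L, phc_hospital_days = 0, shc_hospital_days = 0,
                  shc_outpatient_visits = 0, sickness_allowance_days = 260,
                  disability_pension_subjects = 0, medication_cost = 0)
  i <- compute_indirect_costs(u, unit_cost_table(), days_per_man_year = 260)
  expect_equal(i$sickness_allowance, 24600)  # one man-year exactly

  u2 <- copy(u)[, `:=`(sickness_allowance_days = 0,
                       disability_pension_subjects = 1844)]
  i2 <- compute_indirect_costs(u2, unit_cost_table(), 260)
  ## direct multiplication; the published table implies fractional
  ## person-years (45,348,966), within 0.03% of this product
  expect_equal(i2$disability_pension, 1844 * 24600)
  expect_lt(abs(i2$disability_pension - 45348966) / 45348966, 3e-4)

  zero <- copy(u)[, sickness_allowance_days := 0]
  expect_equal(compute_indirect_costs(zero, unit_cost_table(), 260)$total_indirect, 0)
  expect_error(compute_indirect_costs(u, unit_cost_table(), 0), "days_per_man_year")
})

test_that("breakdown assembly rounds half-up once and is additive by construction", {
  direct <- data.table(year = 2006L, outpatient_shc = 100.5, hospital_shc = 0.49,
                       hospital_phc = 10.5, medication = 1.23,
                       total_direct = NA_real_)
  indirect <- data.table(year = 2006L, sickness_allowance = 2.5,
                         disability_pension = 0.4, total_indirect = NA_real_)
  b <- assemble_breakdown(direct, indirect)
  expect_equal(b$outpatient_shc, 101)
  expect_equal(b$hospital_shc, 0)
  expect_equal(b$hospital_phc, 11)
  expect_equal(b$medication, 1)
  expect_equal(b$sickness_allowance, 3)
  expect_equal(b$total_direct, 101 + 0 + 11 + 1)
  expect_equal(b$total_indirect, 3 + 0)
  expect_equal(b$total, b$total_direct + b$total_indirect)

  expect_error(assemble_breakdown(direct, copy(indirect)[, year := 1996L]),
               "different years")

  ## additivity holds for random fractional inputs
  set.seed(42)
  for (r in 1:20) {
    d <- data.table(year = 1:3, outpatient_shc = runif(3, 0, 1e6),
                    hospital_shc = runif(3, 0, 1e6),
                    hospital_phc = runif(3, 0, 1e6),
                    medication = runif(3, 0, 1e6))
    i <- data.table(year = 1:3, sickness_allowance = runif(3, 0, 1e6),
                    disability_pension = runif(3, 0, 1e6))
    bb <- assemble_breakdown(d, i)
    expect_equal(bb$total_direct,
                 bb$outpatient_shc + bb$hospital_shc + bb$hospital_phc + bb$medication)
    expect_equal(bb$total, bb$total_direct + bb$total_indirect)
    expect_true(all(bb[, -1] == round(bb[, -1])))
  }
})

test_that("per-capita and percent-change follow the published reporting conventions", {
  expect_equal(per_capita(110119638, 5132320), 2145611)
  expect_equal(per_capita(32446, 5276955), 615)
  expect_equal(per_capita(0, 123), 0)
  expect_error(per_capita(1, 0), "population")

  expect_equal(percent_change(58986, 69021), 17)
  expect_equal(percent_change(68231, 32446), -52)
  expect_equal(percent_change(5, 5), 0)
  expect_error(percent_change(0, 5), "before")
})

test_that("brute-force per-event pricing oracle matches compute_direct_costs", {
  set.seed(7)
  idx <- price_index_series(1996:2006, 100 * 1.018^(1996:2006 - 2006), 2006)
  uc <- unit_cost_table()
  cats <- c("phc_hospital_day", "shc_hospital_day", "shc_outpatient_visit",
            "drug_purchase")
  ev <- make_events(sample(cats, 50, replace = TRUE),
                    primary_icd10 = "J44",
                    quantity = sample(1:9, 50, replace = TRUE),
                    year = sample(1996:2006, 50, replace = TRUE),
                    reimbursement_entitled = TRUE, uses_anticholinergic = TRUE)
  ev[category == "drug_purchase", primary_icd10 := ""]
  kept <- rbind(filter_copd_events(ev), filter_copd_medication(ev))

  ## oracle: price every event on its own, then sum
  per_event <- vapply(seq_len(nrow(kept)), function(k) {
    e <- kept[k]
    switch(e$category,
      phc_hospital_day = e$quantity * adjust_unit_cost(uc$phc_hospital_day, e$year, idx),
      shc_hospital_day = e$quantity * adjust_unit_cost(uc$shc_hospital_day, e$year, idx),
      shc_outpatient_visit = e$quantity * adjust_unit_cost(uc$shc_outpatient_visit, e$year, idx),
      drug_purchase = e$quantity)
  }, numeric(1))
  oracle_total <- sum(per_event)

  d <- compute_direct_costs(summarise_utilisation(kept), uc, idx)
  expect_equal(sum(d$total_direct), oracle_total)
})

test_that("costs are scale-equivariant: doubling quantities doubles every component", {
  cfg <- tiny_sim_config(years = 2005:2006, seed = 21L)
  ev <- generate_registers(cfg)
  kept <- rbind(filter_copd_events(ev), filter_copd_medication(ev))
  doubled <- copy(kept)[, quantity := quantity * 2]
  idx <- flat_index(2005:2006)
  f <- function(e) {
    u <- summarise_utilisation(e)
    cbind(compute_direct_costs(u, unit_cost_table(), idx)[, -1],
          compute_indirect_costs(u, unit_cost_table(), 260)[, -1])
  }
  expect_equal(as.matrix(f(doubled)), 2 * as.matrix(f(kept)))
})

test_that("end-to-end accounting on known rates recovers expected costs (100 seeds)", {
  ## one stratum, 1000 equivalents, flat index: expected SHC hospital cost
  ## = rate * equivalents * P(COPD code) * 590
  rate <- 0.4; eqv <- 1000; share <- 0.8
  expected <- rate * eqv * share * 590
  totals <- vapply(1:100, function(s) {
    cfg <- one_stratum_config(equivalents = eqv, rate = rate,
                              category = "shc_hospital_day", seed = s,
                              copd_diagnosis_share = share)
    ev <- filter_copd_events(generate_registers(cfg))
    u <- summarise_utilisation(ev, years = 2006)
    compute_direct_costs(u, unit_cost_table(), flat_index(2006))$total_direct
  }, numeric(1))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})
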