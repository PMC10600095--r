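test_that("decarbonisation multipliers follow the step schedule", {
  sch <- decarb_schedule(data.frame(
    sector = "electricity",
    step_year = c(2030, 2040, 2050),
    multiplier = c(0.6, 0.3, 0)
  ))
  # identity before the first step
  expect_equal(decarb_multiplier("electricity", 2025, sch), 1)
  expect_equal(decarb_multiplier("electricity", 2035, sch), 0.6)
  # piecewise constancy, brute force over every year
  for (y in 2022:2055) {
    expected <- if (y < 2030) 1 else if (y < 2040) 0.6 else if (y < 2050) 0.3 else 0
    expect_equal(decarb_multiplier("electricity", y, sch), expected)
  }
  expect_error(decarb_multiplier("aviation", 2030, sch), "unknown")
})

test_that("fixture schedule multipliers are non-increasing for every sector", {
  sch <- fx_bundle()$schedule
  for (sec in unique(sch$sector)) {
    sweep <- decarb_multiplier(sec, 2022:2050, sch)
    expect_true(all(diff(sweep) <= 0))
    expect_true(all(sweep >= 0 & sweep <= 1))
  }
  # schedules that re-carbonise are rejected
  expect_error(decarb_schedule(data.frame(
    sector = "heat", step_year = c(2030, 2040), multiplier = c(0.5, 0.8)
  )), "non-increasing")
})

test_that("process emissions scale flows by factors and multipliers", {
  sch <- decarb_schedule(data.frame(sector = "fuels", step_year = 2030,
                                    multiplier = 0.5))
  ft <- build_scenario_flows(tiny_flow_spec(10))
  inv <- emission_inventory(data.frame(
    process_id = c("forest_gate", "sawmill"),
    scope = c(1, 1),
    value_kgco2e = c(0, 2),
    unit = "green tonne",
    decarb_sector = "fuels"
  ))
  # 10 t through one process at 2 kg/t and multiplier 0.5 -> 10 kg CO2e
  em <- component_process_emissions(ft, inv, 2035, sch)
  expect_equal(sum(em$value_tco2e), 0.010)
  # zero factors give zero emissions
  inv0 <- inv
  inv0$value_kgco2e <- 0
  em0 <- component_process_emissions(ft, inv0, 2025, sch)
  expect_equal(sum(em0$value_tco2e), 0)
  # missing factor and unit mismatch are structured errors
  expect_error(component_process_emissions(ft, inv[1, ], 2025, sch),
               "missing emission factor")
  inv_bad <- inv
  inv_bad$unit <- "m3 product"
  expect_error(component_process_emissions(ft, inv_bad, 2025, sch),
               "unit mismatch")
})

test_that("emissions are linear in flows and vanish at full decarbonisation", {
  fx <- fx_bundle()
  ft <- fx$flows$bau
  em1 <- component_process_emissions(ft, fx$inventory, 2025, fx$schedule)
  em2 <- component_process_emissions(scale_to_harvest(ft, 200),
                                     fx$inventory, 2025, fx$schedule)
  expect_equal(em2$value_tco2e, 2 * em1$value_tco2e)

  zero_sch <- decarb_schedule(data.frame(
    sector = unique(fx$schedule$sector), step_year = 2030, multiplier = 0
  ))
  em0 <- component_process_emissions(ft, fx$inventory, 2045, zero_sch)
  expect_equal(sum(abs(em0$value_tco2e)), 0)
})

test_that("component totals re-sum across scopes (brute-force oracle)", {
  fx <- fx_bundle()
  for (y in c(2022, 2035, 2050)) {
    em <- component_process_emissions(fx$flows$cascading_circular,
                                      fx$inventory, y, fx$schedule)
    expect_equal(sum(em$value_tco2e),
                 brute_process_emissions(fx$flows$cascading_circular,
                                         fx$inventory, y, fx$schedule))
  }
})

test_that("panels dominate the BAU burden with a large resin share", {
  fx <- fx_bundle()
  em <- component_process_emissions(scale_to_harvest(fx$flows$bau, 9.5e6),
                                    fx$inventory, 2022, fx$schedule)
  by_comp <- tapply(em$value_tco2e, em$component, sum)
  expect_equal(names(which.max(by_comp)), "uk_wood_panel_production")

  # resin rows are around 40% of the panel burden
  thr <- process_throughput(scale_to_harvest(fx$flows$bau, 9.5e6))
  panel_ids <- c("particleboard_mill", "mdf_mill", "recycled_mdf_mill")
  inv <- fx$inventory
  resin <- total <- 0
  for (p in panel_ids) {
    q <- thr$throughput[thr$process_id == p]
    rows <- inv[inv$process_id == p, ]
    total <- total + q * sum(rows$value_kgco2e)
    resin <- resin + q * sum(rows$value_kgco2e[rows$decarb_sector == "resins"])
  }
  expect_gt(resin / total, 0.35)
  expect_lt(resin / total, 0.45)
})

test_that("import-delta emissions follow the consequential convention", {
  fx <- fx_bundle()
  bau <- fx$flows$bau
  # BAU against itself: zero by construction
  z <- import_delta_emissions(derive_import_deltas(bau, bau),
                              fx$inventory, 2025, fx$schedule)
  expect_equal(z$value_tco2e, 0)

  # hand arithmetic: -1000 t at 50 kg/t processing + 20 kg/t transport
  inv <- emission_inventory(data.frame(
    process_id = c("import_processing_carcassing",
                   "import_transport_carcassing"),
    scope = 3, value_kgco2e = c(50, 20), unit = "green tonne",
    decarb_sector = "heat"
  ))
  sch <- decarb_schedule(data.frame(sector = "heat", step_year = 2060,
                                    multiplier = 0))
  d <- tibble::tibble(category = "carcassing", uk_delta = 1000,
                      import_delta = -1000, consumption_delta = 0)
  em <- import_delta_emissions(d, inv, 2025, sch)
  expect_equal(em$value_tco2e, -70)
  expect_equal(em$scope, "4")

  # missing transport factor is a structured error
  expect_error(import_delta_emissions(d, inv[1, ], 2025, sch), "missing")

  # circular: imports fall net (UK production rises) -> negative change;
  # cascading: panel imports rise -> positive change offsetting S1-3 savings
  d_circ <- derive_import_deltas(scale_to_harvest(fx$flows$circular, 9.5e6),
                                 scale_to_harvest(bau, 9.5e6),
                                 woodfuel_replacement = 0.4)
  expect_lt(import_delta_emissions(d_circ, fx$inventory, 2022,
                                   fx$schedule)$value_tco2e, 0)
  d_casc <- derive_import_deltas(scale_to_harvest(fx$flows$cascading, 9.5e6),
                                 scale_to_harvest(bau, 9.5e6))
  expect_gt(import_delta_emissions(d_casc, fx$inventory, 2022,
                                   fx$schedule)$value_tco2e, 0)
})
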