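test_that("yield curves start at zero, grow monotonically and hit their MAI", {
  for (yc in c(6, 14, 24)) {
    curve <- yield_curve(yc)
    expect_equal(volume_at(curve, 0), 0)
    expect_true(all(diff(curve$points$volume_m3_ha) >= 0))
    ages <- 1:150
    expect_equal(max(volume_at(curve, ages) / ages), yc, tolerance = 1e-9)
  }
  # extrapolation beyond the last tabulated age is flat
  curve <- yield_curve(12, max_age = 80)
  expect_equal(volume_at(curve, 200), volume_at(curve, 80))
  expect_error(yield_curve_from_points(
    data.frame(age = c(0, 10, 20), volume_m3_ha = c(0, 50, 30))
  ), "non-decreasing")
})

test_that("stand trajectories follow the yield curve and rotation schedule", {
  # hand arithmetic: linear curve v(a) = 2a, 0.25 t C/m3, 1 ha, age 10 -> 5 t C
  lin <- yield_curve_from_points(
    data.frame(age = 0:100, volume_m3_ha = 2 * (0:100))
  )
  conv <- carbon_convention(tc_per_m3 = 0.25)
  tr <- stand_trajectory(1, plant_year = 2000, rotation = Inf, curve = lin,
                         years = 2010, convention = conv)
  expect_equal(tr$biomass_tc, 5)

  # age-0 cohort has no biomass
  tr0 <- stand_trajectory(1, 2022, Inf, lin, 2022, conv)
  expect_equal(tr0$biomass_tc, 0)

  # sawtooth: zeros exactly at multiples of the rotation (brute-force loop)
  R <- 10
  years <- 2000:2040
  tr <- stand_trajectory(1, 2000, R, lin, years, conv)
  for (i in seq_along(years)) {
    age <- (years[i] - 2000) %% R
    expect_equal(tr$biomass_tc[i], 2 * age * 0.25)
  }
  expect_error(stand_trajectory(-1, 2000, R, lin, years), "positive")
})

test_that("regulated-estate closed form agrees with the cohort simulation", {
  curve <- yield_curve(16)
  conv <- carbon_convention()
  R <- 10
  area <- 500
  closed <- regulated_mean_stock(area, R, curve, conv)
  # route 1: age-class estate simulation held at the same rotation
  est <- estate_trajectory(area, R, R, curve, n_years = 3 * R,
                           convention = conv)
  expect_equal(est$biomass_tc, rep(closed, 3 * R), tolerance = 1e-3)
  # route 2: brute-force sum of R staggered cohorts
  cohorts <- 0
  for (a in 0:(R - 1)) {
    cohorts <- cohorts + stand_trajectory(area / R, 2000 - a, R, curve,
                                          2000, conv)$biomass_tc
  }
  expect_equal(cohorts, closed, tolerance = 1e-3)
})

test_that("weighted mean yield class is the fraction-weighted sum", {
  expect_equal(weighted_mean_yield_class(
    data.frame(fraction = 1, yield_class = 24)), 24)
  expect_equal(weighted_mean_yield_class(
    data.frame(fraction = c(0.5, 0.5), yield_class = c(24, 6))), 15)
  set.seed(7)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    w <- runif(n)
    w <- w / sum(w)
    yc <- runif(n, 4, 24)
    acc <- 0
    for (j in 1:n) acc <- acc + w[j] * yc[j]
    expect_equal(weighted_mean_yield_class(
      data.frame(fraction = w, yield_class = yc)), acc)
  }
  expect_error(weighted_mean_yield_class(
    data.frame(fraction = c(0.5, 0.6), yield_class = c(10, 10))), "sum to 1")
})

test_that("extending the rotation raises estate carbon; credit tracks it", {
  conv <- carbon_convention()
  est <- default_estate()
  # zero recycling: rotation unchanged, credit exactly zero
  z <- avoided_harvest_credit(0, conv, est)
  expect_identical(z$credit_tco2e, 0)
  expect_identical(z$harvest_reduction_gt, 0)
  # positive recycling: storing (negative) credit, positive gain every year
  a <- avoided_harvest_credit(5e5, conv, est)
  expect_lt(a$credit_tco2e, 0)
  expect_true(all(a$gain_series >= 0))
  expect_gt(a$harvest_reduction_gt, 0)
  expect_equal(a$displaced_harvest_gt, 5e5 * conv$gt_per_m3_product)
  # the rotation shift is fixed: credit magnitude is monotone
  # (step) in recycled volume
  b <- avoided_harvest_credit(1e6, conv, est)
  expect_true(abs(z$credit_tco2e) <= abs(a$credit_tco2e))
  expect_equal(a$credit_tco2e, b$credit_tco2e)
  # shrinking the rotation is rejected
  bad <- est
  bad$rotation_extended <- 40
  expect_error(avoided_harvest_credit(1e5, conv, bad), "extended rotation")
})

test_that("afforestation accumulates by cohort superposition", {
  years <- 2023:2040
  mix <- data.frame(fraction = 1, yield_class = 16)
  # zero planting: all zeros
  z <- afforestation_series(afforestation_programme(0, 2023, 2040, mix),
                            years)
  expect_equal(z$cumulative_tco2e, rep(0, length(years)))
  # a two-year programme is the sum of two one-year programmes
  two <- afforestation_series(afforestation_programme(1000, 2023, 2024, mix),
                              years)
  one_a <- afforestation_series(afforestation_programme(1000, 2023, 2023, mix),
                                years)
  one_b <- afforestation_series(afforestation_programme(1000, 2024, 2024, mix),
                                years)
  expect_equal(two$sequestration_tco2e,
               one_a$sequestration_tco2e + one_b$sequestration_tco2e)
  # sequestration is reported negative and cumulative magnitude grows
  expect_true(all(two$sequestration_tco2e <= 0))
  expect_true(all(diff(abs(two$cumulative_tco2e)) >= 0))
  # magnitude is non-decreasing in the planting rate
  faster <- afforestation_series(
    afforestation_programme(2000, 2023, 2024, mix), years)
  expect_true(all(abs(faster$cumulative_tco2e) >= abs(two$cumulative_tco2e)))
  expect_error(afforestation_programme(1000, 2030, 2020, mix), "start_year")
  expect_error(afforestation_programme(1000, 2023, 2040,
                                       data.frame(fraction = numeric(),
                                                  yield_class = numeric())),
               "at least one")
})

test_that("the default programme's pace accelerates towards 2050", {
  fx <- fx_bundle()
  af <- afforestation_series(fx$afforestation, years = 2022:2050)
  early <- mean(abs(af$sequestration_tco2e[af$year %in% 2023:2027]))
  late <- mean(abs(af$sequestration_tco2e[af$year %in% 2046:2050]))
  expect_gt(late, early)
  expect_lt(af$cumulative_tco2e[af$year == 2050], 0)
})
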