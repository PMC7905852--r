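# printed annual component totals (USD, 2019); the transcription oracle
PRINTED_COMPONENTS <- c(
  program_director = 18333.78, program_coordinator = 12213.40,
  administration_officer = 7543.48, office_space = 9422.51,
  data_entry_clerk = 5713.69, finance_officer = 5713.69,
  health_educators = 437521.90, external_consultant = 555.69,
  logistics_social_worker = 7543.48, transportation_drivers = 87635.44,
  vehicles_and_maintenance = 142050, electronic_projectors = 6188.93,
  computers_laptops = 23843.65, transport_allowance = 36679.93,
  electricity_utility = 792.00, telephone_utility = 2736.16,
  hotel_accommodation = 202133.00, respiratory_rate_timers = 2173468.00,
  miscellaneous = 12000)

test_that("capital annualisation is straight-line", {
  expect_equal(annualize_capital(8000, 8), 1000)
  expect_equal(annualize_capital(1136400, 8), 142050)  # the vehicles line
  expect_equal(annualize_capital(500, 1), 500)
  expect_error(annualize_capital(100, 0.5), ">= 1 year")
  expect_error(annualize_capital(-1, 2), ">= 0")
})

test_that("the default ledger reproduces every printed component exactly", {
  led <- default_ledger()
  comp <- led$components
  ann <- stats::setNames(comp$annual_total, comp$name)
  expect_setequal(comp$name, c(names(PRINTED_COMPONENTS), "training_refreshments"))
  for (nm in names(PRINTED_COMPONENTS)) {
    expect_equal(unname(ann[nm]), unname(PRINTED_COMPONENTS[nm]),
                 tolerance = 1e-7, label = nm)
  }
  # the 19 printed rows alone
  expect_equal(sum(ann[names(PRINTED_COMPONENTS)]), 3192088.73, tolerance = 1e-8)
  # with the calibrated refreshments line, the published mean total
  expect_equal(total_annual_cost(led), 3459154, tolerance = 1e-6)
})

test_that("ledger total is permutation-invariant, additive and linear in unit costs", {
  led <- default_ledger()
  comp <- led$components[setdiff(names(led$components), "annual_total")]
  set.seed(7)
  shuffled <- cost_ledger(comp[sample(nrow(comp)), ])
  expect_equal(total_annual_cost(shuffled), total_annual_cost(led))
  half <- nrow(comp) %/% 2
  a <- cost_ledger(comp[seq_len(half), ])
  b <- cost_ledger(comp[(half + 1):nrow(comp), ])
  expect_equal(total_annual_cost(a) + total_annual_cost(b), total_annual_cost(led))
  scaled <- comp
  scaled$unit_cost <- scaled$unit_cost * 1.75
  expect_equal(total_annual_cost(cost_ledger(scaled)),
               1.75 * total_annual_cost(led))
})

test_that("per-child cost reproduces the published 0.25 USD", {
  expect_equal(per_child_cost(total_annual_cost(default_ledger()), 34.6e6, 0.40),
               0.25, tolerance = 2e-3)
  expect_equal(per_child_cost(0, 34.6e6, 0.40), 0)
  expect_equal(per_child_cost(1384000, 34.6e6, 0.40), 0.10)
  expect_error(per_child_cost(1, 0, 0.4), "positive")
})

test_that("shop count and staffing arithmetic reproduce the published figures", {
  expect_equal(shops_count(24.58), 49397)
  expect_equal(shops_count(0, 1e6), 0)
  expect_equal(shops_count(10, 1e6), 100)
  expect_equal(educators_required(49397), 58)
  expect_equal(educators_required(880, reserves = 0), 1)
  expect_equal(educators_required(8800, reserves = 0), 10)
})

test_that("component shares: timers dominate the budget", {
  led <- default_ledger()
  share <- component_share(led, "respiratory_rate_timers")
  expect_equal(share, 0.628, tolerance = 1e-3)
  expect_gte(share, 0.60)
  # against the 19 printed rows only
  comp <- led$components[led$components$name != "training_refreshments",
                         setdiff(names(led$components), "annual_total")]
  expect_equal(component_share(cost_ledger(comp), "respiratory_rate_timers"),
               0.681, tolerance = 1e-3)
  one <- cost_ledger(data.frame(name = "a", kind = "personnel",
                                quantity = 1, unit_cost = 5))
  expect_equal(component_share(one, "a"), 1.0)
  expect_error(component_share(led, "nope"), "unknown ledger component")
})

test_that("hospitalisation cost averted is the simple product", {
  expect_equal(hospitalization_cost_averted(28359, 0.35, 39.35),
               390574, tolerance = 1e-5)
  expect_equal(hospitalization_cost_averted(0), 0)
  expect_equal(hospitalization_cost_averted(1000, 0.35, 40), 14000)
})
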