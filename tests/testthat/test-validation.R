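test_that("microsimulation degenerate cases behave", {
  m <- diag(4)
  dimnames(m) <- list(health_states(), health_states())
  micro <- microsimulate(m, 500, 4, seed = 1)
  expect_true(all(micro$counts[, "well"] == 500))
  one <- microsimulate(baseline_matrix(), 1, 5, seed = 2)
  expect_true(all(rowSums(one$counts) == 1))
})

test_that("cohort engine agrees with the microsimulation oracle within 3 SE", {
  m <- baseline_matrix()
  n <- 200000L
  micro <- microsimulate(m, n, 5, seed = 20210225)
  tr <- run_cohort(m, 1, 5)       # unit cohort = expected proportions
  dev <- abs(micro$proportions - tr$membership)
  tol <- 3 * micro$se + 1e-9      # epsilon for cells with zero expectation
  expect_true(all(dev <= tol))
  # cycle-1 well fraction near its exact value
  expect_equal(unname(micro$proportions[2, "well"]), 0.7167, tolerance = 0.01)
})

test_that("random models are reproducible, valid, and conserve the cohort", {
  expect_identical(random_model(7)$values, random_model(7)$values)
  for (seed in 1:20) {
    ps <- random_model(seed)
    m0 <- build_transition_matrix(ps, "no_promotion")
    m1 <- build_transition_matrix(ps, "promotion")
    expect_identical(unname(rowSums(m0)), rep(1, 4))
    expect_equal(unname(rowSums(m1)), rep(1, 4), tolerance = 1e-12)
    tr <- run_cohort(m0, 1e5, unname(ps$values["n_cycles"]))
    expect_equal(rowSums(tr$membership),
                 rep(1e5, unname(ps$values["n_cycles"]) + 1),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("cohort engine matches the oracle on random models too", {
  for (seed in c(31, 32, 33)) {
    ps <- random_model(seed)
    m <- build_transition_matrix(ps, "no_promotion")
    micro <- microsimulate(m, 50000L, 4, seed = seed + 1000)
    tr <- run_cohort(m, 1, 4)
    expect_true(all(abs(micro$proportions - tr$membership) <=
                      3 * micro$se + 1e-3), label = paste("seed", seed))
  }
})

test_that("the calibration harness is self-consistent and deterministic", {
  grid <- default_option_grid()[c(1, 100, 500, 2000), ]
  rep1 <- calibrate_options(grid = grid)
  rep2 <- calibrate_options(grid = grid)
  expect_identical(rep1$selected_index, rep2$selected_index)
  expect_identical(rep1$grid$distance, rep2$grid$distance)
  # targets set to a member's own outputs -> that member has distance 0
  self <- rep1$grid[2, ]
  t <- published_targets()
  t$mean[match(c("daly_baseline", "daly_promotion", "dalys_averted",
                 "deaths_averted", "severe_averted", "icer"), t$output)] <-
    unlist(self[c("daly_baseline", "daly_promotion", "dalys_averted",
                  "deaths_averted", "severe_averted", "icer")])
  rep3 <- calibrate_options(targets = t, grid = grid)
  expect_equal(rep3$grid$distance[2], 0, tolerance = 1e-12)
  expect_identical(rep3$selected_index, 2L)
  expect_error(calibrate_options(grid = default_option_grid()[0, ]), "empty")
})

test_that("the shipped calibration report matches the package defaults", {
  rep <- shipped_calibration_report()
  sel <- rep$selected
  expect_equal(sel$effect_targets, "ms")
  expect_equal(sel$scaling, "impact")
  expect_equal(sel$yld_occupancy, daly_options()$yld_occupancy)
  expect_equal(sel$discounting, daly_options()$discounting)
  expect_equal(sel$yll_mode, daly_options()$yll_mode)
  expect_equal(sel$death_states, effect_options()$death_states)
  expect_equal(sel$count_recurrent_severe, effect_options()$count_recurrent_severe)
  expect_equal(sel$averted_reporting, effect_options()$averted_reporting)
  # and its deterministic outputs reproduce on this machine
  ce <- run_base_case()
  expect_equal(sel$dalys_averted, ce$dalys_averted, tolerance = 1e-9)
  expect_equal(sel$icer, ce$icer, tolerance = 1e-9)
})

test_that("calibration reports serialise and read back", {
  grid <- default_option_grid()[c(1, 50), ]
  rep <- calibrate_options(grid = grid)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_calibration_report(rep, tmp, top_n = 2)
  back <- read_calibration_report(tmp)
  expect_equal(back$n_options_evaluated, 2)
  expect_equal(back$selected$distance, min(rep$grid$distance), tolerance = 1e-12)
})
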