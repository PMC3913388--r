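test_that("simulation reaches a closed periodic steady state", {
  run <- simulate_day(fixture_midrange_scenario(), fixture_tables())
  for (nm in c("bg", "plasma_insulin", "active_insulin", "gut_absorption",
               "renal_excretion", "peripheral_uptake", "nhgb")) {
    expect_length(run[[nm]], 97)
    expect_true(all(is.finite(run[[nm]])))
  }
  expect_lt(abs(run$bg[1] - run$bg[97]), 0.01)
  expect_true(all(run$bg >= model_constants()$bg_floor))
  expect_true(all(run$gut_absorption >= 0))
  expect_true(all(run$renal_excretion >= 0))
  expect_true(all(run$peripheral_uptake >= 0))
  # renal flux is zero exactly where BG is at or under the threshold
  expect_true(all((run$renal_excretion == 0) == (run$bg <= run$params$RTG)))
})

test_that("every Euler increment is exactly the booked flux balance", {
  cc <- model_constants()
  run <- simulate_day(fixture_midrange_scenario(), fixture_tables(), cc)
  p <- run$params
  gut_avg <- (run$gut_absorption[-97] + run$gut_absorption[-1]) / 2
  ia_avg <- (run$active_insulin[-97] + run$active_insulin[-1]) / 2
  g <- run$bg
  for (i in 1:96) {
    net <- gut_avg[i] + net_hepatic_balance(g[i], ia_avg[i], p, cc) -
      peripheral_utilization_rate(g[i], ia_avg[i], p, cc) -
      renal_excretion_rate(g[i], p)
    expect_equal(g[i + 1] - g[i], 0.25 * net / (cc$Vg * p$weight),
                 tolerance = 1e-12)
  }
})

test_that("seeded random scenarios all converge with day-boundary closure", {
  tabs <- fixture_tables()
  for (seed in 1:20) {
    run <- suppressMessages(simulate_day(random_scenario(seed), tabs))
    expect_lt(abs(run$bg[1] - run$bg[97]), 0.01)
    expect_lte(run$iterations, model_constants()$ss_max_iter)
  }
})

test_that("refining the Euler step barely moves the mid-range trajectory", {
  tabs <- fixture_tables()
  sc <- fixture_midrange_scenario()
  r15 <- simulate_day(sc, tabs)
  r1 <- simulate_day(sc, tabs, dt_min = 1)
  expect_lt(max(abs(r1$bg - r15$bg) / r15$bg), 0.05)
})

test_that("non-convergence inside the iteration cap is an error, not a result", {
  cc <- model_constants(ss_tol = 1e-13, ss_max_iter = 2L)
  expect_error(simulate_day(fixture_midrange_scenario(), fixture_tables(), cc),
               "no periodic steady state")
})

test_that("pharmacology moves mean glucose in the right direction", {
  tabs <- fixture_tables()
  base <- fixture_midrange_scenario()
  run0 <- simulate_day(base, tabs)

  # more insulin anywhere: mean BG must not rise
  up <- base
  up$insulins[[1]]$injections$dose[1] <- up$insulins[[1]]$injections$dose[1] + 4
  expect_lte(simulate_day(up, tabs)$mean_bg, run0$mean_bg)

  # more carbohydrate: mean BG must not fall
  fed <- base
  fed$meals$grams[3] <- fed$meals$grams[3] + 20
  expect_gte(simulate_day(fed, tabs)$mean_bg, run0$mean_bg)

  # higher sensitivity: mean BG must not rise
  sens <- base
  sens$categories$peripheral <- "high_increased"
  expect_lte(simulate_day(sens, tabs)$mean_bg, run0$mean_bg)
  sens2 <- base
  sens2$categories$hepatic <- "high_increased"
  expect_lte(simulate_day(sens2, tabs)$mean_bg, run0$mean_bg)
})
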