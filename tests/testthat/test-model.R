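test_that("renal excretion switches on exactly at the glucose threshold", {
  p <- fixture_params()  # RTG 9 mmol/L, CCR 100 mL/min = 6 L/h
  expect_equal(renal_excretion_rate(8, p), 0)
  expect_equal(renal_excretion_rate(9, p), 0)
  expect_equal(renal_excretion_rate(11, p), 12)  # 6 L/h * 2 mmol/L
  # zero exactly on {G <= RTG}, positive above
  gg <- seq(0, 20, by = 0.25)
  rr <- renal_excretion_rate(gg, p)
  expect_true(all(rr[gg <= 9] == 0))
  expect_true(all(rr[gg > 9] > 0))
  # reduced clearance scales the supra-threshold slope
  p40 <- modifyList(p, list(CCR = 40))
  expect_equal(renal_excretion_rate(11, p40), 4.8)
})

test_that("peripheral utilization saturates in glucose and grows with insulin", {
  p <- fixture_params()
  cc <- model_constants()
  expect_equal(peripheral_utilization_rate(0, 20, p, cc), 0)
  # monotone in G, Ia and Sp over a grid
  gg <- seq(0, 30, by = 1)
  expect_true(all(diff(peripheral_utilization_rate(gg, 20, p, cc)) > 0))
  ia <- seq(0, 80, by = 5)
  expect_true(all(diff(peripheral_utilization_rate(8, ia, p, cc)) > 0))
  hi <- modifyList(p, list(Sp = 0.8))
  expect_gt(peripheral_utilization_rate(8, 20, hi, cc),
            peripheral_utilization_rate(8, 20, p, cc))
  # plateau as G -> infinity equals the closed-form asymptote
  plateau <- cc$peripheral_base + cc$peripheral_insulin_slope * p$Sp * 20
  expect_equal(peripheral_utilization_rate(1e6 * cc$Km, 20, p, cc), plateau,
               tolerance = 1e-5)
})

test_that("hepatic balance interpolates its grid and responds to insulin", {
  p <- fixture_params()
  cc <- model_constants()
  grid <- cc$nhgb
  # interpolation identity at the nodes (Sh = 0.5 maps Ia = 2x to node x)
  for (i in seq_along(grid$ins_nodes)) {
    for (j in seq_along(grid$g_nodes)) {
      expect_equal(net_hepatic_balance(grid$g_nodes[j],
                                       grid$ins_nodes[i] / p$Sh, p, cc),
                   grid$values[i, j])
    }
  }
  # more insulin never raises hepatic output
  for (g in grid$g_nodes) {
    vals <- net_hepatic_balance(rep(g, 40), seq(0, 200, length.out = 40), p, cc)
    expect_true(all(diff(vals) <= 1e-12))
  }
  # zero insulin at euglycaemia: net production
  expect_gt(net_hepatic_balance(7, 0, p, cc), 0)
  # arguments beyond the grid hull are clamped, not extrapolated
  expect_equal(net_hepatic_balance(100, 1e4, p, cc),
               grid$values[nrow(grid$values), ncol(grid$values)])
})

test_that("injection regimens superpose periodically and respect limits", {
  tabs <- fixture_tables()
  cc <- model_constants()
  none <- insulin_day_profiles(
    data.frame(time_min = numeric(), dose = numeric(),
               preparation = character()), tabs, 70, cc)
  expect_true(all(none$plasma == 0) && all(none$active == 0))

  # the basal split of the pump workaround: 4 IU at 07:00 + 6 IU at 19:00
  inj <- data.frame(time_min = c(7, 19) * 60, dose = c(4, 6),
                    preparation = "Ultratard")
  prof <- insulin_day_profiles(inj, tabs, 70, cc)
  expect_length(prof$plasma, 97)
  expect_true(all(prof$plasma > 0))  # long-acting tails cover the whole day
  # superposition: equals the sum of the two single-injection regimens
  single <- function(t, d) insulin_day_profiles(
    data.frame(time_min = t, dose = d, preparation = "Ultratard"),
    tabs, 70, cc)
  expect_equal(prof$plasma,
               single(7 * 60, 4)$plasma + single(19 * 60, 6)$plasma)
  # daily absorbed mass equals the 10 IU injected total (within fold error)
  daily_iu <- sum(prof$plasma[1:96] * cc$Vi * 70 / 1000) * 0.25 * cc$ke
  expect_lt(abs(daily_iu - 10) / 10, 0.01)

  # periodicity: shifting the regimen by exactly 24 h changes nothing
  expect_equal(single(7 * 60, 4)$plasma, single(7 * 60 + 1440, 4)$plasma)

  five <- data.frame(time_min = (8:12) * 60, dose = 2, preparation = "Actrapid")
  expect_error(insulin_day_profiles(five, tabs, 70, cc), "more than 4")
  over <- data.frame(time_min = 8 * 60, dose = 41, preparation = "Actrapid")
  expect_error(insulin_day_profiles(over, tabs, 70, cc), "dose out of range")
})

test_that("the Euler step advances glucose by the flux balance", {
  cc <- model_constants()
  p <- list(weight = 70)
  # all fluxes zero: no change
  expect_equal(glucose_step(7, list(gut_in = 0, nhgb = 0, peripheral = 0,
                                    renal = 0), p, cc), 7)
  # hand arithmetic: 12 mmol/h over 15 min into Vg*weight = 15.4 L
  g2 <- glucose_step(7, list(gut_in = 12, nhgb = 0, peripheral = 0,
                             renal = 0), p, cc)
  expect_equal(g2 - 7, 12 * 0.25 / 15.4)
  expect_error(glucose_step(7, list(gut_in = NaN, nhgb = 0, peripheral = 0,
                                    renal = 0), p, cc), "non-finite")
  # the floor clamps catastrophic drops
  expect_equal(glucose_step(1, list(gut_in = 0, nhgb = -1000, peripheral = 0,
                                    renal = 0), p, cc), cc$bg_floor)
})

test_that("periodic means and unit views behave", {
  expect_equal(mean_bg(rep(5, 97)), 5)
  alt <- rep(c(4, 8), length.out = 97)
  expect_equal(mean_bg(alt), 6)
  expect_equal(mean_bg(alt) * 18, convert_bg(6, "mmol_per_L", "mg_per_dL"))
})

test_that("HbA1c tracks mean glucose through the regression", {
  expect_equal(hba1c_estimate(200), (200 + 86) / 33.3)
  expect_equal(round(hba1c_estimate(200), 1), 8.6)
  expect_equal(hba1c_estimate(113.8), 6.0, tolerance = 1e-3)
  expect_lt(hba1c_estimate(150), hba1c_estimate(151))
  expect_error(hba1c_estimate(0), "positive")
  # the alternative estimated-average-glucose regression is selectable
  expect_equal(hba1c_estimate(240.2, model = "eag"), 10.0, tolerance = 1e-3)
})
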