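test_that("absorption fraction follows the sigmoid with dose-dependent T50", {
  p <- absorption_class_params("ACTRAPID_LIKE")
  t50 <- p$a * 8 + p$b
  expect_equal(absorption_fraction(0, 8, p), 0)
  expect_equal(absorption_fraction(t50, 8, p), 0.5)
  # hand evaluation at t = 2*T50 with s = 2: (2T)^2 / (T^2 + (2T)^2) = 4/5
  expect_equal(absorption_fraction(2 * t50, 8, p), 0.8)
  # monotone non-decreasing in t, bounded by 1
  tt <- seq(0, 100, by = 0.25)
  ff <- absorption_fraction(tt, 8, p)
  expect_true(all(diff(ff) >= 0))
  expect_true(all(ff >= 0 & ff < 1))
  expect_gt(absorption_fraction(1e6, 8, p), 0.999)

  expect_error(absorption_fraction(1, 0, p), "dose out of range")
  expect_error(absorption_fraction(1, 41, p), "dose out of range")
  expect_error(absorption_fraction(-1, 8, p), "t must be")
})

test_that("single-injection responses conserve the injected dose", {
  cc <- model_constants()
  for (cls in names(absorption_class_params())) {
    p <- absorption_class_params(cls)
    for (dose in c(1, 10, 40)) {
      resp <- single_injection_response(dose, p, cc, horizon_h = 600,
                                        dt_min = 1)
      absorbed <- sum(resp$rate) / 60  # rectangle rule at 1-min steps
      expect_lt(abs(absorbed - dose) / dose, 0.01,
                label = paste(cls, dose, "IU absorbed mass error"))
      expect_true(all(resp$plasma >= 0) && all(resp$active >= 0))
    }
  }
})

test_that("a zero dose yields an identically zero response", {
  resp <- single_injection_response(0, absorption_class_params("NPH_LIKE"),
                                    horizon_h = 48)
  expect_true(all(resp$rate == 0))
  expect_true(all(resp$plasma == 0))
  expect_true(all(resp$active == 0))
})

test_that("plasma peaks order short-acting before long-acting", {
  cc <- model_constants()
  peak_time <- function(cls) {
    resp <- single_injection_response(8, absorption_class_params(cls), cc,
                                      horizon_h = 72, dt_min = 5)
    resp$time_min[which.max(resp$plasma)]
  }
  t_short <- peak_time("ACTRAPID_LIKE")
  t_nph <- peak_time("NPH_LIKE")
  t_lente <- peak_time("LENTE_LIKE")
  t_ultra <- peak_time("ULTRALENTE_LIKE")
  expect_lt(t_short, t_nph)
  expect_lte(t_nph, t_lente)
  expect_lt(t_lente, t_ultra)
})

test_that("insulin tables have the dose-indexed 41 x 97 layout", {
  tabs <- fixture_tables()
  for (nm in setdiff(profile_file_names(), "CAR")) {
    expect_equal(dim(tabs[[nm]]$values), c(41, 97))
    expect_true(all(tabs[[nm]]$values[1, ] == 0))  # row 0: zero dose
    expect_true(all(tabs[[nm]]$values >= 0))
    # periodic closure: column 97 repeats column 1
    expect_equal(tabs[[nm]]$values[, 97], tabs[[nm]]$values[, 1])
  }
})

test_that("dose-dependent kinetics make the tables genuinely nonlinear", {
  tabs <- fixture_tables()
  pa <- tabs$Actrapid_pa$values
  # row(2d) is not 2*row(d): T50 grows with dose
  expect_gt(max(abs(pa[21, ] - 2 * pa[11, ])), 1e-3)
  # but folded daily mass still scales with dose (superposed conservation)
  daily <- rowSums(pa[, 1:96])
  expect_true(all(diff(daily) > 0))
})

test_that("gut appearance conserves the meal's glucose equivalent", {
  cc <- model_constants()
  expect_true(all(gastric_emptying_profile(0) == 0))
  for (g in c(1, 5, 40, 60, 80)) {
    app <- gastric_emptying_profile(g, cc, horizon_h = 24, dt_min = 1)
    total <- sum(app) / 60
    expect_lt(abs(total - g * cc$carb_mmol_per_g) / (g * cc$carb_mmol_per_g),
              0.01, label = paste(g, "g appearance integral"))
    expect_true(all(app >= 0))
  }
  expect_error(gastric_emptying_profile(81), "0-80")
  expect_error(gastric_emptying_profile(-1), ">= 0")
})

test_that("carbohydrate table rows are monotone in meal size", {
  tabs <- fixture_tables()
  car <- tabs$CAR$values
  expect_equal(dim(car), c(81, 97))
  expect_true(all(car[1, ] == 0))
  totals <- rowSums(car[, 1:96]) * 0.25  # mmol absorbed per day per row
  expect_true(all(diff(totals) > 0))
})
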