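test_that("blood glucose unit conversion uses the factor 18", {
  expect_equal(convert_bg(5, "mmol_per_L", "mg_per_dL"), 90)
  expect_equal(convert_bg(convert_bg(7.3, "mmol_per_L", "mg_per_dL"),
                          "mg_per_dL", "mmol_per_L"), 7.3)
  expect_equal(convert_bg(9, "mmol_per_L", "mmol_per_L"), 9)
  expect_equal(convert_bg(c(4, 10), "mmol_per_L", "mg_per_dL"), c(72, 180))
  expect_error(convert_bg(5, "mmol_per_L", "furlongs"), "unknown unit")
})

test_that("options validate bounds and expose the units factor", {
  o <- simulator_options(bg_units = "mg_per_dL")
  expect_equal(o$units_factor, 18)
  expect_equal(simulator_options()$units_factor, 1)
  expect_equal(simulator_options(show_bounds = TRUE)$bounds, c(4, 10))
  expect_error(simulator_options(bounds = c(10, 4)), "lower < upper")
})

test_that("sessions number runs and retain exactly two", {
  tabs <- fixture_tables()
  sc <- fixture_midrange_scenario()
  opts <- simulator_options()
  s <- new_session("11111")

  out1 <- run_simulation(sc, opts, s, tabs)
  expect_equal(out1$run$run_number, 1)
  expect_length(out1$session$runs, 1)

  out2 <- run_simulation(sc, opts, out1$session, tabs)
  out3 <- run_simulation(sc, opts, out2$session, tabs)
  expect_equal(out3$run$run_number, 3)
  expect_length(out3$session$runs, 2)
  expect_equal(vapply(out3$session$runs, `[[`, 0, "run_number"), c(3, 2))

  # determinism: identical scenario twice gives identical series
  expect_identical(out1$run$bg, out2$run$bg)
  expect_identical(out1$run$plasma_insulin, out2$run$plasma_insulin)
})

test_that("each run exports six 97-row data files stamped with the session", {
  tabs <- fixture_tables()
  dir <- withr::local_tempdir()
  out <- run_simulation(fixture_midrange_scenario(), simulator_options(),
                        new_session("22222"), tabs)
  paths <- export_run(out$run, dir)
  expect_length(paths, 6)
  expect_true(all(file.exists(paths)))
  expect_true(all(grepl("^22222_run1_", basename(paths))))
  for (f in paths) {
    d <- utils::read.table(f, comment.char = "#")
    expect_equal(nrow(d), 97)
    expect_equal(ncol(d), 2)
    expect_equal(d[[1]][1], 0)
    expect_equal(d[[1]][97], 24)
  }

  # repeated export of the same run is byte-identical
  dir2 <- withr::local_tempdir()
  paths2 <- export_run(out$run, dir2)
  for (i in seq_along(paths)) {
    expect_identical(readLines(paths[i]), readLines(paths2[i]))
  }

  # concurrent sessions produce disjoint filename sets
  outB <- run_simulation(fixture_midrange_scenario(), simulator_options(),
                         new_session("33333"), tabs)
  pathsB <- export_run(outB$run, dir)
  expect_length(intersect(basename(paths), basename(pathsB)), 0)

  # cleanup targets one session at a time
  expect_equal(clean_exports(dir, "22222"), 6)
  expect_length(list.files(dir, pattern = "^22222"), 0)
  expect_length(list.files(dir, pattern = "^33333"), 6)
})

test_that("the comparison payload distinguishes current from previous", {
  tabs <- fixture_tables()
  sc <- fixture_midrange_scenario()
  opts <- simulator_options(show_bounds = TRUE)
  expect_error(comparison_payload(new_session("44444")), "no runs")

  out1 <- run_simulation(sc, opts, new_session("44444"), tabs)
  p1 <- comparison_payload(out1$session)
  expect_equal(p1$current$run_number, 1)
  expect_null(p1$previous)
  expect_equal(p1$bounds, c(4, 10))

  sc2 <- sc
  sc2$insulins[[1]]$injections$dose[2] <- 6
  out2 <- run_simulation(sc2, opts, out1$session, tabs)
  p2 <- comparison_payload(out2$session)
  expect_equal(p2$current$run_number, 2)
  expect_equal(p2$previous$run_number, 1)
  expect_false(identical(p2$current$bg, p2$previous$bg))
})
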