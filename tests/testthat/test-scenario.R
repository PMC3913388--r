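test_that("scenario text round trip is the identity on canonical form", {
  for (seed in c(1, 42, 99)) {
    sc <- random_scenario(seed)
    txt <- write_scenario(sc)
    sc2 <- parse_scenario(txt)
    expect_identical(write_scenario(sc2), txt)
  }
  # and for a packaged case file (already canonical)
  path <- system.file("extdata", "cases", "0010.aida", package = "glucosim")
  txt <- readLines(path)
  expect_identical(write_scenario(parse_scenario(path)), txt)
})

test_that("data-entry limits are enforced with named errors", {
  base <- write_scenario(fixture_midrange_scenario())
  seven_meals <- append(base, "meal: 11:00 10", after = grep("^meal:", base)[1])
  expect_error(parse_scenario(seven_meals), "6-meal")

  five_inj <- append(base, c("injection: 12:00 2", "injection: 13:00 2",
                             "injection: 14:00 2"),
                     after = grep("^injection: 19:30", base))
  expect_error(parse_scenario(five_inj), "4-injection")

  expect_error(parse_scenario(sub("injection: 08:00 6", "injection: 08:00 41",
                                  base)), "exceeds 40 IU")
  expect_error(parse_scenario(sub("meal: 13:00 40", "meal: 13:00 85", base)),
               "exceed 80")
})

test_that("malformed lines fail with their line number", {
  expect_error(parse_scenario(c("id: 1", "name: x", "weight: 70 kg",
                                "meal: noon 30")), "line 4")
  expect_error(parse_scenario(c("id: 1", "gibberish without colon")), "line 2")
  expect_error(parse_scenario(c("id: 1", "name: x", "weight: 70 kg",
                                "injection: 08:00 6")), "before any insulin")
  expect_error(parse_scenario(c("name: x", "weight: 70 kg")), "id")
})

test_that("validation reports violations as ordered data, not errors", {
  sc <- fixture_midrange_scenario()
  expect_identical(validate_scenario(sc), character(0))

  sc$insulins[[1]]$injections$dose[1] <- 41
  sc$meals$grams[3] <- 85
  v <- validate_scenario(sc)
  expect_length(v, 2)
  expect_match(v[1], "grams 85 exceed 80")   # meals checked before insulin
  expect_match(v[2], "dose 41 exceeds 40 IU")

  sc2 <- fixture_midrange_scenario()
  sc2$categories$ccr <- "high_increased"
  expect_match(validate_scenario(sc2), "no high_increased preset")
})

test_that("weights entered in pounds are converted on parse", {
  txt <- c("id: 0001", "name: x", "weight: 154 lb")
  expect_equal(parse_scenario(txt)$weight, lb_to_kg(154))
})

test_that("the fixture generator is deterministic, valid and covering", {
  a <- random_scenario(7)
  b <- random_scenario(7)
  expect_identical(write_scenario(a), write_scenario(b))
  # the generator must not disturb the caller's RNG stream
  set.seed(123); x <- runif(1)
  set.seed(123); invisible(random_scenario(5)); y <- runif(1)
  expect_identical(x, y)

  reg <- insulin_registry()
  rtg_seen <- character()
  for (seed in 1:200) {
    sc <- random_scenario(seed)
    expect_identical(validate_scenario(sc, reg), character(0))
    rtg_seen <- union(rtg_seen, sc$categories$rtg)
  }
  expect_setequal(rtg_seen, c("low_reduced", "normal", "high_increased"))
})
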