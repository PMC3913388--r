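# Shared fixtures, built in code.

# The nine-member profile table set (built once per test session).
fixture_tables <- function() default_profile_tables()

# A mid-range fixture patient: persistently elevated glucose on a
# twice-daily soluble + bedtime ultralente regimen, the canonical subject
# for the dose/diet adjustment sequence.
fixture_midrange_scenario <- function() {
  case_scenario(
    id = "0010", name = "Hugh Allibaster",
    description = "mid-range fixture",
    weight = 70,
    meals = data.frame(time_min = c(8, 10.5, 13, 16, 19, 22.5) * 60,
                       grams = c(30, 15, 40, 15, 40, 10)),
    insulins = list(
      list(preparation = "Actrapid",
           injections = data.frame(time_min = c(8, 19.5) * 60, dose = c(6, 4))),
      list(preparation = "Ultratard",
           injections = data.frame(time_min = 23 * 60, dose = 8))))
}

# Nominal patient parameters for flux-level unit tests.
fixture_params <- function() {
  list(weight = 70, RTG = 9, CCR = 100, Sh = 0.5, Sp = 0.5)
}
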