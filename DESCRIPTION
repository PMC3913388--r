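Package: glucosim
Title: Educational Glucose-Insulin Simulator for Insulin-Dependent Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic compartmental simulation of 24-hour blood glucose
    and plasma insulin profiles in insulin-dependent diabetes, driven by meal
    and subcutaneous insulin injection schedules. Ships dose-indexed insulin
    and carbohydrate absorption lookup tables, a registry of classic insulin
    preparations (including biphasic premixes), preset physiological
    parameters, Euler integration to a 24-hour periodic steady state, four
    glucose flux panels (gut absorption, renal excretion, peripheral
    utilization, net hepatic glucose balance), HbA1c estimation from mean
    blood glucose, a database of 40 reconstructed case scenarios, two-run
    comparison sessions, and a command-line interface with PNG plotting.
    Intended for teaching and self-learning, not therapy planning.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
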