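# Case scenarios: the virtual patients. Data model, line-oriented ASCII
# format, validation, and a seeded fixture generator.

#' Construct a case scenario
#'
#' A case scenario describes one virtual insulin-dependent patient: body
#' weight, up to six meals (time + grams of carbohydrate), up to two insulin
#' preparations with up to four injections each, and four categorical
#' physiology parameters (renal glucose threshold, creatinine clearance,
#' hepatic and peripheral insulin sensitivity) resolved through
#' [preset_lookup()].
#'
#' The constructor performs no validation so that [validate_scenario()] can
#' report violations as data; [parse_scenario()] rejects invalid input.
#'
#' @param id zero-padded 4-digit identifier string.
#' @param name patient name.
#' @param description free-text case description.
#' @param weight body weight in kg (use [lb_to_kg()] for pounds).
#' @param meals data frame with columns `time_min` (minutes since midnight)
#'   and `grams`.
#' @param insulins list of up to two slots, each a list with `preparation`
#'   (brand name) and `injections` (data frame with `time_min`, `dose`).
#' @param categories named list `rtg`, `ccr`, `hepatic`, `peripheral`, each
#'   one of `"low_reduced"`, `"normal"`, `"high_increased"`; omitted entries
#'   default to `"normal"`.
#' @return A `case_scenario` object.
#' @export
case_scenario <- function(id, name, description = "", weight,
                          meals = data.frame(time_min = numeric(), grams = numeric()),
                          insulins = list(), categories = list()) {
  defaults <- list(rtg = "normal", ccr = "normal",
                   hepatic = "normal", peripheral = "normal")
  defaults[names(categories)] <- categories
  structure(list(id = id, name = name, description = description,
                 weight = weight, meals = meals, insulins = insulins,
                 categories = defaults),
            class = "case_scenario")
}

#' @export
print.case_scenario <- function(x, ...) {
  cat(sprintf("<case_scenario %s> %s (%.0f kg)\n", x$id, x$name, x$weight))
  cat(sprintf("  meals: %d (%s g total)\n", nrow(x$meals), sum(x$meals$grams)))
  for (slot in x$insulins) {
    cat(sprintf("  %s: %s\n", slot$preparation,
                paste(sprintf("%s %g IU", format_hhmm(slot$injections$time_min),
                              slot$injections$dose), collapse = ", ")))
  }
  cat("  physiology:", paste(unlist(x$categories), collapse = "/"), "\n")
  invisible(x)
}

format_hhmm <- function(min) sprintf("%02d:%02d", min %/% 60, min %% 60)

parse_hhmm <- function(txt) {
  m <- regmatches(txt, regexec("^([0-9]{1,2}):([0-9]{2})$", txt))[[1]]
  if (length(m) != 3) return(NA_real_)
  h <- as.numeric(m[2]); mi <- as.numeric(m[3])
  if (h > 23 || mi > 59) return(NA_real_)
  h * 60 + mi
}

#' Validate a case scenario
#'
#' Checks every structural invariant of the scenario format and returns the
#' violations as a character vector (empty when the scenario is valid), in a
#' deterministic order. Violations are data, not errors.
#'
#' @param scenario a `case_scenario`.
#' @param registry an [insulin_registry()] for brand-name resolution.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
#' @examples
#' sc <- random_scenario(1)
#' validate_scenario(sc)  # character(0)
validate_scenario <- function(scenario, registry = insulin_registry()) {
  v <- character()
  say <- function(...) v <<- c(v, sprintf(...))
  if (!is.numeric(scenario$weight) || length(scenario$weight) != 1L ||
      is.na(scenario$weight) || scenario$weight <= 0) {
    say("weight must be a positive number of kg")
  }
  if (nrow(scenario$meals) > 6) {
    say("meal count %d exceeds the 6-meal limit", nrow(scenario$meals))
  }
  for (i in seq_len(nrow(scenario$meals))) {
    tm <- scenario$meals$time_min[i]; g <- scenario$meals$grams[i]
    if (is.na(tm) || tm < 0 || tm >= 1440) {
      say("meal %d time out of range [00:00, 24:00)", i)
    }
    if (is.na(g) || g < 0) say("meal %d grams must be >= 0", i)
    else if (g > 80) say("meal %d grams %g exceed 80", i, g)
  }
  if (length(scenario$insulins) > 2) {
    say("insulin slot count %d exceeds the 2-preparation limit",
        length(scenario$insulins))
  }
  for (s in seq_along(scenario$insulins)) {
    slot <- scenario$insulins[[s]]
    known <- tryCatch({resolve_preparation(slot$preparation, registry); TRUE},
                      error = function(e) FALSE)
    if (!known) say("slot %d preparation '%s' not in registry", s, slot$preparation)
    inj <- slot$injections
    if (nrow(inj) > 4) {
      say("slot %d injection count %d exceeds the 4-injection limit",
          s, nrow(inj))
    }
    for (i in seq_len(nrow(inj))) {
      if (is.na(inj$time_min[i]) || inj$time_min[i] < 0 || inj$time_min[i] >= 1440) {
        say("slot %d injection %d time out of range [00:00, 24:00)", s, i)
      }
      if (is.na(inj$dose[i]) || inj$dose[i] < 0) {
        say("slot %d injection %d dose must be >= 0", s, i)
      } else if (inj$dose[i] > 40) {
        say("slot %d injection %d dose %g exceeds 40 IU", s, i, inj$dose[i])
      }
    }
  }
  cats <- c("low_reduced", "normal", "high_increased")
  for (key in c("rtg", "ccr", "hepatic", "peripheral")) {
    val <- scenario$categories[[key]]
    if (is.null(val) || !val %in% cats) {
      say("category '%s' must be one of %s", key, paste(cats, collapse = ", "))
    } else if (key == "ccr" && val == "high_increased") {
      say("category 'ccr' has no high_increased preset")
    }
  }
  v
}

#' Parse a case scenario from its ASCII text form
#'
#' The format is line-oriented `key: value` text: `id`, `name`,
#' `description`, `weight` (kg, or with an `lb` suffix), repeated
#' `meal: HH:MM grams` lines, `insulin: <brand>` lines each followed by its
#' `injection: HH:MM dose` lines, and the four category keys `rtg`, `ccr`,
#' `hepatic`, `peripheral` (omitted categories default to normal). Blank
#' lines and `#` comments are ignored.
#'
#' @param text character vector of lines, a single string with newlines, or
#'   a file path.
#' @param registry an [insulin_registry()] used for validation.
#' @return A validated `case_scenario`.
#' @seealso [write_scenario()] for the inverse; the round trip is the
#'   identity on canonical text.
#' @export
parse_scenario <- function(text, registry = insulin_registry()) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- readLines(text)
  } else if (length(text) == 1L) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  fields <- list(id = NULL, name = NULL, description = "", weight = NULL)
  meals <- data.frame(time_min = numeric(), grams = numeric())
  insulins <- list()
  categories <- list()
  current_slot <- 0L
  for (ln in seq_along(text)) {
    line <- trimws(text[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([A-Za-z_][A-Za-z0-9_]*):\\s*(.*)$", line))[[1]]
    if (length(m) != 3) {
      stop("parse error at line ", ln, ": expected 'key: value', got '",
           line, "'", call. = FALSE)
    }
    key <- tolower(m[2]); val <- trimws(m[3])
    if (key %in% c("id", "name", "description")) {
      fields[[key]] <- val
    } else if (key == "weight") {
      wm <- regmatches(val, regexec("^([0-9.]+)\\s*(kg|lb)?$", val))[[1]]
      if (length(wm) != 3) {
        stop("parse error at line ", ln, ": bad weight '", val, "'",
             call. = FALSE)
      }
      w <- as.numeric(wm[2])
      fields$weight <- if (identical(wm[3], "lb")) lb_to_kg(w) else w
    } else if (key == "meal") {
      parts <- strsplit(val, "\\s+")[[1]]
      tm <- if (length(parts) == 2) parse_hhmm(parts[1]) else NA_real_
      if (length(parts) != 2 || is.na(tm) ||
          is.na(suppressWarnings(as.numeric(parts[2])))) {
        stop("parse error at line ", ln, ": expected 'meal: HH:MM grams'",
             call. = FALSE)
      }
      meals <- rbind(meals,
                     data.frame(time_min = tm, grams = as.numeric(parts[2])))
    } else if (key == "insulin") {
      current_slot <- current_slot + 1L
      insulins[[current_slot]] <- list(
        preparation = val,
        injections = data.frame(time_min = numeric(), dose = numeric()))
    } else if (key == "injection") {
      if (current_slot == 0L) {
        stop("parse error at line ", ln,
             ": injection before any insulin line", call. = FALSE)
      }
      parts <- strsplit(val, "\\s+")[[1]]
      tm <- if (length(parts) == 2) parse_hhmm(parts[1]) else NA_real_
      if (length(parts) != 2 || is.na(tm) ||
          is.na(suppressWarnings(as.numeric(parts[2])))) {
        stop("parse error at line ", ln, ": expected 'injection: HH:MM dose'",
             call. = FALSE)
      }
      inj <- insulins[[current_slot]]$injections
      insulins[[current_slot]]$injections <-
        rbind(inj, data.frame(time_min = tm, dose = as.numeric(parts[2])))
    } else if (key %in% c("rtg", "ccr", "hepatic", "peripheral")) {
      categories[[key]] <- val
    } else {
      stop("parse error at line ", ln, ": unknown key '", key, "'",
           call. = FALSE)
    }
  }
  if (is.null(fields$id) || is.null(fields$name) || is.null(fields$weight)) {
    stop("parse error: scenario must set id, name and weight", call. = FALSE)
  }
  sc <- case_scenario(fields$id, fields$name, fields$description,
                      fields$weight, meals, insulins, categories)
  violations <- validate_scenario(sc, registry)
  if (length(violations)) {
    stop("invalid scenario: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  sc
}

#' Write a case scenario in its canonical ASCII text form
#'
#' @param scenario a `case_scenario`.
#' @param path optional file path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written to a file).
#' @export
write_scenario <- function(scenario, path = NULL) {
  lines <- c(
    paste0("id: ", scenario$id),
    paste0("name: ", scenario$name),
    paste0("description: ", scenario$description),
    sprintf("weight: %g kg", scenario$weight)
  )
  for (i in seq_len(nrow(scenario$meals))) {
    lines <- c(lines, sprintf("meal: %s %g",
                              format_hhmm(scenario$meals$time_min[i]),
                              scenario$meals$grams[i]))
  }
  for (slot in scenario$insulins) {
    lines <- c(lines, paste0("insulin: ", slot$preparation))
    for (i in seq_len(nrow(slot$injections))) {
      lines <- c(lines, sprintf("injection: %s %g",
                                format_hhmm(slot$injections$time_min[i]),
                                slot$injections$dose[i]))
    }
  }
  for (key in c("rtg", "ccr", "hepatic", "peripheral")) {
    lines <- c(lines, paste0(key, ": ", scenario$categories[[key]]))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Generate a random valid case scenario
#'
#' A seeded fixture generator: draws body weight, 3-6 meals, a basal/bolus
#' or premixed insulin regimen, and categorical physiology, producing a
#' scenario that always passes [validate_scenario()]. The generator does not
#' disturb the caller's random-number stream.
#'
#' @param seed integer seed; the same seed always yields the same scenario.
#' @return A `case_scenario` with id `"R<seed>"`.
#' @export
#' @examples
#' identical(write_scenario(random_scenario(7)), write_scenario(random_scenario(7)))
random_scenario <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)

  weight <- sample(45:100, 1)
  n_meals <- sample(3:6, 1)
  meal_slots <- c(breakfast = 8 * 60, midmorning = 10.5 * 60, lunch = 13 * 60,
                  afternoon = 16 * 60, supper = 19 * 60, bedtime = 22.5 * 60)
  chosen <- sort(sample(seq_along(meal_slots), n_meals))
  main <- meal_slots[chosen] %in% meal_slots[c(1, 3, 5)]
  grams <- ifelse(main, sample(25:60, n_meals, replace = TRUE),
                  sample(10:25, n_meals, replace = TRUE))
  meals <- data.frame(time_min = unname(meal_slots[chosen]), grams = grams)

  reg <- insulin_registry()
  regimen <- sample(c("basal_bolus", "premixed"), 1, prob = c(0.7, 0.3))
  if (regimen == "premixed") {
    brand <- sample(reg$name[reg$category == "biphasic"], 1)
    insulins <- list(list(
      preparation = brand,
      injections = data.frame(time_min = c(8, 19) * 60,
                              dose = sample(10:24, 2, replace = TRUE))))
  } else {
    short <- sample(reg$name[reg$category == "short"], 1)
    basal <- sample(reg$name[reg$category %in% c("intermediate", "long")], 1)
    n_bolus <- sample(2:4, 1)
    bolus_times <- c(8, 13, 19, 22.5)[seq_len(n_bolus)] * 60
    insulins <- list(
      list(preparation = short,
           injections = data.frame(time_min = bolus_times,
                                   dose = sample(4:10, n_bolus, replace = TRUE))),
      list(preparation = basal,
           injections = data.frame(time_min = c(8, 22.5) * 60,
                                   dose = sample(6:14, 2, replace = TRUE))))
  }
  cats <- c("low_reduced", "normal", "high_increased")
  sc <- case_scenario(
    id = paste0("R", as.integer(seed)),
    name = sprintf("Random case (seed %d)", as.integer(seed)),
    description = "Seeded synthetic fixture scenario.",
    weight = weight, meals = meals, insulins = insulins,
    categories = list(rtg = sample(cats, 1),
                      ccr = sample(cats[1:2], 1),
                      hepatic = sample(cats, 1),
                      peripheral = sample(cats, 1)))
  stopifnot(length(validate_scenario(sc, reg)) == 0L)
  sc
}
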