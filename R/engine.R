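# Run orchestration: options handling, unit conversion, run numbering,
# two-run comparison sessions, and export of the per-run data files.

#' Simulator options
#'
#' @param bg_units `"mmol_per_L"` (factor 1) or `"mg_per_dL"` (factor 18).
#' @param display `"standard"` (BG + insulin panels) or `"advanced"`
#'   (adds the four flux panels).
#' @param insulin_mode `"standard"` or `"premixed"` (which half of the
#'   registry a new case chooses from; informational).
#' @param bounds optional `c(lower, upper)` normoglycaemic range, mmol/L.
#' @param show_bounds draw the bounds lines on the BG panel; when enabled
#'   without explicit `bounds`, the default 4-10 mmol/L range is used.
#' @return A `simulator_options` object.
#' @export
#' @examples
#' simulator_options(bg_units = "mg_per_dL", show_bounds = TRUE)
simulator_options <- function(bg_units = c("mmol_per_L", "mg_per_dL"),
                              display = c("standard", "advanced"),
                              insulin_mode = c("standard", "premixed"),
                              bounds = NULL, show_bounds = FALSE) {
  bg_units <- match.arg(bg_units)
  display <- match.arg(display)
  insulin_mode <- match.arg(insulin_mode)
  if (show_bounds && is.null(bounds)) bounds <- c(4, 10)
  if (!is.null(bounds)) {
    stopifnot(is.numeric(bounds), length(bounds) == 2L)
    if (bounds[1] >= bounds[2]) {
      stop("bounds must satisfy lower < upper", call. = FALSE)
    }
  }
  structure(list(bg_units = bg_units,
                 units_factor = if (bg_units == "mg_per_dL") 18 else 1,
                 display = display, insulin_mode = insulin_mode,
                 bounds = bounds, show_bounds = show_bounds),
            class = "simulator_options")
}

#' Convert blood glucose values between mmol/L and mg/dL
#'
#' @param x value or series.
#' @param from,to `"mmol_per_L"` or `"mg_per_dL"`; 1 mmol/L = 18 mg/dL.
#' @return Converted values; same-unit conversion is the identity.
#' @export
#' @examples
#' convert_bg(5, "mmol_per_L", "mg_per_dL")  # 90
convert_bg <- function(x, from, to) {
  units <- c(mmol_per_L = 1, mg_per_dL = 18)
  if (!from %in% names(units)) stop("unknown unit '", from, "'", call. = FALSE)
  if (!to %in% names(units)) stop("unknown unit '", to, "'", call. = FALSE)
  x * units[[to]] / units[[from]]
}

#' Start a simulation session
#'
#' A session retains at most two runs (the current one and the most recent
#' previous one, for overlay comparison) and stamps its 5-digit id into
#' every exported filename so concurrent sessions never collide.
#'
#' @param id optional 5-digit id string; drawn at random when omitted.
#' @return A `sim_session` object.
#' @export
new_session <- function(id = NULL) {
  if (is.null(id)) id <- sprintf("%05d", sample.int(99999L, 1))
  stopifnot(grepl("^[0-9]{5}$", id))
  structure(list(id = id, runs = list(), counter = 0L), class = "sim_session")
}

#' @export
print.sim_session <- function(x, ...) {
  cat(sprintf("<sim_session %s> %d run(s) retained, %d run(s) so far\n",
              x$id, length(x$runs), x$counter))
  invisible(x)
}

#' Run a simulation within a session
#'
#' Executes [simulate_day()], numbers the run (1 for the baseline, then
#' incrementing), and rotates the session's retained runs: the previous
#' current run becomes the comparison run and anything older is discarded.
#'
#' @param scenario a `case_scenario`.
#' @param options a [simulator_options()] object.
#' @param session a [new_session()] object.
#' @param tables,constants,registry forwarded to [simulate_day()].
#' @return List with `run` (a `simulation_run`) and the updated `session`.
#' @export
#' @examples
#' \donttest{
#' s <- new_session("00001")
#' out <- run_simulation(random_scenario(1), simulator_options(), s)
#' out$run$run_number  # 1
#' }
run_simulation <- function(scenario, options = simulator_options(),
                           session = new_session(),
                           tables = default_profile_tables(),
                           constants = model_constants(),
                           registry = insulin_registry()) {
  stopifnot(inherits(options, "simulator_options"),
            inherits(session, "sim_session"))
  result <- simulate_day(scenario, tables, constants, registry)
  session$counter <- session$counter + 1L
  run <- structure(c(unclass(result),
                     list(run_number = session$counter, options = options,
                          session_id = session$id)),
                   class = c("simulation_run", "simulation_result"))
  session$runs <- c(list(run), session$runs)
  if (length(session$runs) > 2L) session$runs <- session$runs[1:2]
  list(run = run, session = session)
}

# The six exported series: name -> (field, units label).
.export_members <- list(
  bg = c("bg", "mmol_per_L"),
  plasma_insulin = c("plasma_insulin", "mU_per_L"),
  glucose_absorption = c("gut_absorption", "mmol_per_h"),
  renal_excretion = c("renal_excretion", "mmol_per_h"),
  peripheral_utilization = c("peripheral_uptake", "mmol_per_h"),
  nhgb = c("nhgb", "mmol_per_h")
)

#' Export a run's six data files
#'
#' Writes the blood glucose, plasma insulin and four flux series as six
#' two-column (time, value) ASCII files with 97 rows each, at 15-min
#' spacing from 0 to 24 h. Filenames carry the session id and run number,
#' e.g. `12345_run1_bg.dat`. Blood glucose is written in the run's display
#' units.
#'
#' @param run a `simulation_run` from [run_simulation()].
#' @param directory output directory (created if needed).
#' @return Character vector of the six file paths, invisibly.
#' @export
export_run <- function(run, directory) {
  stopifnot(inherits(run, "simulation_run"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory)) {
    stop("cannot create export directory: ", directory, call. = FALSE)
  }
  time_h <- run$time_min / 60
  paths <- character()
  for (nm in names(.export_members)) {
    field <- .export_members[[nm]][1]
    units <- .export_members[[nm]][2]
    values <- run[[field]]
    if (nm == "bg" && run$options$bg_units == "mg_per_dL") {
      values <- convert_bg(values, "mmol_per_L", "mg_per_dL")
      units <- "mg_per_dL"
    }
    path <- file.path(directory, sprintf("%s_run%d_%s.dat",
                                         run$session_id, run$run_number, nm))
    lines <- c(sprintf("# time_h %s", units),
               sprintf("%.4f %.6f", time_h, values))
    writeLines(lines, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Remove a session's exported files from a directory
#'
#' @param directory export directory.
#' @param session_id 5-digit session id whose files to remove; `NULL`
#'   removes all `.dat`/`.png` exports in the directory.
#' @return Number of files removed, invisibly.
#' @export
clean_exports <- function(directory, session_id = NULL) {
  if (!dir.exists(directory)) return(invisible(0L))
  pattern <- if (is.null(session_id)) {
    "^[0-9]{5}_run[0-9]+.*\\.(dat|png)$"
  } else {
    paste0("^", session_id, "_run[0-9]+.*\\.(dat|png)$")
  }
  files <- list.files(directory, pattern = pattern, full.names = TRUE)
  unlink(files)
  invisible(length(files))
}

#' Overlay description for plotting a session's runs
#'
#' @param session a session holding at least one run.
#' @return List with `current` (the highlighted run), `previous` (the
#'   comparison run, or `NULL` after a baseline run) and `bounds`
#'   (`c(lower, upper)` mmol/L when the current run's options request the
#'   bounds lines, else `NULL`).
#' @export
comparison_payload <- function(session) {
  stopifnot(inherits(session, "sim_session"))
  if (!length(session$runs)) {
    stop("session holds no runs yet", call. = FALSE)
  }
  current <- session$runs[[1]]
  list(current = current,
       previous = if (length(session$runs) > 1L) session$runs[[2]],
       bounds = if (isTRUE(current$options$show_bounds)) current$options$bounds)
}
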