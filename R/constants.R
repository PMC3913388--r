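# Model constants, physiological presets and the NHGB lookup grid.

#' Default model constants
#'
#' Builds the full set of rate constants, distribution volumes and lookup
#' grids used by the simulation engine. All values are editable: pass
#' overrides as named arguments (scalars, or a replacement NHGB grid), or
#' load them from a config file with [load_config()].
#'
#' The defaults describe a nominal insulin-dependent adult and are the
#' package's own calibration of the classic two-compartment educational
#' model family; they are documented, with units and rationale, in the
#' methods vignette.
#'
#' @param ... named overrides for any constant, e.g. `Km = 12`.
#' @return An object of class `model_constants` (a validated named list) with
#'   elements:
#' \describe{
#'   \item{Vg}{glucose distribution volume, L/kg (default 0.22)}
#'   \item{Vi}{insulin distribution volume, L/kg (default 0.142)}
#'   \item{ke}{plasma insulin elimination rate, 1/h (default 5.4)}
#'   \item{k_act}{plasma to effect-compartment transfer rate, 1/h (default 1.2)}
#'   \item{Km}{half-saturation of peripheral glucose utilization, mmol/L (default 10)}
#'   \item{carb_mmol_per_g}{glucose equivalent of dietary carbohydrate,
#'     mmol/g (default 5.551, from the 180.16 g/mol molar mass of glucose)}
#'   \item{gut_absorption_rate}{first-order gut absorption rate, 1/h (default 1.8)}
#'   \item{emptying_vmax}{maximal gastric emptying rate, mmol/h (default 120)}
#'   \item{emptying_ascent_h, emptying_descent_h}{ramp durations of the
#'     trapezoidal emptying profile, h (default 0.5 each)}
#'   \item{peripheral_base}{insulin-independent peripheral utilization at
#'     glucose saturation, mmol/h (default 45)}
#'   \item{peripheral_insulin_slope}{insulin-dependent utilization slope,
#'     mmol/h per effective mU/L (default 4.8)}
#'   \item{bg_floor}{lower clamp on simulated blood glucose, mmol/L (default 0.5)}
#'   \item{ss_tol}{periodic steady-state tolerance, mmol/L max-norm (default 0.01)}
#'   \item{ss_max_iter}{day-iteration cap (default 50)}
#'   \item{nhgb}{net hepatic glucose balance grid, see [net_hepatic_balance()]}
#'   \item{hba1c_model}{"linear" (default) or "eag", see [hba1c_estimate()]}
#' }
#' @seealso [preset_lookup()], [load_config()], [simulate_day()]
#' @export
#' @examples
#' cc <- model_constants()
#' cc$Km
#' model_constants(Km = 12)$Km
model_constants <- function(...) {
  defaults <- list(
    Vg = 0.22,
    Vi = 0.142,
    ke = 5.4,
    k_act = 1.2,
    Km = 10,
    carb_mmol_per_g = 5.551,
    gut_absorption_rate = 1.8,
    emptying_vmax = 120,
    emptying_ascent_h = 0.5,
    emptying_descent_h = 0.5,
    peripheral_base = 45,
    peripheral_insulin_slope = 4.8,
    bg_floor = 0.5,
    ss_tol = 0.01,
    ss_max_iter = 50L,
    nhgb = default_nhgb_grid(),
    hba1c_model = "linear"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides)))) {
      stop("all overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown)) {
      stop("unknown constant(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  validate_constants(defaults)
  structure(defaults, class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("<model_constants>\n")
  scalars <- x[!vapply(x, is.list, logical(1))]
  for (nm in names(scalars)) cat(sprintf("  %-24s %s\n", nm, format(scalars[[nm]])))
  cat(sprintf("  nhgb grid: %d insulin x %d glucose nodes\n",
              length(x$nhgb$ins_nodes), length(x$nhgb$g_nodes)))
  invisible(x)
}

# Stops with the offending key on any invariant violation.
validate_constants <- function(cc) {
  pos <- c("Vg", "Vi", "ke", "k_act", "Km", "carb_mmol_per_g",
           "gut_absorption_rate", "emptying_vmax", "emptying_ascent_h",
           "emptying_descent_h", "peripheral_base", "peripheral_insulin_slope",
           "bg_floor", "ss_tol")
  for (key in pos) {
    v <- cc[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("invalid constant '", key, "': must be a positive finite number",
           call. = FALSE)
    }
  }
  if (!is.numeric(cc$ss_max_iter) || cc$ss_max_iter < 1) {
    stop("invalid constant 'ss_max_iter': must be >= 1", call. = FALSE)
  }
  if (!cc$hba1c_model %in% c("linear", "eag")) {
    stop("invalid constant 'hba1c_model': must be \"linear\" or \"eag\"",
         call. = FALSE)
  }
  validate_nhgb_grid(cc$nhgb)
  invisible(cc)
}

#' Default net hepatic glucose balance grid
#'
#' The liver flux is tabulated (mmol/h, positive = production, negative =
#' uptake) over nodes of effective hepatic insulin (`Sh * active insulin`,
#' mU/L) by blood glucose (mmol/L), and bilinearly interpolated at run time.
#' Values decrease along both axes: more insulin or more glucose shifts the
#' liver from production towards uptake.
#'
#' @return A list with `ins_nodes`, `g_nodes` and a `values` matrix
#'   (rows = insulin nodes, columns = glucose nodes).
#' @export
default_nhgb_grid <- function() {
  grid <- list(
    ins_nodes = c(0, 5, 10, 20, 40, 80),
    g_nodes = c(0, 4, 7, 10, 15, 25),
    values = rbind(
      c(50,  47,  45,  43,  41,  39),
      c(32,  29,  27,  25,  23,  21),
      c(18,  15,  13,  11,   9,   7),
      c(4,    1,  -1,  -3,  -5,  -7),
      c(-8, -11, -13, -15, -17, -19),
      c(-16, -19, -21, -23, -25, -27)
    )
  )
  validate_nhgb_grid(grid)
  grid
}

validate_nhgb_grid <- function(grid) {
  if (!is.list(grid) || !all(c("ins_nodes", "g_nodes", "values") %in% names(grid))) {
    stop("invalid constant 'nhgb': need ins_nodes, g_nodes and values",
         call. = FALSE)
  }
  v <- grid$values
  if (!is.matrix(v) ||
      nrow(v) != length(grid$ins_nodes) || ncol(v) != length(grid$g_nodes)) {
    stop("invalid constant 'nhgb': values must be ",
         length(grid$ins_nodes), " x ", length(grid$g_nodes), call. = FALSE)
  }
  if (is.unsorted(grid$ins_nodes, strictly = TRUE) ||
      is.unsorted(grid$g_nodes, strictly = TRUE)) {
    stop("invalid constant 'nhgb': node vectors must be strictly increasing",
         call. = FALSE)
  }
  if (any(apply(v, 2, function(col) any(diff(col) > 0)))) {
    stop("invalid constant 'nhgb': values must be non-increasing in insulin",
         call. = FALSE)
  }
  if (any(apply(v, 1, function(row) any(diff(row) > 0)))) {
    stop("invalid constant 'nhgb': values must be non-increasing in glucose",
         call. = FALSE)
  }
  invisible(grid)
}

# Preset table: categorical physiology -> numeric value.
.presets <- list(
  RTG = c(low_reduced = 7, normal = 9, high_increased = 11),
  CCR = c(low_reduced = 40, normal = 100, high_increased = NA_real_),
  hepatic_sensitivity = c(low_reduced = 0.2, normal = 0.5, high_increased = 0.8),
  peripheral_sensitivity = c(low_reduced = 0.2, normal = 0.5, high_increased = 0.8)
)

#' Physiological parameter presets
#'
#' Maps the categorical physiology entries of a case scenario
#' ("low/reduced", "normal", "high/increased") to numeric parameter values:
#' renal threshold of glucose (RTG, mmol/L), creatinine clearance rate
#' (CCR, mL/min, used as a glomerular filtration rate estimate), and the
#' dimensionless hepatic and peripheral insulin sensitivities. Creatinine
#' clearance has no "high/increased" preset.
#'
#' @param parameter one of `"RTG"`, `"CCR"`, `"hepatic_sensitivity"`,
#'   `"peripheral_sensitivity"`.
#' @param category one of `"low_reduced"`, `"normal"`, `"high_increased"`.
#' @return The preset numeric value.
#' @export
#' @examples
#' preset_lookup("RTG", "normal")      # 9 mmol/L
#' preset_lookup("CCR", "low_reduced") # 40 mL/min
preset_lookup <- function(parameter, category) {
  parameter <- match.arg(parameter, names(.presets))
  category <- match.arg(category, c("low_reduced", "normal", "high_increased"))
  value <- .presets[[parameter]][[category]]
  if (is.na(value)) {
    stop("unsupported combination: no '", category, "' preset for ", parameter,
         call. = FALSE)
  }
  value
}

#' Resolve a scenario's categorical physiology into numeric patient parameters
#'
#' @param scenario a `case_scenario` object.
#' @return A list with `weight` (kg), `RTG` (mmol/L), `CCR` (mL/min),
#'   `Sh` and `Sp` (dimensionless sensitivities).
#' @export
patient_parameters <- function(scenario) {
  stopifnot(inherits(scenario, "case_scenario"))
  list(
    weight = scenario$weight,
    RTG = preset_lookup("RTG", scenario$categories$rtg),
    CCR = preset_lookup("CCR", scenario$categories$ccr),
    Sh = preset_lookup("hepatic_sensitivity", scenario$categories$hepatic),
    Sp = preset_lookup("peripheral_sensitivity", scenario$categories$peripheral)
  )
}

#' Convert a body weight entered in pounds to kilograms
#'
#' @param lb weight in pounds.
#' @return Weight in kg (0.45359237 kg/lb).
#' @export
lb_to_kg <- function(lb) lb * 0.45359237
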