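# Subcutaneous insulin absorption and carbohydrate gut appearance:
# the precomputed, dose-indexed profile tables that drive the simulation.

.class_file_stem <- c(ACTRAPID_LIKE = "Actrapid", NPH_LIKE = "NPH",
                      LENTE_LIKE = "Lente", ULTRALENTE_LIKE = "UltraLente")

#' Absorption-curve parameters for the four insulin classes
#'
#' Subcutaneous absorption is modelled as a sigmoid cumulative fraction
#' `F(t) = t^s / (T50(D)^s + t^s)` with a dose-dependent half-absorption
#' time `T50(D) = a*D + b` (hours): larger depots absorb more slowly, which
#' is why the lookup tables are indexed by dose rather than scaled per unit.
#' The default parameters place the plasma peaks in the classic order
#' short < NPH <= Lente < UltraLente.
#'
#' @param class_id one of `"ACTRAPID_LIKE"`, `"NPH_LIKE"`, `"LENTE_LIKE"`,
#'   `"ULTRALENTE_LIKE"`, or `NULL` for the full named list.
#' @return A list with `class_id`, `s` (dimensionless shape, > 1),
#'   `a` (h/IU) and `b` (h); or a named list of all four.
#' @export
#' @examples
#' absorption_class_params("ACTRAPID_LIKE")
absorption_class_params <- function(class_id = NULL) {
  all <- list(
    ACTRAPID_LIKE   = list(class_id = "ACTRAPID_LIKE",   s = 2, a = 0.05, b = 1.7),
    NPH_LIKE        = list(class_id = "NPH_LIKE",        s = 2, a = 0.09, b = 4.5),
    LENTE_LIKE      = list(class_id = "LENTE_LIKE",      s = 2, a = 0.11, b = 5.5),
    ULTRALENTE_LIKE = list(class_id = "ULTRALENTE_LIKE", s = 2, a = 0.15, b = 9.0)
  )
  for (p in all) validate_class_params(p)
  if (is.null(class_id)) return(all)
  class_id <- match.arg(class_id, names(all))
  all[[class_id]]
}

validate_class_params <- function(p) {
  if (!all(c("class_id", "s", "a", "b") %in% names(p))) {
    stop("absorption class params need class_id, s, a, b", call. = FALSE)
  }
  if (p$s <= 1) stop("shape s must be > 1 for class ", p$class_id, call. = FALSE)
  if (p$b <= 0) stop("t50 intercept b must be > 0 for class ", p$class_id,
                     call. = FALSE)
  if (p$a < 0) stop("t50 slope a must be >= 0 for class ", p$class_id,
                    call. = FALSE)
  invisible(p)
}

#' Cumulative fraction of a subcutaneous dose absorbed by time t
#'
#' @param t hours since injection (vectorized, >= 0).
#' @param dose dose in IU, in (0, 40].
#' @param params class parameters from [absorption_class_params()].
#' @return Fraction in `[0, 1)`, non-decreasing in `t`, 0.5 at
#'   `t = T50(dose)`, tending to 1 as `t` grows.
#' @export
#' @examples
#' p <- absorption_class_params("ACTRAPID_LIKE")
#' absorption_fraction(c(0, 2, 8), dose = 8, params = p)
absorption_fraction <- function(t, dose, params) {
  if (any(t < 0)) stop("t must be >= 0 (hours since injection)", call. = FALSE)
  if (!is.numeric(dose) || length(dose) != 1L || dose <= 0 || dose > 40) {
    stop("dose out of range: must be in (0, 40] IU", call. = FALSE)
  }
  t50 <- params$a * dose + params$b
  t^params$s / (t50^params$s + t^params$s)
}

# Instantaneous absorption rate dose * dF/dt, IU/h (closed form).
absorption_rate <- function(t, dose, params) {
  if (dose == 0) return(numeric(length(t)))
  s <- params$s
  t50 <- params$a * dose + params$b
  num <- s * t^(s - 1) * t50^s
  dose * num / (t50^s + t^s)^2
}

#' Plasma and active insulin response to a single subcutaneous injection
#'
#' The absorption rate (the time derivative of [absorption_fraction()] times
#' the dose) feeds a first-order plasma compartment (elimination rate `ke`),
#' which in turn drives a first-order effect ("active") compartment
#' (transfer rate `k_act`). Both series are amounts in IU on a unit
#' distribution-volume basis; the engine divides by `Vi * weight` when a
#' concentration is needed, so the tables stay patient-independent.
#'
#' @param dose IU, in `[0, 40]`.
#' @param class_params from [absorption_class_params()].
#' @param constants from [model_constants()].
#' @param horizon_h simulation horizon, hours (>= 24).
#' @param dt_min Euler step, minutes (must divide 60).
#' @return A list with `time_min`, `rate` (IU/h absorbed), `plasma` and
#'   `active` (IU), all of length `horizon_h * 60 / dt_min + 1`.
#' @export
single_injection_response <- function(dose, class_params,
                                      constants = model_constants(),
                                      horizon_h = 360, dt_min = 1) {
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0 || dose > 40) {
    stop("dose out of range: must be in [0, 40] IU", call. = FALSE)
  }
  if (horizon_h < 24) stop("horizon_h must be >= 24", call. = FALSE)
  if (60 %% dt_min != 0) stop("dt_min must divide 60", call. = FALSE)
  time_min <- seq(0, horizon_h * 60, by = dt_min)
  t_h <- time_min / 60
  rate <- absorption_rate(t_h, dose, class_params)
  dt_h <- dt_min / 60
  # Euler recursions X[n+1] = X[n]*(1 - k*dt) + dt*input[n], vectorized.
  plasma <- euler_first_order(rate, constants$ke, dt_h)
  active <- euler_first_order(constants$k_act * plasma, constants$k_act, dt_h)
  if (any(!is.finite(plasma)) || any(!is.finite(active))) {
    stop("numerical failure in injection response (class ",
         class_params$class_id, ", dose ", dose, " IU)", call. = FALSE)
  }
  list(time_min = time_min, rate = rate, plasma = plasma, active = active)
}

# Explicit-Euler solution of x' = input - k*x, x(0) = 0, via a recursive
# filter; input is sampled at the step boundaries.
euler_first_order <- function(input, k, dt_h) {
  n <- length(input)
  if (k * dt_h >= 1) stop("Euler step too large for rate ", k, "/h", call. = FALSE)
  drive <- dt_h * input[-n]
  c(0, stats::filter(drive, 1 - k * dt_h, method = "recursive"))
}

# Fold a fine-grained series onto the 97-point periodic day grid:
# value at grid minute g is the sum of the series at g + k*1440 for all
# whole days k inside the horizon (steady-state daily repetition).
fold_to_day_grid <- function(values, dt_min) {
  stopifnot(1440 %% dt_min == 0)
  per_day <- 1440 / dt_min
  n_days <- (length(values) - 1) %/% per_day
  stopifnot(n_days >= 1)
  folded <- rowSums(matrix(values[seq_len(per_day * n_days)], nrow = per_day))
  idx <- seq(1, per_day, by = 15 / dt_min)
  day <- folded[idx]
  c(day, day[1]) # 97 points, periodic closure
}

#' Construct a validated absorption lookup table
#'
#' @param kind `"insulin_plasma"`, `"insulin_active"` or `"carbohydrate"`.
#' @param values numeric matrix: 41 rows (0-40 IU) x 97 columns for insulin
#'   kinds, 81 rows (0-80 g) x 97 columns for the carbohydrate kind; one
#'   column per 15-min grid point over 0-24 h.
#' @param class_id insulin absorption class (insulin kinds only).
#' @return An `absorption_table` object.
#' @export
absorption_table <- function(kind, values, class_id = NULL) {
  kind <- match.arg(kind, c("insulin_plasma", "insulin_active", "carbohydrate"))
  expect_rows <- if (kind == "carbohydrate") 81L else 41L
  if (kind != "carbohydrate") {
    class_id <- match.arg(class_id, names(.class_file_stem))
  } else {
    class_id <- NULL
  }
  if (!is.matrix(values) || nrow(values) != expect_rows || ncol(values) != 97L) {
    stop(kind, " table must be ", expect_rows, " x 97", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < -1e-12)) {
    stop(kind, " table values must be finite and non-negative", call. = FALSE)
  }
  if (any(abs(values[1, ]) > 1e-12)) {
    stop(kind, " table row 0 must be all zeros", call. = FALSE)
  }
  structure(list(kind = kind, class_id = class_id, values = values),
            class = "absorption_table")
}

#' @export
print.absorption_table <- function(x, ...) {
  cat(sprintf("<absorption_table> kind=%s%s, %d rows x %d time points\n",
              x$kind, if (!is.null(x$class_id)) paste0(" class=", x$class_id) else "",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Precompute the dose-indexed insulin tables for one absorption class
#'
#' Row `d + 1` holds the periodic-day folding of the
#' [single_injection_response()] at dose `d` IU, sampled on the 15-min grid:
#' the response is computed over a long internal horizon so that slow
#' (long-acting) tails are captured, then wrapped onto 24 h, which is exact
#' under steady-state daily repetition of the regimen.
#'
#' @inheritParams single_injection_response
#' @return List of two [absorption_table()]s: `plasma` and `active`.
#' @export
build_insulin_tables <- function(class_params, constants = model_constants(),
                                 horizon_h = 360, dt_min = 1) {
  validate_class_params(class_params)
  rows_p <- rows_a <- matrix(0, nrow = 41, ncol = 97)
  for (d in 1:40) {
    resp <- single_injection_response(d, class_params, constants,
                                      horizon_h = horizon_h, dt_min = dt_min)
    rows_p[d + 1, ] <- fold_to_day_grid(resp$plasma, dt_min)
    rows_a[d + 1, ] <- fold_to_day_grid(resp$active, dt_min)
  }
  list(
    plasma = absorption_table("insulin_plasma", rows_p, class_params$class_id),
    active = absorption_table("insulin_active", rows_a, class_params$class_id)
  )
}

#' Gut glucose appearance after a carbohydrate meal
#'
#' Gastric emptying follows a trapezoidal rate profile: a linear ramp up
#' over `emptying_ascent_h`, a plateau at `emptying_vmax` (mmol/h), and a
#' linear ramp down over `emptying_descent_h`. Meals below the critical
#' load (the area of the ramps alone) use a triangular profile of the same
#' width with a reduced peak. The emptied glucose then passes through a
#' first-order gut compartment (`gut_absorption_rate`), whose outflow is
#' the systemic appearance rate. Total appearance equals
#' `grams * carb_mmol_per_g`.
#'
#' @param grams grams of carbohydrate, integer in `[0, 80]`.
#' @param constants from [model_constants()].
#' @param horizon_h series horizon, hours.
#' @param dt_min output grid spacing, minutes (computed internally at 1 min).
#' @return Appearance rate series, mmol/h, at `dt_min` spacing from 0 to
#'   `horizon_h` hours inclusive.
#' @export
#' @examples
#' app <- gastric_emptying_profile(60)
#' sum(app) * 15 / 60  # close to 60 * 5.551 mmol
gastric_emptying_profile <- function(grams, constants = model_constants(),
                                     horizon_h = 24, dt_min = 15) {
  if (!is.numeric(grams) || length(grams) != 1L || is.na(grams)) {
    stop("grams must be a single number", call. = FALSE)
  }
  if (grams < 0) stop("grams must be >= 0", call. = FALSE)
  if (grams > 80) {
    stop("grams exceed the 0-80 g carbohydrate table bound", call. = FALSE)
  }
  stopifnot(dt_min %% 1 == 0, dt_min >= 1, 1440 %% dt_min == 0)
  time_min <- seq(0, horizon_h * 60, by = 1)
  t_h <- time_min / 60
  load <- grams * constants$carb_mmol_per_g
  ta <- constants$emptying_ascent_h
  td <- constants$emptying_descent_h
  vmax <- constants$emptying_vmax
  critical <- vmax * (ta + td) / 2
  if (load >= critical) {
    peak <- vmax
    tp <- load / vmax - (ta + td) / 2
  } else {
    peak <- 2 * load / (ta + td)
    tp <- 0
  }
  emptying <- ifelse(t_h < ta, peak * t_h / ta,
              ifelse(t_h < ta + tp, peak,
              ifelse(t_h < ta + tp + td, peak * (1 - (t_h - ta - tp) / td), 0)))
  k <- constants$gut_absorption_rate
  gut <- euler_first_order(emptying, k, 1 / 60)
  appearance <- k * gut
  appearance[seq(1, length(appearance), by = dt_min)]
}

#' Precompute the grams-indexed carbohydrate appearance table
#'
#' Row `g + 1` is [gastric_emptying_profile()] for `g` grams, folded onto
#' the periodic 24-h grid.
#'
#' @param constants from [model_constants()].
#' @param horizon_h internal horizon before folding, hours.
#' @return An [absorption_table()] of kind `"carbohydrate"`, 81 x 97.
#' @export
build_carb_table <- function(constants = model_constants(), horizon_h = 72) {
  rows <- matrix(0, nrow = 81, ncol = 97)
  for (g in 1:80) {
    app <- gastric_emptying_profile(g, constants, horizon_h = horizon_h,
                                    dt_min = 1)
    rows[g + 1, ] <- fold_to_day_grid(app, 1)
  }
  absorption_table("carbohydrate", rows)
}

#' Build the complete nine-member profile table set
#'
#' Eight insulin tables (plasma and active response for each of the four
#' absorption classes) plus the carbohydrate table, named after the nine
#' storage files: `Actrapid_pa`, `Actrapid_act`, `NPH_pa`, `NPH_act`,
#' `Lente_pa`, `Lente_act`, `UltraLente_pa`, `UltraLente_act`, `CAR`.
#'
#' Building takes a few seconds; the default-parameter set is cached per
#' session (see [default_profile_tables()]).
#'
#' @param class_params named list of per-class parameters, as returned by
#'   [absorption_class_params()].
#' @param constants from [model_constants()].
#' @return Named list of nine [absorption_table()]s.
#' @export
build_profile_tables <- function(class_params = absorption_class_params(),
                                 constants = model_constants()) {
  out <- list()
  for (cls in names(.class_file_stem)) {
    tabs <- build_insulin_tables(class_params[[cls]], constants)
    stem <- .class_file_stem[[cls]]
    out[[paste0(stem, "_pa")]] <- tabs$plasma
    out[[paste0(stem, "_act")]] <- tabs$active
  }
  out$CAR <- build_carb_table(constants)
  out[profile_file_names()]
}

.glucosim_cache <- new.env(parent = emptyenv())

#' Default profile tables, built once per session
#'
#' @return The nine-member table set for the default absorption-class
#'   parameters and model constants (cached after the first call).
#' @export
default_profile_tables <- function() {
  if (is.null(.glucosim_cache$tables)) {
    .glucosim_cache$tables <- build_profile_tables()
  }
  .glucosim_cache$tables
}
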