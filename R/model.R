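# The physiological model: four glucose fluxes, insulin superposition,
# Euler integration at 15-minute steps to a 24-h periodic steady state.

#' Renal excretion of glucose into the urine
#'
#' Zero below the renal threshold of glucose (RTG); above it, glucose is
#' lost at the glomerular filtration rate times the excess concentration.
#' Creatinine clearance (mL/min) serves as the GFR estimate and is
#' converted to L/h, so 100 mL/min clears 6 L/h.
#'
#' @param G blood glucose, mmol/L (vectorized).
#' @param params patient parameters from [patient_parameters()] (uses
#'   `RTG` and `CCR`).
#' @return Excretion rate, mmol/h; continuous at `G = RTG`.
#' @export
#' @examples
#' p <- list(RTG = 9, CCR = 100)
#' renal_excretion_rate(c(8, 9, 11), p)  # 0, 0, 12
renal_excretion_rate <- function(G, params) {
  if (any(G < 0)) stop("G must be >= 0", call. = FALSE)
  gfr_l_per_h <- params$CCR * 60 / 1000
  pmax(0, G - params$RTG) * gfr_l_per_h
}

#' Peripheral glucose utilization
#'
#' Saturable in glucose through a factor `G / (Km + G)`, multiplying the
#' sum of an insulin-independent uptake (brain and obligate consumers) and
#' a term linear in effective peripheral insulin `Sp * Ia`. Monotone
#' non-decreasing in `G`, `Ia` and `Sp`.
#'
#' @param G blood glucose, mmol/L (vectorized).
#' @param Ia active (effect-compartment) insulin, mU/L (vectorized).
#' @param params patient parameters (uses `Sp`).
#' @param constants from [model_constants()] (uses `Km`, `peripheral_base`,
#'   `peripheral_insulin_slope`).
#' @return Utilization rate, mmol/h.
#' @export
peripheral_utilization_rate <- function(G, Ia, params,
                                        constants = model_constants()) {
  if (any(G < 0) || any(Ia < 0)) stop("G and Ia must be >= 0", call. = FALSE)
  sat <- G / (constants$Km + G)
  sat * (constants$peripheral_base +
           constants$peripheral_insulin_slope * params$Sp * Ia)
}

#' Net hepatic glucose balance
#'
#' The signed liver flux: positive values are hepatic glucose production,
#' negative values hepatic uptake. Evaluated by bilinear interpolation on
#' the tabulated grid in `constants$nhgb` at the point
#' (`Sh * Ia`, `G`); arguments outside the grid hull are clamped to it,
#' never extrapolated. The grid is monotone non-increasing along both axes
#' (checked at load), so more insulin or more glucose always moves the
#' liver towards uptake.
#'
#' @param G blood glucose, mmol/L (vectorized).
#' @param Ia active insulin, mU/L (vectorized).
#' @param params patient parameters (uses `Sh`).
#' @param constants from [model_constants()].
#' @return Net hepatic glucose balance, mmol/h (signed).
#' @export
net_hepatic_balance <- function(G, Ia, params, constants = model_constants()) {
  if (any(G < 0) || any(Ia < 0)) stop("G and Ia must be >= 0", call. = FALSE)
  grid <- constants$nhgb
  x <- pmin(pmax(params$Sh * Ia, min(grid$ins_nodes)), max(grid$ins_nodes))
  y <- pmin(pmax(G, min(grid$g_nodes)), max(grid$g_nodes))
  bilinear_interp(grid$ins_nodes, grid$g_nodes, grid$values, x, y)
}

# Vectorized bilinear interpolation on a rectilinear grid.
bilinear_interp <- function(xs, ys, z, x, y) {
  i <- pmin(pmax(findInterval(x, xs), 1L), length(xs) - 1L)
  j <- pmin(pmax(findInterval(y, ys), 1L), length(ys) - 1L)
  fx <- (x - xs[i]) / (xs[i + 1] - xs[i])
  fy <- (y - ys[j]) / (ys[j + 1] - ys[j])
  z00 <- z[cbind(i, j)]; z10 <- z[cbind(i + 1L, j)]
  z01 <- z[cbind(i, j + 1L)]; z11 <- z[cbind(i + 1L, j + 1L)]
  (1 - fx) * (1 - fy) * z00 + fx * (1 - fy) * z10 +
    (1 - fx) * fy * z01 + fx * fy * z11
}

#' Daily plasma and active insulin profiles for an injection regimen
#'
#' Superposes the dose-indexed table rows of every injection (after
#' premixed preparations are split into their short- and
#' intermediate-acting components with [biphasic_split()]), each circularly
#' shifted to its injection time. Because the table rows are already folded
#' onto the periodic day, the circular shift is exact under steady-state
#' daily repetition of the regimen. Doses and times are snapped to the
#' nearest table row / 15-min grid point (with a message when snapping
#' changes a value).
#'
#' @param injections data frame with columns `time_min`, `dose` and
#'   `preparation` (brand name), at most 4 injections per preparation.
#' @param tables a nine-member table set from [build_profile_tables()] or
#'   [default_profile_tables()].
#' @param weight patient weight, kg.
#' @param constants from [model_constants()] (uses `Vi`).
#' @param registry an [insulin_registry()].
#' @return List of two 97-point series (mU/L on the 15-min grid):
#'   `plasma` and `active`.
#' @export
insulin_day_profiles <- function(injections, tables, weight,
                                 constants = model_constants(),
                                 registry = insulin_registry()) {
  plasma <- active <- numeric(96)
  if (nrow(injections)) {
    counts <- table(injections$preparation)
    if (any(counts > 4)) {
      stop("more than 4 injections of one preparation: ",
           paste(names(counts)[counts > 4], collapse = ", "), call. = FALSE)
    }
    for (r in seq_len(nrow(injections))) {
      prep <- resolve_preparation(injections$preparation[r], registry)
      dose <- injections$dose[r]
      if (dose < 0 || dose > 40) {
        stop("dose out of range: ", dose, " IU (allowed 0-40)", call. = FALSE)
      }
      components <- if (prep$category == "biphasic") {
        split <- biphasic_split(dose, prep)
        list(list(class = "ACTRAPID_LIKE", dose = split[["short"]]),
             list(class = prep$intermediate_class,
                  dose = split[["intermediate"]]))
      } else {
        list(list(class = prep$class, dose = dose))
      }
      shift <- round(injections$time_min[r] / 15) %% 96
      if (abs(shift * 15 - injections$time_min[r]) > 1e-9 &&
          injections$time_min[r] < 1440) {
        message("injection time ", format_hhmm(injections$time_min[r]),
                " snapped to ", format_hhmm(shift * 15))
      }
      for (comp in components) {
        row_idx <- round(comp$dose) + 1L
        if (abs(comp$dose - round(comp$dose)) > 1e-9) {
          message("dose ", comp$dose, " IU snapped to table row ",
                  row_idx - 1L, " IU")
        }
        stem <- .class_file_stem[[comp$class]]
        pa_row <- tables[[paste0(stem, "_pa")]]$values[row_idx, 1:96]
        act_row <- tables[[paste0(stem, "_act")]]$values[row_idx, 1:96]
        idx <- ((seq_len(96) - 1 - shift) %% 96) + 1
        plasma <- plasma + pa_row[idx]
        active <- active + act_row[idx]
      }
    }
  }
  scale <- 1000 / (constants$Vi * weight)  # IU amount -> mU/L
  list(plasma = c(plasma, plasma[1]) * scale,
       active = c(active, active[1]) * scale)
}

#' Daily gut glucose appearance for a meal schedule
#'
#' @param meals data frame with columns `time_min` and `grams`.
#' @param tables table set containing the `CAR` member.
#' @return 97-point appearance series, mmol/h, on the 15-min grid.
#' @export
carb_day_profile <- function(meals, tables) {
  gut <- numeric(96)
  car <- tables$CAR$values
  for (r in seq_len(nrow(meals))) {
    g <- meals$grams[r]
    if (g < 0 || g > 80) {
      stop("grams out of range: ", g, " (allowed 0-80)", call. = FALSE)
    }
    row_idx <- round(g) + 1L
    shift <- round(meals$time_min[r] / 15) %% 96
    row <- car[row_idx, 1:96]
    idx <- ((seq_len(96) - 1 - shift) %% 96) + 1
    gut <- gut + row[idx]
  }
  c(gut, gut[1])
}

#' One explicit-Euler glucose step
#'
#' Advances blood glucose by `dt` minutes under the four-flux balance:
#' `G' = G + dt * (gut_in + nhgb - peripheral - renal) / (Vg * weight)`,
#' floored at `constants$bg_floor`.
#'
#' @param G blood glucose, mmol/L.
#' @param fluxes named list or vector with `gut_in`, `nhgb`, `peripheral`,
#'   `renal`, all mmol/h (`nhgb` signed).
#' @param params patient parameters (uses `weight`).
#' @param constants from [model_constants()].
#' @param dt_min step, minutes (default 15).
#' @return Updated glucose, mmol/L.
#' @export
#' @examples
#' p <- list(weight = 70)
#' glucose_step(7, list(gut_in = 12, nhgb = 0, peripheral = 0, renal = 0), p)
glucose_step <- function(G, fluxes, params, constants = model_constants(),
                         dt_min = 15) {
  net <- fluxes$gut_in + fluxes$nhgb - fluxes$peripheral - fluxes$renal
  if (!is.finite(net)) {
    stop("non-finite flux in glucose step (G = ", G, ")", call. = FALSE)
  }
  max(constants$bg_floor,
      G + (dt_min / 60) * net / (constants$Vg * params$weight))
}

#' Simulate one case scenario to its 24-h periodic steady state
#'
#' Runs the 24-hour Euler pass repeatedly, feeding each day's final glucose
#' into the next day's start, until the whole daily glucose trajectory
#' changes by less than `constants$ss_tol` (max-norm) between consecutive
#' days. Since meals and injections repeat identically every day, the
#' converged solution is the model's periodic steady state and closes on
#' itself at the day boundary.
#'
#' Within each Euler interval the meal and insulin driver series are
#' sampled as interval averages (trapezoidal sampling of the forcing),
#' while the glucose-dependent fluxes are evaluated explicitly at the
#' interval start; the flux series in the returned object are pointwise
#' evaluations on the grid for display.
#'
#' @param scenario a validated `case_scenario`.
#' @param tables profile table set; defaults to [default_profile_tables()].
#' @param constants from [model_constants()].
#' @param registry an [insulin_registry()].
#' @param dt_min Euler step in minutes (default 15; finer steps interpolate
#'   the driver series linearly and return results resampled to the 15-min
#'   grid).
#' @return An object of class `simulation_result`: list with `time_min`
#'   (97 points), `bg` (mmol/L), `plasma_insulin` and `active_insulin`
#'   (mU/L), the four flux series `gut_absorption`, `renal_excretion`,
#'   `peripheral_uptake`, `nhgb` (mmol/h), `mean_bg` (mmol/L), `hba1c`
#'   (percent), `iterations`, and the `scenario`.
#' @export
#' @examples
#' \donttest{
#' run <- simulate_day(random_scenario(1))
#' run$hba1c
#' }
simulate_day <- function(scenario, tables = default_profile_tables(),
                         constants = model_constants(),
                         registry = insulin_registry(), dt_min = 15) {
  violations <- validate_scenario(scenario, registry)
  if (length(violations)) {
    stop("invalid scenario: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  params <- patient_parameters(scenario)
  injections <- scenario_injections(scenario)
  ins <- insulin_day_profiles(injections, tables, params$weight, constants,
                              registry)
  gut <- carb_day_profile(scenario$meals, tables)

  if (dt_min != 15) {
    stopifnot(dt_min >= 1, 15 %% dt_min == 0)
    fine_t <- seq(0, 1440, by = dt_min)
    grid_t <- seq(0, 1440, by = 15)
    gut_d <- stats::approx(grid_t, gut, xout = fine_t)$y
    ia_d <- stats::approx(grid_t, ins$active, xout = fine_t)$y
  } else {
    gut_d <- gut
    ia_d <- ins$active
  }
  n <- length(gut_d)
  dt_h <- dt_min / 60
  denom <- constants$Vg * params$weight

  # Drivers are sampled as interval averages (trapezoidal sampling of the
  # forcing); the G-dependent fluxes stay explicit at the interval start.
  gut_avg <- (gut_d[-n] + gut_d[-1]) / 2
  ia_avg <- (ia_d[-n] + ia_d[-1]) / 2

  G <- rep(7.0, n)  # initial guess, iterated to the periodic fixed point
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    G_new <- numeric(n)
    G_new[1] <- if (iterations == 1L) 7.0 else G[n]
    for (i in seq_len(n - 1)) {
      net <- gut_avg[i] +
        net_hepatic_balance(G_new[i], ia_avg[i], params, constants) -
        peripheral_utilization_rate(G_new[i], ia_avg[i], params, constants) -
        renal_excretion_rate(G_new[i], params)
      if (!is.finite(net)) {
        stop("non-finite flux during simulation at step ", i, call. = FALSE)
      }
      G_new[i + 1] <- max(constants$bg_floor, G_new[i] + dt_h * net / denom)
    }
    delta <- max(abs(G_new - G))
    G <- G_new
    if (delta < constants$ss_tol) break
    if (iterations >= constants$ss_max_iter) {
      stop("no periodic steady state within ", constants$ss_max_iter,
           " day iterations (residual ", signif(delta, 3), " mmol/L)",
           call. = FALSE)
    }
  }

  if (dt_min != 15) {
    keep <- match(seq(0, 1440, by = 15), seq(0, 1440, by = dt_min))
    G <- G[keep]
    ia_d <- ia_d[keep]
    gut_d <- gut_d[keep]
  }

  nhgb <- net_hepatic_balance(G, ia_d, params, constants)
  peri <- peripheral_utilization_rate(G, ia_d, params, constants)
  renal <- renal_excretion_rate(G, params)
  mbg <- mean_bg(G)
  structure(list(
    time_min = seq(0, 1440, by = 15),
    bg = G,
    plasma_insulin = ins$plasma,
    active_insulin = ins$active,
    gut_absorption = gut_d,
    renal_excretion = renal,
    peripheral_uptake = peri,
    nhgb = nhgb,
    mean_bg = mbg,
    hba1c = hba1c_estimate(mbg * 18, model = constants$hba1c_model),
    iterations = iterations,
    dt_min = dt_min,
    scenario = scenario,
    params = params
  ), class = "simulation_result")
}

# Flatten a scenario's insulin slots into one injection data frame.
scenario_injections <- function(scenario) {
  rows <- lapply(scenario$insulins, function(slot) {
    if (!nrow(slot$injections)) return(NULL)
    data.frame(time_min = slot$injections$time_min,
               dose = slot$injections$dose,
               preparation = slot$preparation)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(time_min = numeric(), dose = numeric(),
                      preparation = character()))
  }
  do.call(rbind, rows)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result> %s (%s)\n", x$scenario$name, x$scenario$id))
  cat(sprintf("  mean BG  %.2f mmol/L (%.0f mg/dL)\n", x$mean_bg,
              x$mean_bg * 18))
  cat(sprintf("  BG range %.2f-%.2f mmol/L\n", min(x$bg), max(x$bg)))
  cat(sprintf("  HbA1c    %.1f %%\n", x$hba1c))
  cat(sprintf("  steady state in %d day iteration(s)\n", x$iterations))
  invisible(x)
}

#' Time-weighted mean of a periodic daily series
#'
#' Under 24-h periodicity the trapezoidal mean with wraparound equals the
#' arithmetic mean of the 96 interval start points.
#'
#' @param series 97-point series on the 15-min grid (or any periodic series
#'   whose last point repeats the first).
#' @return The periodic mean.
#' @export
mean_bg <- function(series) {
  n <- length(series)
  stopifnot(n >= 2)
  mean(series[-n])
}

#' Estimate HbA1c from 24-h mean blood glucose
#'
#' The default linear regression is `HbA1c = (mean_bg_mgdl + 86) / 33.3`
#' percent. The alternative `"eag"` model inverts the estimated-average-
#' glucose regression `mean_bg_mgdl = 28.7 * HbA1c - 46.7`.
#'
#' @param mean_bg_mgdl mean blood glucose in mg/dL (> 0); multiply a
#'   mmol/L mean by 18.
#' @param model `"linear"` (default) or `"eag"`.
#' @return Estimated HbA1c, percent; strictly increasing in its input.
#' @export
#' @examples
#' hba1c_estimate(200)    # about 8.6
#' hba1c_estimate(113.8)  # about 6.0
hba1c_estimate <- function(mean_bg_mgdl, model = c("linear", "eag")) {
  model <- match.arg(model)
  if (any(!is.finite(mean_bg_mgdl)) || any(mean_bg_mgdl <= 0)) {
    stop("mean_bg_mgdl must be positive", call. = FALSE)
  }
  switch(model,
         linear = (mean_bg_mgdl + 86) / 33.3,
         eag = (mean_bg_mgdl + 46.7) / 28.7)
}
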