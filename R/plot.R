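# Rendering of the standard (2-panel) and advanced (6-panel) displays to
# PNG. Previous run solid blue, current run red, bars beneath the curves.

#' Render a simulation run (with optional comparison overlay) to PNG
#'
#' The standard display stacks two panels: blood glucose with carbohydrate
#' intake bars (and optional normoglycaemic bounds lines), and plasma
#' insulin with injection bars. The advanced display appends the four
#' glucose flux panels (gut absorption, renal excretion, peripheral
#' utilization, net hepatic glucose balance). The current run is drawn in
#' red over the previous run in blue, matching the two-run comparison
#' convention; colors are configurable. Axes span exactly 0-24 h.
#'
#' @param payload a [comparison_payload()], or a single `simulation_run`.
#' @param options a [simulator_options()]; defaults to the current run's.
#' @param out_path output PNG path.
#' @param width,height image size in pixels (height is per standard
#'   display; the advanced display scales it by 3).
#' @param col_current,col_previous line colors.
#' @return `out_path`, invisibly.
#' @export
render <- function(payload, options = NULL, out_path,
                   width = 900, height = 600,
                   col_current = "red", col_previous = "blue") {
  if (inherits(payload, "simulation_run")) {
    payload <- list(current = payload, previous = NULL,
                    bounds = if (isTRUE(payload$options$show_bounds))
                      payload$options$bounds)
  }
  current <- payload$current
  previous <- payload$previous
  if (is.null(options)) options <- current$options
  advanced <- identical(options$display, "advanced")
  n_panels <- if (advanced) 6L else 2L
  ok <- tryCatch({
    grDevices::png(out_path, width = width,
                   height = if (advanced) height * 3 else height)
    TRUE
  }, error = function(e) FALSE)
  if (!ok || !file.exists(dirname(out_path))) {
    stop("cannot write plot to ", out_path, call. = FALSE)
  }
  on.exit(grDevices::dev.off())
  old <- graphics::par(mfrow = c(n_panels, 1), mar = c(4, 4.5, 2.5, 1))
  on.exit(graphics::par(old), add = TRUE, after = FALSE)

  time_h <- current$time_min / 60
  uf <- options$units_factor
  unit_lab <- if (uf == 18) "mg/dL" else "mmol/L"

  # Panel 1: blood glucose + carbohydrate bars (+ bounds)
  bg_cur <- current$bg * uf
  bg_prev <- if (!is.null(previous)) previous$bg * uf
  ylim <- range(0, bg_cur, bg_prev,
                if (!is.null(payload$bounds)) payload$bounds * uf)
  graphics::plot(time_h, bg_cur, type = "n", xlim = c(0, 24), ylim = ylim,
                 xlab = "Time (h)", ylab = paste0("Blood glucose (", unit_lab, ")"),
                 main = sprintf("Blood glucose  |  HbA1c %.1f%%", current$hba1c),
                 xaxs = "i")
  meals <- current$scenario$meals
  if (nrow(meals)) {
    bar_h <- diff(ylim) * meals$grams / 80 * 0.25
    graphics::rect(meals$time_min / 60 - 0.2, ylim[1],
                   meals$time_min / 60 + 0.2, ylim[1] + bar_h,
                   col = "grey70", border = NA)
  }
  if (!is.null(payload$bounds)) {
    graphics::abline(h = payload$bounds * uf, lty = 3)
  }
  if (!is.null(bg_prev)) {
    graphics::lines(time_h, bg_prev, col = col_previous, lwd = 2)
  }
  graphics::lines(time_h, bg_cur, col = col_current, lwd = 2)

  # Panel 2: plasma insulin + injection bars
  ins_cur <- current$plasma_insulin
  ins_prev <- if (!is.null(previous)) previous$plasma_insulin
  ylim2 <- range(0, ins_cur, ins_prev)
  graphics::plot(time_h, ins_cur, type = "n", xlim = c(0, 24), ylim = ylim2,
                 xlab = "Time (h)", ylab = "Plasma insulin (mU/L)",
                 main = "Plasma insulin", xaxs = "i")
  inj <- scenario_injections(current$scenario)
  if (nrow(inj)) {
    bar_h <- diff(ylim2) * inj$dose / 40 * 0.25
    graphics::rect(inj$time_min / 60 - 0.15, 0,
                   inj$time_min / 60 + 0.15, bar_h,
                   col = "grey40", border = NA)
  }
  if (!is.null(ins_prev)) {
    graphics::lines(time_h, ins_prev, col = col_previous, lwd = 2)
  }
  graphics::lines(time_h, ins_cur, col = col_current, lwd = 2)

  if (advanced) {
    flux_panels <- list(
      c("gut_absorption", "Glucose absorption rate"),
      c("renal_excretion", "Renal excretion"),
      c("peripheral_uptake", "Peripheral glucose utilization"),
      c("nhgb", "Net hepatic glucose balance"))
    for (fp in flux_panels) {
      cur <- current[[fp[1]]]
      prev <- if (!is.null(previous)) previous[[fp[1]]]
      ylim_f <- range(0, cur, prev)
      graphics::plot(time_h, cur, type = "n", xlim = c(0, 24), ylim = ylim_f,
                     xlab = "Time (h)", ylab = "mmol/h", main = fp[2],
                     xaxs = "i")
      if (fp[1] == "nhgb") graphics::abline(h = 0, lty = 3)
      if (!is.null(prev)) graphics::lines(time_h, prev, col = col_previous,
                                          lwd = 2)
      graphics::lines(time_h, cur, col = col_current, lwd = 2)
    }
  }
  invisible(out_path)
}
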