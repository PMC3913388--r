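# Configuration loading: one editable file can override any model
# constant, absorption-class parameter or the HbA1c regression choice.

#' Load simulator configuration
#'
#' Reads a YAML `key: value` config file and merges it over the built-in
#' defaults. Recognised top-level sections:
#' \describe{
#'   \item{constants}{named overrides for [model_constants()], including a
#'     replacement `nhgb` grid (`ins_nodes`, `g_nodes`, `values` as a list
#'     of rows), whose monotonicity is machine-checked at load}
#'   \item{absorption_classes}{per-class overrides of `s`, `a`, `b`}
#'   \item{registry}{path to an alternative preparation registry TSV}
#'   \item{hba1c_model}{`"linear"` or `"eag"` (shorthand for
#'     `constants$hba1c_model`)}
#' }
#' Every merged value is validated against its type invariants; an invalid
#' constant (e.g. a negative volume, or a non-monotone NHGB grid) is
#' rejected with an error naming the key.
#'
#' @param path config file path, or `NULL` for the documented defaults.
#' @return List with `constants` (a `model_constants` object),
#'   `class_params` (named list of four), and `registry`
#'   (an `insulin_registry`).
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$constants$Km
load_config <- function(path = NULL) {
  constants_over <- list()
  class_params <- absorption_class_params()
  registry_path <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (!is.null(cfg$constants)) {
      constants_over <- cfg$constants
      if (!is.null(constants_over$nhgb)) {
        g <- constants_over$nhgb
        g$values <- do.call(rbind, lapply(g$values, as.numeric))
        constants_over$nhgb <- g
      }
    }
    if (!is.null(cfg$hba1c_model)) {
      constants_over$hba1c_model <- cfg$hba1c_model
    }
    for (cls in names(cfg$absorption_classes)) {
      if (!cls %in% names(class_params)) {
        stop("config error: unknown absorption class '", cls, "'",
             call. = FALSE)
      }
      over <- cfg$absorption_classes[[cls]]
      bad <- setdiff(names(over), c("s", "a", "b"))
      if (length(bad)) {
        stop("config error: unknown absorption parameter '", bad[1],
             "' for class ", cls, call. = FALSE)
      }
      class_params[[cls]][names(over)] <- over
      validate_class_params(class_params[[cls]])
    }
    registry_path <- cfg$registry
  }
  constants <- do.call(model_constants, constants_over)
  list(constants = constants,
       class_params = class_params,
       registry = insulin_registry(registry_path))
}
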