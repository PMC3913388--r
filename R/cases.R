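# The packaged database of 40 virtual patients.
#
# The scenarios are reconstructions: the historical database is described
# only narratively, so cases 0001, 0010 and 0026 follow the documented
# details (names, the twice-daily 30/70 premix of 0026, the Actrapid +
# Ultratard regimen of 0010) and the remaining cases are authored afresh in
# the same style.

#' Load the 40 built-in case scenarios
#'
#' @param registry an [insulin_registry()] used for validation.
#' @return Named list of 40 validated `case_scenario` objects, ids
#'   `"0001"` to `"0040"`.
#' @export
#' @examples
#' cases <- builtin_cases()
#' length(cases)
#' cases[["0001"]]$name
builtin_cases <- function(registry = insulin_registry()) {
  dir <- system.file("extdata", "cases", package = "glucosim")
  files <- list.files(dir, pattern = "\\.aida$", full.names = TRUE)
  if (!length(files)) stop("packaged case directory not found", call. = FALSE)
  cases <- lapply(files, function(f) {
    tryCatch(parse_scenario(f, registry),
             error = function(e) {
               stop("corrupt packaged case file ", basename(f), ": ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  names(cases) <- vapply(cases, `[[`, "", "id")
  cases[order(names(cases))]
}

#' Fetch one built-in case scenario by id
#'
#' @param id 4-digit id string (e.g. `"0001"`) or an integer.
#' @inheritParams builtin_cases
#' @return A `case_scenario`.
#' @export
builtin_case <- function(id, registry = insulin_registry()) {
  if (is.numeric(id)) id <- sprintf("%04d", id)
  cases <- builtin_cases(registry)
  if (!id %in% names(cases)) {
    stop("unknown case id '", id, "' (known: 0001-",
         names(cases)[length(cases)], ")", call. = FALSE)
  }
  cases[[id]]
}
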