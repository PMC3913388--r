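# Insulin preparation registry: brand names -> absorption classes or
# biphasic percent splits.

.absorption_classes <- c("ACTRAPID_LIKE", "NPH_LIKE", "LENTE_LIKE",
                         "ULTRALENTE_LIKE")

#' Load the insulin preparation registry
#'
#' The registry maps insulin brand names to an absorption-speed class
#' (short = Actrapid-like, intermediate = NPH- or Lente-like,
#' long = UltraLente-like), or, for biphasic premixes, to a percent split
#' between a short-acting and an intermediate-acting component. The packaged
#' registry ships 10 short, 19 intermediate, 4 long and 18 biphasic brands;
#' it is an editable tab-separated text file, so brands can be re-mapped or
#' added without touching code.
#'
#' @param path path to a registry TSV; defaults to the packaged file.
#' @return An object of class `insulin_registry`: a data frame with columns
#'   `name`, `category`, `class`, `percent_short`, `intermediate_class`.
#' @seealso [resolve_preparation()], [biphasic_split()]
#' @export
#' @examples
#' reg <- insulin_registry()
#' table(reg$category)
insulin_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "insulin_registry.tsv", package = "glucosim")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("insulin registry file not found: ", path, call. = FALSE)
  }
  reg <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = "", quote = "")
  needed <- c("name", "category", "class", "percent_short", "intermediate_class")
  if (!all(needed %in% names(reg))) {
    stop("malformed registry: need columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  validate_registry(reg)
  structure(reg, class = c("insulin_registry", "data.frame"))
}

validate_registry <- function(reg) {
  if (anyDuplicated(reg$name)) {
    stop("malformed registry: duplicated brand name(s): ",
         paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad_cat <- setdiff(unique(reg$category),
                     c("short", "intermediate", "long", "biphasic"))
  if (length(bad_cat)) {
    stop("malformed registry: unknown category: ",
         paste(bad_cat, collapse = ", "), call. = FALSE)
  }
  bi <- reg$category == "biphasic"
  # exactly one of class / (percent_short + intermediate_class) per entry
  if (any(!bi & (is.na(reg$class) | !is.na(reg$percent_short)))) {
    stop("malformed registry: non-biphasic entries must set class only",
         call. = FALSE)
  }
  if (any(bi & (!is.na(reg$class) | is.na(reg$percent_short) |
                  is.na(reg$intermediate_class)))) {
    stop("malformed registry: biphasic entries must set percent_short ",
         "and intermediate_class only", call. = FALSE)
  }
  if (!all(reg$class[!bi] %in% .absorption_classes)) {
    stop("malformed registry: unknown absorption class", call. = FALSE)
  }
  if (any(reg$percent_short[bi] < 1 | reg$percent_short[bi] > 99)) {
    stop("malformed registry: percent_short must be in 1-99", call. = FALSE)
  }
  if (!all(reg$intermediate_class[bi] %in% c("NPH_LIKE", "LENTE_LIKE"))) {
    stop("malformed registry: intermediate_class must be NPH_LIKE or LENTE_LIKE",
         call. = FALSE)
  }
  invisible(reg)
}

#' Resolve an insulin brand name to its registry entry
#'
#' @param name brand name, matched exactly (case-insensitively).
#' @param registry an [insulin_registry()]; defaults to the packaged one.
#' @return A one-row list: `name`, `category`, and either `class` or
#'   (`percent_short`, `intermediate_class`).
#' @export
#' @examples
#' resolve_preparation("Actrapid")$class
#' resolve_preparation("Mixtard 30/70")$percent_short
resolve_preparation <- function(name, registry = insulin_registry()) {
  hit <- which(tolower(registry$name) == tolower(trimws(name)))
  if (length(hit) != 1L) {
    stop("unknown insulin preparation: '", name, "'", call. = FALSE)
  }
  as.list(registry[hit, , drop = FALSE])
}

#' Split a biphasic (premixed) insulin dose into its two components
#'
#' Biphasic preparations such as Mixtard 30/70 contain a fixed percentage of
#' short-acting insulin premixed with an intermediate-acting component; the
#' engine simulates one premixed injection as two separate injections at the
#' same time.
#'
#' @param dose injected dose, IU (>= 0).
#' @param prep a biphasic registry entry from [resolve_preparation()], or a
#'   brand name resolved against the packaged registry.
#' @return Named numeric vector `c(short = ..., intermediate = ...)`, IU,
#'   summing to `dose`.
#' @export
#' @examples
#' biphasic_split(10, "Mixtard 30/70")  # 3 IU short + 7 IU intermediate
#' biphasic_split(10, "Humulin 50/50")  # 5 + 5
biphasic_split <- function(dose, prep) {
  if (is.character(prep)) prep <- resolve_preparation(prep)
  if (!identical(prep$category, "biphasic")) {
    stop("biphasic_split() requires a biphasic preparation, got '",
         prep$name, "' (", prep$category, ")", call. = FALSE)
  }
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0) {
    stop("dose must be a single non-negative number", call. = FALSE)
  }
  short <- dose * prep$percent_short / 100
  c(short = short, intermediate = dose - short)
}
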