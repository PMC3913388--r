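# Reading and writing the nine ASCII profile storage files.

#' Names of the nine profile storage files
#'
#' @return Character vector of the nine member names, in canonical order.
#' @export
profile_file_names <- function() {
  c("Actrapid_act", "Actrapid_pa", "NPH_act", "NPH_pa",
    "Lente_act", "Lente_pa", "UltraLente_act", "UltraLente_pa", "CAR")
}

# file stem -> absorption class
.stem_class <- c(Actrapid = "ACTRAPID_LIKE", NPH = "NPH_LIKE",
                 Lente = "LENTE_LIKE", UltraLente = "ULTRALENTE_LIKE")

#' Write a profile table set to its nine ASCII files
#'
#' Each file holds a `#`-prefixed header line (kind, class, units, grid
#' spec) followed by one whitespace-separated row of 97 values per dose or
#' gram offset. Values are written with 15 significant digits so that a
#' write/read round trip reproduces the tables to better than 1e-9.
#'
#' @param tables named list of nine [absorption_table()]s, as produced by
#'   [build_profile_tables()].
#' @param directory output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_profile_files <- function(tables, directory) {
  wanted <- profile_file_names()
  missing <- setdiff(wanted, names(tables))
  if (length(missing)) {
    stop("incomplete table set: missing ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(tables), wanted)
  if (length(extra)) {
    stop("unexpected table(s): ", paste(extra, collapse = ", "), call. = FALSE)
  }
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  for (nm in wanted) {
    tab <- tables[[nm]]
    stopifnot(inherits(tab, "absorption_table"))
    units <- if (tab$kind == "carbohydrate") "mmol_per_h" else "IU"
    header <- sprintf("# kind=%s class=%s units=%s grid=0:1440:15 rows=%d",
                      tab$kind, if (is.null(tab$class_id)) "NA" else tab$class_id,
                      units, nrow(tab$values))
    body <- apply(tab$values, 1, function(r) {
      paste(formatC(r, digits = 15, format = "g"), collapse = " ")
    })
    writeLines(c(header, body), file.path(directory, nm))
  }
  invisible(directory)
}

#' Read a profile table set back from its nine ASCII files
#'
#' @param directory directory containing exactly the nine files named by
#'   [profile_file_names()].
#' @return Named list of nine [absorption_table()]s.
#' @export
read_profile_files <- function(directory) {
  if (!dir.exists(directory)) {
    stop("profile directory not found: ", directory, call. = FALSE)
  }
  wanted <- profile_file_names()
  present <- list.files(directory)
  missing <- setdiff(wanted, present)
  if (length(missing)) {
    stop("profile file set is missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(present, wanted)
  if (length(extra)) {
    stop("unexpected file(s) in profile directory: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (nm in wanted) {
    path <- file.path(directory, nm)
    lines <- readLines(path)
    if (!length(lines) || !startsWith(lines[1], "#")) {
      stop("malformed profile file ", nm, ": missing header line", call. = FALSE)
    }
    header <- parse_profile_header(lines[1], nm)
    body <- lines[-1]
    if (length(body) != header$rows) {
      stop("malformed profile file ", nm, ": expected ", header$rows,
           " data rows, found ", length(body), call. = FALSE)
    }
    values <- matrix(0, nrow = header$rows, ncol = 97)
    for (i in seq_along(body)) {
      row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
      if (length(row) != 97 || any(is.na(row))) {
        stop("malformed profile file ", nm, ": bad row at line ", i + 1,
             " (", length(row), " values, 97 expected)", call. = FALSE)
      }
      values[i, ] <- row
    }
    class_id <- if (header$kind == "carbohydrate") NULL else header$class
    out[[nm]] <- absorption_table(header$kind, values, class_id)
  }
  out
}

parse_profile_header <- function(line, file) {
  fields <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
  kv <- strsplit(fields, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  need <- c("kind", "class", "units", "grid", "rows")
  if (!all(need %in% keys)) {
    stop("malformed profile file ", file, ": incomplete header", call. = FALSE)
  }
  h <- as.list(stats::setNames(vals, keys))
  h$rows <- as.integer(h$rows)
  if (!identical(h$grid, "0:1440:15")) {
    stop("malformed profile file ", file, ": unsupported grid ", h$grid,
         call. = FALSE)
  }
  h
}
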