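# CSV input/output for series, realized assignments, and enumerated
# assignment sets, plus the flat key:value config dialect used by the
# command-line interface.

#' Read a measurement-series CSV
#'
#' Expects a header `unit,occasion,value` with occasions 1-based and
#' contiguous within each unit; any gap, duplicate, missing value, or
#' non-numeric value is an error naming the offending unit/occasion.
#'
#' @param path Path to the CSV file.
#' @return A validated series tibble.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("unit", "occasion", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_invalid("series CSV ", path, " is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  if (!is.numeric(raw$value)) {
    abort_invalid("series CSV ", path, " has non-numeric values")
  }
  validate_series(tibble::as_tibble(raw[required]))
}

#' Write a measurement-series CSV
#'
#' @param data A series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(data, path) {
  data <- validate_series(data)
  utils::write.csv(data[, c("unit", "occasion", "value")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a realized-assignment CSV
#'
#' Format: header `unit,occasion,label`, one row per occasion per unit.
#'
#' @param path Path to the CSV file.
#' @return A named list of per-unit label vectors, in occasion order.
#' @export
read_assignment_csv <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("unit", "occasion", "label")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort_invalid("assignment CSV is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  lapply(split(raw, raw$unit), function(d) {
    d$label[order(d$occasion)]
  })
}

#' Write an enumerated or sampled assignment set to CSV
#'
#' One row per assignment: `assignment_id` plus `labels` (collapsed label
#' string) for label families or `assignment` (semicolon-joined integers)
#' for start-point and change-point families.
#'
#' @param set A tibble from [enumerate_assignments()] or
#'   [sample_assignments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assignments_csv <- function(set, path) {
  out <- if ("labels" %in% names(set)) {
    tibble::tibble(assignment_id = set$assignment_id, labels = set$labels)
  } else {
    vec_col <- intersect(c("start_points", "change_points"), names(set))[1]
    tibble::tibble(
      assignment_id = set$assignment_id,
      assignment = vapply(set[[vec_col]], paste, "", collapse = ";")
    )
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a flat key:value config file
#'
#' One `key: value` (or `key = value`) pair per line; blank lines and lines
#' starting with `#` are ignored. Values stay as strings; consumers parse
#' them.
#'
#' @param path Path to the config file.
#' @return A named list of character values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort_invalid("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  for (line in lines) {
    m <- regmatches(line, regexec("^([^:=]+)[:=](.*)$", line))[[1]]
    if (length(m) != 3) abort_invalid("config line not key: value — ", line)
    out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}
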