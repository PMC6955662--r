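# Measurement series: the tidy container every analysis function consumes.
#
# A series set is an ordinary tibble with columns `unit`, `occasion`, `value`;
# single-case data are simply the one-unit special case. Occasions are
# 1-based and contiguous within each unit, and missing values are a hard
# error: a gap in the record would silently change the reference
# distribution of any randomization test computed from it.

#' Construct a measurement series
#'
#' Builds the tidy per-occasion measurement table used throughout the
#' package: one row per measurement occasion, optionally for several units
#' (multiple baseline designs). Occasions are numbered 1..n within each unit.
#'
#' @param values Numeric vector of measurements for a single unit, or a
#'   named list of numeric vectors (one per unit).
#' @param unit Unit identifier used when `values` is a single vector.
#' @return A tibble with columns `unit` (character), `occasion` (integer),
#'   and `value` (double).
#' @examples
#' sced_series(c(4, 5, 6, 9, 10, 11))
#' sced_series(list(p1 = rnorm(10), p2 = rnorm(10)))
#' @export
sced_series <- function(values, unit = "unit1") {
  if (is.numeric(values)) {
    values <- stats::setNames(list(values), unit)
  }
  if (!is.list(values) || length(values) == 0) {
    abort_invalid("`values` must be a numeric vector or a list of numeric vectors")
  }
  if (is.null(names(values)) || anyNA(names(values)) || any(names(values) == "")) {
    names(values) <- paste0("unit", seq_along(values))
  }
  out <- purrr::imap_dfr(values, function(v, id) {
    tibble::tibble(unit = id, occasion = seq_along(v), value = as.double(v))
  })
  validate_series(out)
}

#' Validate a measurement series table
#'
#' Checks the series-set contract: columns `unit`, `occasion`, `value`;
#' occasions contiguous from 1 within each unit; no duplicated
#' (unit, occasion) pairs; no missing or non-finite values.
#'
#' @param data A data frame of measurements.
#' @return The validated data, as a tibble, invisibly usable in pipes.
#' @export
validate_series <- function(data) {
  required <- c("unit", "occasion", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort_invalid("series data is missing column(s): ",
                  paste(missing_cols, collapse = ", "))
  }
  data <- tibble::as_tibble(data)
  if (nrow(data) == 0) abort_invalid("series data has no rows")
  if (!is.numeric(data$value) || anyNA(data$value) || any(!is.finite(data$value))) {
    abort_invalid("series values must be numeric with no missing values")
  }
  if (anyNA(data$occasion)) abort_invalid("series occasions contain missing values")
  split_occ <- split(data$occasion, data$unit)
  for (u in names(split_occ)) {
    occ <- sort(as.integer(split_occ[[u]]))
    if (anyDuplicated(occ)) {
      abort_invalid("duplicated occasion for unit '", u, "'")
    }
    if (!identical(occ, seq_len(length(occ)))) {
      gap <- setdiff(seq_len(max(occ)), occ)[1]
      abort_invalid("unit '", u, "' has non-contiguous occasions (missing occasion ",
                    gap, ")")
    }
  }
  dplyr::arrange(data, .data$unit, .data$occasion)
}

# values of a single-unit series, in occasion order
series_values <- function(data, unit = NULL) {
  data <- validate_series(data)
  units <- unique(data$unit)
  if (is.null(unit)) {
    if (length(units) > 1) {
      abort_invalid("data contains ", length(units),
                    " units; supply `unit` to pick one")
    }
    unit <- units[1]
  }
  d <- data[data$unit == unit, ]
  if (nrow(d) == 0) abort_invalid("no rows for unit '", unit, "'")
  d$value[order(d$occasion)]
}

# list of per-unit value vectors, in unit order of first appearance
series_value_list <- function(data) {
  data <- validate_series(data)
  units <- unique(data$unit)
  stats::setNames(lapply(units, function(u) series_values(data, u)), units)
}
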