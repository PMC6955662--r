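# Level-based test statistics for randomized single-case designs.
#
# Phase designs compare means WITHIN maximal runs (phases) and sum them per
# role; alternation designs pool all occasions of a condition before taking
# the mean; multiple baseline designs average per-unit mean differences;
# changing criterion designs score adherence as the mean absolute deviation
# from the phase criteria. All statistics are computed in full floating
# precision; rounding to two decimals is a display concern only.

#' Statistic specification
#'
#' Names one of the built-in test statistics and declares which condition
#' labels play the baseline (A) and treatment (B) roles, so that patterns
#' like ABACA work without hardcoding two conditions.
#'
#' @param name One of `"phase_mean_diff_BA"`, `"phase_mean_diff_AB"`,
#'   `"phase_mean_diff_abs"`, `"alternation_mean_diff_AB"`,
#'   `"mbd_mean_diff"`, `"ccd_mad"`.
#' @param a_labels,b_labels Disjoint, non-empty character vectors of labels
#'   in the baseline and treatment roles (ignored by `mbd_mean_diff`, where
#'   phases are defined by start points, and by `ccd_mad`).
#' @return An object of class `sced_statistic`.
#' @examples
#' sced_statistic("phase_mean_diff_BA")
#' @export
sced_statistic <- function(name = c("phase_mean_diff_BA", "phase_mean_diff_AB",
                                    "phase_mean_diff_abs",
                                    "alternation_mean_diff_AB",
                                    "mbd_mean_diff", "ccd_mad"),
                           a_labels = "A", b_labels = "B") {
  name <- match.arg(name)
  a_labels <- as.character(a_labels)
  b_labels <- as.character(b_labels)
  if (length(a_labels) == 0 || length(b_labels) == 0) {
    abort_invalid("a_labels and b_labels must be non-empty")
  }
  if (length(intersect(a_labels, b_labels)) > 0) {
    abort_invalid("a_labels and b_labels must be disjoint")
  }
  structure(list(name = name, a_labels = a_labels, b_labels = b_labels),
            class = "sced_statistic")
}

#' @export
print.sced_statistic <- function(x, ...) {
  cat("<sced_statistic> ", x$name, "  (A role: ",
      paste(x$a_labels, collapse = ","), "; B role: ",
      paste(x$b_labels, collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' Per-phase means of a series
#'
#' Splits a single-unit series into its maximal runs of identical condition
#' labels (the phases) and returns one mean per phase, in temporal order.
#'
#' @param data A single-unit series tibble (`unit`, `occasion`, `value`).
#' @param labels Per-occasion condition labels (vector, or collapsed string
#'   of single-character labels), length equal to the number of occasions.
#' @return A tibble with columns `phase`, `label`, `n`, `mean`.
#' @examples
#' phase_means(sced_series(1:6), c("A", "A", "A", "B", "B", "B"))
#' @export
phase_means <- function(data, labels) {
  values <- series_values(data)
  labels <- string_to_labels(labels)
  if (length(labels) != length(values)) {
    abort_invalid("labels length (", length(labels),
                  ") does not match number of occasions (", length(values), ")")
  }
  runs <- label_runs(labels)
  ends <- cumsum(runs$length)
  starts <- ends - runs$length + 1L
  runs$n <- runs$length
  runs$mean <- vapply(seq_len(nrow(runs)), function(i) {
    mean(values[starts[i]:ends[i]])
  }, 1.0)
  runs[, c("phase", "label", "n", "mean")]
}

#' Phase-mean-difference statistic
#'
#' The sum of the treatment-role phase means minus the sum of the
#' baseline-role phase means (direction `"BA"`), the negative of that
#' (`"AB"`, for an expected decrease), or its absolute value (`"abs"`, the
#' two-sided statistic).
#'
#' @inheritParams phase_means
#' @param direction `"BA"`, `"AB"`, or `"abs"`.
#' @param a_labels,b_labels Labels in the baseline and treatment roles.
#' @return The statistic value (double scalar).
#' @examples
#' phase_mean_diff(sced_series(c(0, 0, 0, 1, 1, 1)), "AAABBB", "BA") # 1
#' @export
phase_mean_diff <- function(data, labels, direction = c("BA", "AB", "abs"),
                            a_labels = "A", b_labels = "B") {
  direction <- match.arg(direction)
  pm <- phase_means(data, labels)
  in_a <- pm$label %in% a_labels
  in_b <- pm$label %in% b_labels
  if (!any(in_a)) abort_invalid("no phase carries a baseline-role label")
  if (!any(in_b)) abort_invalid("no phase carries a treatment-role label")
  ba <- sum(pm$mean[in_b]) - sum(pm$mean[in_a])
  switch(direction, BA = ba, AB = -ba, abs = abs(ba))
}

#' Pooled condition-mean difference for alternation designs
#'
#' Mean of all baseline-role occasions minus mean of all treatment-role
#' occasions, pooled across occasions rather than per run (so A - B, the
#' form used when a higher baseline mean counts as evidence against the
#' treatment raising the outcome).
#'
#' @inheritParams phase_mean_diff
#' @return The statistic value (double scalar).
#' @examples
#' alternation_mean_diff(sced_series(1:6), c("A", "A", "A", "B", "B", "B")) # -3
#' @export
alternation_mean_diff <- function(data, labels, a_labels = "A", b_labels = "B") {
  values <- series_values(data)
  labels <- string_to_labels(labels)
  if (length(labels) != length(values)) {
    abort_invalid("labels length does not match number of occasions")
  }
  in_a <- labels %in% a_labels
  in_b <- labels %in% b_labels
  if (!any(in_a)) abort_invalid("no occasion carries a baseline-role label")
  if (!any(in_b)) abort_invalid("no occasion carries a treatment-role label")
  mean(values[in_a]) - mean(values[in_b])
}

#' Mean across units of per-unit intervention effects (multiple baseline)
#'
#' For each unit, the mean of the intervention occasions (at or after the
#' unit's start point) minus the mean of the baseline occasions (before
#' it); the statistic is the average of these per-unit differences.
#'
#' @param data A multi-unit series tibble (`unit`, `occasion`, `value`).
#' @param start_points Integer vector of per-unit intervention start
#'   occasions, one per unit in the order units first appear in `data`
#'   (or named by unit).
#' @return The statistic value (double scalar).
#' @export
mbd_mean_diff <- function(data, start_points) {
  vals <- series_value_list(data)
  u <- length(vals)
  if (length(start_points) != u) {
    abort_invalid("need one start point per unit (", u, ")")
  }
  if (!is.null(names(start_points))) {
    if (!setequal(names(start_points), names(vals))) {
      abort_invalid("start point names do not match the units")
    }
    start_points <- start_points[names(vals)]
  }
  diffs <- mapply(function(v, s) {
    s <- as.integer(s)
    if (s < 2 || s > length(v)) {
      abort_invalid("start point ", s, " outside 2..n for a unit of length ",
                    length(v))
    }
    mean(v[s:length(v)]) - mean(v[seq_len(s - 1)])
  }, vals, start_points)
  mean(diffs)
}

#' Mean absolute deviation from phase criteria (changing criterion designs)
#'
#' Sums, over every occasion, the absolute distance between the measurement
#' and its phase criterion and divides by the total number of occasions.
#' For range-bound criteria the deviation is zero inside `[lower, upper]`
#' and the distance to the nearer bound outside. A value of zero indicates
#' perfect adherence; smaller is better.
#'
#' @param data A single-unit series tibble.
#' @param change_points Integer vector of per-boundary change points (first
#'   occasion of each phase after the first).
#' @param criteria Data frame with columns `phase_label`, `lower`, `upper`
#'   covering every phase including the baseline, in phase order; obtain it
#'   from a design with [resolve_ccd_criteria()].
#' @return The statistic value (double scalar).
#' @export
ccd_mad <- function(data, change_points, criteria) {
  values <- series_values(data)
  n <- length(values)
  k <- nrow(criteria)
  if (length(change_points) != k - 1) {
    abort_invalid("need one change point per boundary (", k - 1, ")")
  }
  phase_of <- rep(seq_len(k), times = diff(c(1L, as.integer(change_points), n + 1L)))
  if (length(phase_of) != n) abort_invalid("change points incompatible with series length")
  lo <- criteria$lower[phase_of]
  hi <- criteria$upper[phase_of]
  dev <- pmax(lo - values, values - hi, 0)
  mean(dev)
}

#' Resolve the full per-phase criterion table of a changing criterion design
#'
#' Prepends the baseline criterion to the design's treatment-phase criteria.
#' Under the `"median_of_baseline"` rule the baseline criterion is the
#' median of the observed baseline segment — the occasions before the first
#' REALIZED change point — computed once and held fixed across all
#' reference assignments (recomputing it per candidate assignment would
#' change the hypothesis being tested).
#'
#' @param design A `sced_ccd_design`.
#' @param data The observed single-unit series (required for the
#'   median-of-baseline rule).
#' @param observed_change_points The realized change points (required for
#'   the median-of-baseline rule).
#' @return A tibble with columns `phase_label`, `lower`, `upper`, one row
#'   per phase including the baseline.
#' @export
resolve_ccd_criteria <- function(design, data = NULL, observed_change_points = NULL) {
  validate_design(design)
  base_label <- design$phase_labels[1]
  base_crit <- switch(
    design$baseline_criterion,
    fixed = design$baseline_value,
    median_of_baseline = {
      if (is.null(data) || is.null(observed_change_points)) {
        abort_invalid("median_of_baseline needs the observed data and realized change points")
      }
      values <- series_values(data)
      first_cp <- as.integer(observed_change_points)[1]
      stats::median(values[seq_len(first_cp - 1L)])
    },
    none = abort_invalid("baseline criterion rule is \"none\" but baseline occasions are scored")
  )
  dplyr::bind_rows(
    tibble::tibble(phase_label = base_label, lower = base_crit, upper = base_crit),
    design$criteria
  )
}

#' Compute a statistic for a series under one assignment
#'
#' Dispatches a [sced_statistic()] to the matching low-level statistic
#' function, translating the assignment representation of the design family
#' (labels, start points, or change points) as needed.
#'
#' @param data A series tibble (single- or multi-unit as the design requires).
#' @param design A design object.
#' @param statistic A [sced_statistic()] (or its name as a string).
#' @param assignment Labels, start points, or change points, per family.
#' @param criteria Resolved criterion table for `ccd_mad`
#'   (see [resolve_ccd_criteria()]).
#' @return The statistic value (double scalar).
#' @export
compute_statistic <- function(data, design, statistic, assignment,
                              criteria = NULL) {
  if (is.character(statistic)) statistic <- sced_statistic(statistic)
  if (!is_admissible(design, assignment)) {
    abort_invalid("assignment is not admissible under the design")
  }
  assignment_statistic(data, design, statistic, assignment, criteria)
}

# as compute_statistic, without the admissibility re-check (hot path)
assignment_statistic <- function(data, design, statistic, assignment,
                                 criteria = NULL) {
  switch(
    statistic$name,
    phase_mean_diff_BA = phase_mean_diff(data, to_labels(design, assignment), "BA",
                                         statistic$a_labels, statistic$b_labels),
    phase_mean_diff_AB = phase_mean_diff(data, to_labels(design, assignment), "AB",
                                         statistic$a_labels, statistic$b_labels),
    phase_mean_diff_abs = phase_mean_diff(data, to_labels(design, assignment), "abs",
                                          statistic$a_labels, statistic$b_labels),
    alternation_mean_diff_AB = alternation_mean_diff(
      data, to_labels(design, assignment), statistic$a_labels, statistic$b_labels),
    mbd_mean_diff = mbd_mean_diff(data, assignment),
    ccd_mad = {
      if (is.null(criteria)) {
        abort_invalid("ccd_mad needs a resolved criterion table; see resolve_ccd_criteria()")
      }
      ccd_mad(data, assignment, criteria)
    }
  )
}

# assignment -> per-occasion labels for families whose assignments are
# label sequences or phase change points
to_labels <- function(design, assignment) {
  if (design$family == "phase" && is.numeric(assignment)) {
    labels_from_changepoints(assignment, design$n, design$pattern)
  } else {
    string_to_labels(assignment)
  }
}

#' Default statistic of a design family
#'
#' @param design A design object.
#' @return A [sced_statistic()]: phase-mean difference (B minus A) for phase
#'   designs, pooled A-minus-B mean difference for alternation designs, the
#'   across-unit mean difference for multiple baseline designs, and the
#'   mean absolute deviation for changing criterion designs.
#' @export
default_statistic <- function(design) {
  validate_design(design)
  switch(
    design$family,
    phase = sced_statistic("phase_mean_diff_BA"),
    crd = ,
    atd = ,
    rbd = sced_statistic("alternation_mean_diff_AB",
                         a_labels = first_label(design),
                         b_labels = other_labels(design)),
    mbd = sced_statistic("mbd_mean_diff"),
    ccd = sced_statistic("ccd_mad")
  )
}

first_label <- function(design) {
  labs <- if (design$family == "rbd") design$treatments else names(design$counts)
  labs[1]
}

other_labels <- function(design) {
  labs <- if (design$family == "rbd") design$treatments else names(design$counts)
  labs[-1]
}
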