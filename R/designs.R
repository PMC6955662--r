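# Design specifications for the four families of randomized single-case
# experimental designs. Each constructor validates its invariants and
# returns a classed list; all downstream operations (counting, enumeration,
# sampling, testing, power) dispatch on the design class.
#
# Conventions: occasions are 1-based; a change point is the index of the
# FIRST occasion of the new phase; phases are closed intervals. Condition
# labels are arbitrary text, with "A" conventionally the baseline role.

new_design <- function(family, fields) {
  structure(c(list(family = family), fields),
            class = c(paste0("sced_", family, "_design"), "sced_design"))
}

#' Phase design (AB, ABA, ABAB, ...)
#'
#' A phase design takes measurements in consecutive phases that alternate
#' between levels of the independent variable, e.g., the ABAB withdrawal
#' design. The restricted randomization scheme randomizes the moments of
#' phase change subject to a minimum number of measurements per phase
#' (three per phase meets common minimum evidence standards).
#'
#' @param pattern Character vector of condition labels, one per phase, in
#'   temporal order (e.g., `c("A","B","A","B")`). At least two phases with
#'   at least two distinct labels.
#' @param n Total number of measurement occasions.
#' @param min_phase_length Minimum measurements per phase (default 3).
#' @return A design object of class `sced_phase_design`.
#' @examples
#' phase_design(c("A", "B", "A", "B"), n = 24, min_phase_length = 3)
#' @export
phase_design <- function(pattern, n, min_phase_length = 3) {
  pattern <- as.character(pattern)
  k <- length(pattern)
  if (k < 2) abort_invalid("a phase design needs at least 2 phases")
  if (length(unique(pattern)) < 2) {
    abort_invalid("phase pattern must contain at least two distinct labels")
  }
  if (any(pattern[-1] == pattern[-k])) {
    abort_invalid("adjacent phases must carry different labels")
  }
  n <- as.integer(n)
  m <- as.integer(min_phase_length)
  if (m < 1) abort_invalid("min_phase_length must be >= 1")
  if (n < k * m) {
    abort_invalid("n = ", n, " occasions cannot hold ", k, " phases of at least ",
                  m, " measurements each (need >= ", k * m, ")")
  }
  new_design("phase", list(pattern = pattern, n = n, min_phase_length = m))
}

#' Completely randomized alternation design
#'
#' Every measurement occasion is randomly assigned a condition. By default
#' the per-condition totals are fixed in advance (the reference set is the
#' set of label permutations); `unrestricted = TRUE` instead gives each
#' occasion an independent, equal chance of every condition (reference set
#' of size `c^n`).
#'
#' @param n Total occasions.
#' @param counts Named integer vector of per-condition totals, e.g.,
#'   `c(A = 3, B = 3)`. With `unrestricted = TRUE` only the names are used
#'   (the totals are free).
#' @param unrestricted If `TRUE`, use the independent coin-flip scheme.
#' @return A design object of class `sced_crd_design`.
#' @examples
#' crd_design(n = 6, counts = c(A = 3, B = 3))
#' @export
crd_design <- function(n, counts, unrestricted = FALSE) {
  n <- as.integer(n)
  check_counts(counts, n, required_sum = !unrestricted)
  new_design("crd", list(n = n, counts = counts, unrestricted = unrestricted))
}

#' Alternating treatments design
#'
#' Rapid alternation of conditions with fixed per-condition totals and a
#' cap on the number of consecutive occasions under the same condition
#' (recommended caps are two or three consecutive measures).
#'
#' @param n Total occasions.
#' @param counts Named integer vector of per-condition totals summing to `n`.
#' @param max_run Maximum run length of identical consecutive labels,
#'   enforced on maximal runs across the whole sequence; `Inf` disables the
#'   restriction.
#' @return A design object of class `sced_atd_design`.
#' @examples
#' atd_design(n = 6, counts = c(A = 3, B = 3), max_run = 2)
#' @export
atd_design <- function(n, counts, max_run = 2) {
  n <- as.integer(n)
  check_counts(counts, n, required_sum = TRUE)
  if (!(is.infinite(max_run) || (max_run >= 1 && max_run == as.integer(max_run)))) {
    abort_invalid("max_run must be a positive integer or Inf")
  }
  new_design("atd", list(n = n, counts = counts, max_run = max_run))
}

#' Randomized block alternation design
#'
#' Occasions are grouped into consecutive equal-size blocks; within each
#' block every treatment occurs exactly once, in random order (e.g., five
#' 3-day segments with each of three drugs administered once per segment).
#'
#' @param n_blocks Number of blocks.
#' @param treatments Character vector of treatment labels (each occurs once
#'   per block).
#' @return A design object of class `sced_rbd_design`; total occasions are
#'   `n_blocks * length(treatments)`.
#' @examples
#' rbd_design(n_blocks = 5, treatments = c("A", "B", "C"))
#' @export
rbd_design <- function(n_blocks, treatments) {
  n_blocks <- as.integer(n_blocks)
  treatments <- as.character(treatments)
  if (n_blocks < 1) abort_invalid("n_blocks must be >= 1")
  if (length(treatments) < 2 || anyDuplicated(treatments)) {
    abort_invalid("treatments must be >= 2 distinct labels")
  }
  new_design("rbd", list(n_blocks = n_blocks, treatments = treatments,
                         n = n_blocks * length(treatments)))
}

#' Multiple baseline design
#'
#' Replicated AB designs across units (participants, outcomes, or settings)
#' with a staggered introduction of the intervention: each unit's
#' intervention start occasion is drawn from a common window, and by
#' default no two units may start on the same occasion.
#'
#' @param n_units Number of units.
#' @param n Occasions per unit.
#' @param start_window Integer vector `c(earliest, latest)` of admissible
#'   intervention start occasions (the start occasion is the first
#'   intervention occasion, so `earliest >= 2` leaves at least one baseline
#'   occasion and `latest <= n` leaves at least one intervention occasion).
#' @param distinct_starts Require pairwise-distinct start occasions
#'   (default `TRUE`).
#' @param min_stagger Minimum separation between any two start occasions
#'   (1 = distinctness only; larger values enforce wider stagger, which
#'   increases power).
#' @return A design object of class `sced_mbd_design`.
#' @examples
#' mbd_design(n_units = 5, n = 55, start_window = c(15, 36))
#' @export
mbd_design <- function(n_units, n, start_window, distinct_starts = TRUE,
                       min_stagger = 1L) {
  n_units <- as.integer(n_units)
  n <- as.integer(n)
  if (n_units < 1) abort_invalid("n_units must be >= 1")
  if (length(start_window) != 2) abort_invalid("start_window must be c(earliest, latest)")
  earliest <- as.integer(start_window[1])
  latest <- as.integer(start_window[2])
  if (earliest < 2) abort_invalid("earliest start must be >= 2 (at least one baseline occasion)")
  if (latest > n) abort_invalid("latest start must be <= n")
  if (latest < earliest) abort_invalid("start window is empty")
  min_stagger <- as.integer(min_stagger)
  if (distinct_starts && min_stagger < 1) {
    abort_invalid("min_stagger must be >= 1 when starts are distinct")
  }
  if (min_stagger < 0) abort_invalid("min_stagger must be >= 0")
  w <- latest - earliest + 1
  if (distinct_starts && w < n_units) {
    abort_invalid("window width ", w, " cannot hold ", n_units,
                  " pairwise-distinct start occasions")
  }
  new_design("mbd", list(n_units = n_units, n = n,
                         start_window = c(earliest = earliest, latest = latest),
                         distinct_starts = isTRUE(distinct_starts),
                         min_stagger = min_stagger))
}

#' Changing criterion design
#'
#' After a baseline phase, a performance criterion is set and changed
#' stepwise between adjacent treatment phases; treatment is never
#' withdrawn. The randomization scheme randomizes, for each phase boundary,
#' the moment of phase change among a small set of admissible candidate
#' occasions.
#'
#' @param phase_labels Character vector of phase labels in order, baseline
#'   first (e.g., `c("A","B","C",...)`).
#' @param candidate_changepoints List with one element per phase boundary
#'   (length `length(phase_labels) - 1`); each element is a strictly
#'   increasing integer vector of admissible first occasions of the next
#'   phase.
#' @param criteria Data frame with columns `phase_label`, `lower`, `upper`
#'   giving the criterion for each treatment phase; single-point criteria
#'   have `lower == upper`, range-bound criteria have `lower < upper`.
#' @param n Total occasions.
#' @param direction `"decrease"` or `"increase"`: the therapeutic direction
#'   of the criterion schedule (metadata used by the synthetic generator
#'   and reports).
#' @param baseline_criterion One of `"median_of_baseline"` (the baseline
#'   criterion is the median of the observed baseline phase, computed once
#'   from the realized assignment and held fixed across all reference
#'   assignments), `"fixed"` (use `baseline_value`), or `"none"` (baseline
#'   occasions excluded from the adherence statistic is not supported;
#'   "none" errors if baseline occasions are scored).
#' @param baseline_value Numeric criterion for the baseline phase when
#'   `baseline_criterion = "fixed"`.
#' @return A design object of class `sced_ccd_design`.
#' @examples
#' ccd_design(
#'   phase_labels = c("A", "B", "C"),
#'   candidate_changepoints = list(c(6, 7), c(11, 12)),
#'   criteria = data.frame(phase_label = c("B", "C"), lower = c(300, 295),
#'                         upper = c(300, 295)),
#'   n = 16, direction = "decrease"
#' )
#' @export
ccd_design <- function(phase_labels, candidate_changepoints, criteria, n,
                       direction = c("decrease", "increase"),
                       baseline_criterion = c("median_of_baseline", "fixed", "none"),
                       baseline_value = NULL) {
  phase_labels <- as.character(phase_labels)
  direction <- match.arg(direction)
  baseline_criterion <- match.arg(baseline_criterion)
  k <- length(phase_labels)
  n <- as.integer(n)
  if (k < 2) abort_invalid("a changing criterion design needs a baseline and >= 1 treatment phase")
  if (anyDuplicated(phase_labels)) abort_invalid("phase labels must be distinct")
  if (!is.list(candidate_changepoints) || length(candidate_changepoints) != k - 1) {
    abort_invalid("candidate_changepoints must be a list with one element per boundary (",
                  k - 1, ")")
  }
  candidate_changepoints <- lapply(candidate_changepoints, as.integer)
  for (b in seq_along(candidate_changepoints)) {
    cand <- candidate_changepoints[[b]]
    if (length(cand) == 0) abort_invalid("boundary ", b, " has no candidate change points")
    if (is.unsorted(cand, strictly = TRUE)) {
      abort_invalid("candidates for boundary ", b, " must be strictly increasing")
    }
    if (min(cand) < 2 || max(cand) > n) {
      abort_invalid("candidates for boundary ", b, " must lie in 2..n")
    }
  }
  # every combination of candidates must yield non-empty phases in order:
  # the largest candidate at boundary b must precede the smallest at b + 1
  if (k > 2) {
    for (b in seq_len(k - 2)) {
      if (max(candidate_changepoints[[b]]) >= min(candidate_changepoints[[b + 1]])) {
        abort_invalid("candidate lists for boundaries ", b, " and ", b + 1,
                      " overlap; some combinations would give an empty phase")
      }
    }
  }
  criteria <- tibble::as_tibble(criteria)
  needed <- c("phase_label", "lower", "upper")
  if (!all(needed %in% names(criteria))) {
    abort_invalid("criteria needs columns phase_label, lower, upper")
  }
  treatment_labels <- phase_labels[-1]
  if (!setequal(criteria$phase_label, treatment_labels)) {
    abort_invalid("criteria must cover exactly the treatment phases: ",
                  paste(treatment_labels, collapse = ", "))
  }
  if (any(criteria$lower > criteria$upper)) {
    abort_invalid("criterion ranges need lower <= upper")
  }
  if (baseline_criterion == "fixed") {
    if (is.null(baseline_value) || !is.numeric(baseline_value)) {
      abort_invalid("baseline_criterion = \"fixed\" requires a numeric baseline_value")
    }
  } else {
    baseline_value <- NULL
  }
  new_design("ccd", list(
    phase_labels = phase_labels,
    candidate_changepoints = candidate_changepoints,
    criteria = criteria[match(treatment_labels, criteria$phase_label), ],
    n = n,
    direction = direction,
    baseline_criterion = baseline_criterion,
    baseline_value = baseline_value
  ))
}

check_counts <- function(counts, n, required_sum = TRUE) {
  if (is.null(names(counts)) || any(names(counts) == "") || anyDuplicated(names(counts))) {
    abort_invalid("counts must be a named vector with distinct condition labels")
  }
  if (length(counts) < 2) abort_invalid("at least two conditions are required")
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    abort_invalid("condition counts must be non-negative integers")
  }
  if (required_sum && sum(counts) != n) {
    abort_invalid("condition counts sum to ", sum(counts), ", not n = ", n)
  }
  invisible(counts)
}

#' Validate a design specification
#'
#' Re-checks all type invariants of a design object (constructors validate
#' on creation; this re-validates objects that may have been edited or
#' deserialized).
#'
#' @param design A design object created by one of the design constructors.
#' @return The design, unchanged, if valid; otherwise an error naming the
#'   violated invariant.
#' @export
validate_design <- function(design) {
  if (!inherits(design, "sced_design")) abort_invalid("not an sced_design object")
  rebuilt <- switch(
    design$family,
    phase = phase_design(design$pattern, design$n, design$min_phase_length),
    crd = crd_design(design$n, design$counts, design$unrestricted),
    atd = atd_design(design$n, design$counts, design$max_run),
    rbd = rbd_design(design$n_blocks, design$treatments),
    mbd = mbd_design(design$n_units, design$n, design$start_window,
                     design$distinct_starts, design$min_stagger),
    ccd = ccd_design(design$phase_labels, design$candidate_changepoints,
                     design$criteria, design$n, design$direction,
                     design$baseline_criterion, design$baseline_value),
    abort_invalid("unknown design family: ", design$family)
  )
  design
}

#' @export
print.sced_design <- function(x, ...) {
  cat("<sced_design:", x$family, ">\n")
  desc <- switch(
    x$family,
    phase = paste0("  pattern ", labels_to_string(x$pattern), ", n = ", x$n,
                   ", min phase length ", x$min_phase_length),
    crd = paste0("  n = ", x$n, ", counts ",
                 paste0(names(x$counts), "=", x$counts, collapse = " "),
                 if (x$unrestricted) " (unrestricted)" else " (fixed totals)"),
    atd = paste0("  n = ", x$n, ", counts ",
                 paste0(names(x$counts), "=", x$counts, collapse = " "),
                 ", max run ", x$max_run),
    rbd = paste0("  ", x$n_blocks, " blocks x treatments {",
                 paste(x$treatments, collapse = ","), "}, n = ", x$n),
    mbd = paste0("  ", x$n_units, " units, n = ", x$n, ", starts in ",
                 x$start_window[1], "..", x$start_window[2],
                 if (x$distinct_starts) paste0(", min stagger ", x$min_stagger) else ""),
    ccd = paste0("  phases ", paste(x$phase_labels, collapse = ""), ", n = ", x$n,
                 ", ", length(x$candidate_changepoints), " randomized boundaries")
  )
  cat(desc, "\n")
  invisible(x)
}

#' Convert change points to per-occasion condition labels
#'
#' Occasion `t` receives the label of the phase whose closed interval
#' contains it; the first phase starts at occasion 1 and each change point
#' is the first occasion of the next phase.
#'
#' @param change_points Strictly increasing integer vector of phase-change
#'   occasions (possibly empty for a single phase), each in `2..n`.
#' @param n Total occasions.
#' @param pattern Character vector of phase labels, one per phase
#'   (`length(change_points) + 1`).
#' @return Character vector of `n` per-occasion labels.
#' @examples
#' labels_from_changepoints(c(7, 13, 19), n = 24, pattern = c("A", "B", "A", "B"))
#' @export
labels_from_changepoints <- function(change_points, n, pattern) {
  change_points <- as.integer(change_points)
  n <- as.integer(n)
  pattern <- as.character(pattern)
  if (length(pattern) != length(change_points) + 1) {
    abort_invalid("pattern must have one more label than there are change points")
  }
  if (length(change_points) > 0) {
    if (is.unsorted(change_points, strictly = TRUE)) {
      abort_invalid("change points must be strictly increasing")
    }
    if (min(change_points) < 2 || max(change_points) > n) {
      abort_invalid("change points must lie within 2..n")
    }
  }
  starts <- c(1L, change_points)
  ends <- c(change_points - 1L, n)
  rep(pattern, times = ends - starts + 1L)
}

#' Recover change points from a per-occasion label sequence
#'
#' The inverse of [labels_from_changepoints()]: returns the first occasion
#' of every phase after the first (maximal runs define the phases).
#'
#' @param labels Character vector of per-occasion condition labels.
#' @return Integer vector of change points (empty for a single phase).
#' @examples
#' changepoints_from_labels(c("A", "A", "A", "B", "B", "B"))
#' @export
changepoints_from_labels <- function(labels) {
  labels <- string_to_labels(labels)
  if (length(labels) == 0) return(integer(0))
  which(labels[-1] != labels[-length(labels)]) + 1L
}

# run lengths and labels of the maximal runs of a label sequence
label_runs <- function(labels) {
  labels <- string_to_labels(labels)
  r <- rle(labels)
  tibble::tibble(phase = seq_along(r$values), label = r$values, length = r$lengths)
}
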