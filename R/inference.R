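# Reference distributions and randomization p-values.
#
# The randomization test evaluates the chosen statistic under every
# admissible assignment (exhaustive) or under a uniform random sample of
# them (Monte Carlo), and the p-value is the proportion of reference
# statistics as extreme as or more extreme than the observed one, with the
# observed assignment always counted in the denominator: this guarantees
# p >= 1/R and makes the test exactly valid under the randomization model.

#' Build the reference distribution of a statistic
#'
#' Evaluates the statistic at every admissible assignment (exhaustive) or
#' at `n_mc - 1` uniform draws with replacement plus the observed
#' assignment (Monte Carlo).
#'
#' @param data A series tibble (`unit`, `occasion`, `value`).
#' @param design A design object.
#' @param observed The realized assignment: per-occasion labels for phase
#'   and alternation designs (phase designs also accept the change-point
#'   vector), start points for multiple baseline designs, change points for
#'   changing criterion designs.
#' @param statistic A [sced_statistic()] or its name; defaults to the
#'   design family's conventional statistic ([default_statistic()]).
#' @param method `"auto"` (exhaustive when `R <= exhaustive_cap`, else
#'   Monte Carlo), `"exhaustive"`, or `"monte_carlo"`.
#' @param n_mc Monte Carlo sample size (reference set size including the
#'   observed assignment).
#' @param seed Optional integer seed for the Monte Carlo draws.
#' @param exhaustive_cap Largest reference set enumerated exhaustively.
#' @param criteria Resolved criterion table for `ccd_mad`; when omitted for
#'   a changing criterion design it is resolved from the design and the
#'   observed assignment (see [resolve_ccd_criteria()]).
#' @return An object of class `sced_reference` with elements `values`
#'   (statistic values, one per reference assignment), `observed`,
#'   `observed_assignment`, `R` (admissible-set size), `method`, `n_mc`,
#'   `seed`, and `statistic`.
#' @examples
#' d <- phase_design(c("A", "B"), n = 10, min_phase_length = 3)
#' y <- sced_series(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
#' build_reference(y, d, observed = c(5))
#' @export
build_reference <- function(data, design, observed, statistic = NULL,
                            method = c("auto", "exhaustive", "monte_carlo"),
                            n_mc = 1000, seed = NULL, exhaustive_cap = 1e7,
                            criteria = NULL) {
  method <- match.arg(method)
  validate_design(design)
  data <- validate_series(data)
  if (is.null(statistic)) statistic <- default_statistic(design)
  if (is.character(statistic)) statistic <- sced_statistic(statistic)
  observed <- normalize_assignment(design, observed)
  if (!is_admissible(design, observed)) {
    abort_invalid("the realized assignment is not admissible under the design")
  }
  if (statistic$name == "ccd_mad" && is.null(criteria)) {
    criteria <- resolve_ccd_criteria(design, data, observed)
  }
  R <- count_assignments(design)
  if (method == "auto") {
    method <- if (R <= exhaustive_cap) "exhaustive" else "monte_carlo"
  }
  if (method == "exhaustive" && R > exhaustive_cap) {
    abort_invalid("R = ", format(R, big.mark = ","), " exceeds the exhaustive cap ",
                  "of ", format(exhaustive_cap, big.mark = ","),
                  "; use method = \"monte_carlo\"")
  }
  evaluate <- make_stat_evaluator(data, design, statistic, criteria)
  observed_value <- evaluate(observed)
  if (method == "exhaustive") {
    set <- enumerate_assignments(design, cap = exhaustive_cap)
    values <- vapply(assignment_column(design, set), evaluate, 1.0)
  } else {
    if (n_mc < 2) abort_invalid("n_mc must be >= 2")
    draws <- sample_assignments(design, n_draws = n_mc - 1, seed = seed)
    values <- c(vapply(assignment_column(design, draws), evaluate, 1.0),
                observed_value)
  }
  structure(
    list(values = values, observed = observed_value,
         observed_assignment = observed, R = R, method = method,
         n_mc = if (method == "monte_carlo") as.integer(n_mc) else NA_integer_,
         seed = seed, statistic = statistic, design = design),
    class = "sced_reference"
  )
}

# the list of assignment representations that the evaluator consumes
assignment_column <- function(design, set) {
  switch(design$family,
         phase = set$change_points,
         crd = ,
         atd = ,
         rbd = set$label_seq,
         mbd = set$start_points,
         ccd = set$change_points)
}

# phase assignments may be given as labels or change points; other families
# pass through (labels coerced from string form)
normalize_assignment <- function(design, assignment) {
  if (design$family == "phase") {
    if (is.numeric(assignment)) return(as.integer(assignment))
    labels <- string_to_labels(assignment)
    runs <- label_runs(labels)
    if (!identical(as.character(runs$label), design$pattern)) {
      abort_invalid("label sequence does not follow the phase pattern ",
                    labels_to_string(design$pattern))
    }
    return(changepoints_from_labels(labels))
  }
  if (design$family %in% c("crd", "atd", "rbd")) {
    return(string_to_labels(assignment))
  }
  as.integer(assignment)
}

# Precomputed fast evaluators, one per (family, statistic) pair; they must
# agree exactly with the exported statistic functions (tested).
make_stat_evaluator <- function(data, design, statistic, criteria = NULL) {
  if (design$family == "phase" &&
      statistic$name %in% c("phase_mean_diff_BA", "phase_mean_diff_AB",
                            "phase_mean_diff_abs")) {
    values <- series_values(data)
    if (length(values) != design$n) {
      abort_invalid("series has ", length(values), " occasions but the design has ",
                    design$n)
    }
    cs <- c(0, cumsum(values))
    sign <- ifelse(design$pattern %in% statistic$b_labels, 1,
                   ifelse(design$pattern %in% statistic$a_labels, -1, 0))
    n <- design$n
    k <- length(design$pattern)
    flip <- switch(statistic$name, phase_mean_diff_BA = 1,
                   phase_mean_diff_AB = -1, phase_mean_diff_abs = 0)
    return(function(assignment) {
      cp <- as.integer(assignment)
      starts <- c(1L, cp)
      ends <- c(cp - 1L, n)
      means <- (cs[ends + 1L] - cs[starts]) / (ends - starts + 1L)
      ba <- sum(sign * means)
      if (flip == 0) abs(ba) else flip * ba
    })
  }
  if (design$family %in% c("crd", "atd", "rbd") &&
      statistic$name == "alternation_mean_diff_AB") {
    values <- series_values(data)
    if (length(values) != design$n) {
      abort_invalid("series length does not match the design")
    }
    a_labels <- statistic$a_labels
    b_labels <- statistic$b_labels
    return(function(assignment) {
      labels <- assignment
      in_a <- labels %in% a_labels
      in_b <- labels %in% b_labels
      mean(values[in_a]) - mean(values[in_b])
    })
  }
  if (design$family == "mbd" && statistic$name == "mbd_mean_diff") {
    vals <- series_value_list(data)
    if (length(vals) != design$n_units) {
      abort_invalid("data has ", length(vals), " units but the design has ",
                    design$n_units)
    }
    # per-unit table of (post mean - pre mean) for every window start
    w <- design$start_window
    window <- seq(w[["earliest"]], w[["latest"]])
    diff_table <- vapply(vals, function(v) {
      cs <- c(0, cumsum(v))
      n <- length(v)
      vapply(window, function(s) {
        (cs[n + 1] - cs[s]) / (n - s + 1) - cs[s] / (s - 1)
      }, 1.0)
    }, numeric(length(window)))
    offset <- w[["earliest"]] - 1L
    u <- design$n_units
    return(function(assignment) {
      idx <- as.integer(assignment) - offset
      mean(diff_table[cbind(idx, seq_len(u))])
    })
  }
  if (design$family == "ccd" && statistic$name == "ccd_mad") {
    values <- series_values(data)
    n <- length(values)
    k <- length(design$phase_labels)
    lo <- criteria$lower
    hi <- criteria$upper
    return(function(assignment) {
      cp <- as.integer(assignment)
      phase_of <- rep(seq_len(k), times = diff(c(1L, cp, n + 1L)))
      dev <- pmax(lo[phase_of] - values, values - hi[phase_of], 0)
      mean(dev)
    })
  }
  # generic fallback through the exported statistic functions
  function(assignment) {
    assignment_statistic(data, design, statistic, assignment, criteria)
  }
}

#' Randomization-test p-value from a reference distribution
#'
#' The right-tailed p-value is the proportion of reference statistics
#' greater than or equal to the observed one; left-tailed, less than or
#' equal; two-sided, the right tail applied to absolute values (the
#' absolute-difference statistic), not tail-doubling. The observed
#' assignment counts itself, so `p >= 1/R` always. Value comparisons use a
#' small relative tolerance so that algebraically tied statistics compare
#' as ties.
#'
#' @param ref A [build_reference()] result.
#' @param tail `"right"`, `"left"`, or `"two_sided"`.
#' @param alpha Significance level for the verbal decision (reject iff
#'   `p <= alpha`).
#' @return An object of class `sced_test` with the observed statistic,
#'   p-value, tail, reference-set size, method, and decision.
#' @export
randomization_pvalue <- function(ref, tail = c("right", "left", "two_sided"),
                                 alpha = 0.05) {
  tail <- match.arg(tail)
  if (!inherits(ref, "sced_reference")) abort_invalid("ref must be an sced_reference")
  if (!(alpha > 0 && alpha < 1)) abort_invalid("alpha must be in (0, 1)")
  values <- ref$values
  obs <- ref$observed
  count <- switch(
    tail,
    right = sum(ge_tol(values, obs)),
    left = sum(le_tol(values, obs)),
    two_sided = sum(ge_tol(abs(values), abs(obs)))
  )
  p <- count / length(values)
  structure(
    list(statistic_name = ref$statistic$name, observed = obs, p_value = p,
         tail = tail, R = ref$R, method = ref$method, n_mc = ref$n_mc,
         seed = ref$seed, alpha = alpha, reject = p <= alpha,
         n_values = length(values)),
    class = "sced_test"
  )
}

#' Run a randomization test in one call
#'
#' Convenience wrapper: builds the reference distribution and computes the
#' p-value.
#'
#' @inheritParams build_reference
#' @inheritParams randomization_pvalue
#' @return An `sced_test` (the reference distribution is attached as
#'   attribute `"reference"` for plotting).
#' @examples
#' d <- phase_design(c("A", "B", "A", "B"), n = 24, min_phase_length = 3)
#' y <- sced_series(rep(c(0, 1, 0, 1), each = 6))
#' sced_test(y, d, observed = c(7, 13, 19))
#' @export
sced_test <- function(data, design, observed, statistic = NULL,
                      tail = c("right", "left", "two_sided"),
                      method = c("auto", "exhaustive", "monte_carlo"),
                      n_mc = 1000, seed = NULL, alpha = 0.05,
                      exhaustive_cap = 1e7, criteria = NULL) {
  tail <- match.arg(tail)
  ref <- build_reference(data, design, observed, statistic = statistic,
                         method = method, n_mc = n_mc, seed = seed,
                         exhaustive_cap = exhaustive_cap, criteria = criteria)
  out <- randomization_pvalue(ref, tail = tail, alpha = alpha)
  attr(out, "reference") <- ref
  out
}

#' @export
print.sced_test <- function(x, digits = 2, ...) {
  cat("Randomization test\n")
  cat("  statistic: ", x$statistic_name, " = ", round(x$observed, digits), "\n", sep = "")
  cat("  reference: ", if (x$method == "exhaustive") {
    paste0("exhaustive, R = ", format(x$R, big.mark = ","))
  } else {
    paste0("Monte Carlo, ", x$n_values, " of R = ", format(x$R, big.mark = ","),
           if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")") else "")
  }, "\n", sep = "")
  cat("  p-value (", x$tail, " tail): ", format(round(x$p_value, 3)), "\n", sep = "")
  cat("  decision at alpha = ", x$alpha, ": ",
      if (x$reject) "reject" else "do not reject",
      " the null hypothesis of no treatment effect\n", sep = "")
  invisible(x)
}

#' @export
print.sced_reference <- function(x, ...) {
  cat("<sced_reference> ", x$statistic$name, ", ",
      if (x$method == "exhaustive") {
        paste0("exhaustive (R = ", format(x$R, big.mark = ","), ")")
      } else {
        paste0("Monte Carlo (", length(x$values), " values, R = ",
               format(x$R, big.mark = ","), ")")
      }, "\n", sep = "")
  cat("  observed ", round(x$observed, 4), "; reference range [",
      round(min(x$values), 4), ", ", round(max(x$values), 4), "]\n", sep = "")
  invisible(x)
}
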