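# Power diagnostics for randomization tests.
#
# Because a randomization p-value can never fall below 1/R, a design whose
# admissible set is smaller than 1/alpha has exactly zero power at level
# alpha, whatever the effect size. Beyond that analytic floor, power is
# estimated by simulation under the randomization model: the true
# assignment is redrawn uniformly each replicate, data are generated
# conditional on it, and the test is run at level alpha.

#' Minimal attainable randomization p-value
#'
#' The lowest possible p-value of a randomization test is the inverse of
#' the number of admissible assignments.
#'
#' @param R Number of admissible assignments (>= 1).
#' @return `1/R`.
#' @examples
#' minimal_pvalue(455)
#' minimal_pvalue(14)
#' @export
minimal_pvalue <- function(R) {
  if (R < 1) abort_invalid("R must be >= 1")
  1 / R
}

#' Can a randomization test ever reject?
#'
#' `TRUE` iff the minimal p-value `1/R` is attainable at level `alpha`,
#' i.e., `1/R <= alpha`. With fewer than `1/alpha` admissible assignments
#' (fewer than 20 at the conventional alpha of 0.05) the test has zero
#' power.
#'
#' @param R Number of admissible assignments.
#' @param alpha Significance level in (0, 1).
#' @return Logical.
#' @examples
#' has_nonzero_power(14, 0.05)  # FALSE
#' has_nonzero_power(20, 0.05)  # TRUE
#' @export
has_nonzero_power <- function(R, alpha = 0.05) {
  if (R < 1) abort_invalid("R must be >= 1")
  if (!(alpha > 0 && alpha < 1)) abort_invalid("alpha must be in (0, 1)")
  1 / R <= alpha
}

#' Estimate the power of a randomization test by simulation
#'
#' Simulates `n_sims` experiments: each replicate draws a true assignment
#' uniformly from the admissible set (or uses `fixed_assignment`), generates
#' data from the effect model conditional on it, runs the randomization
#' test, and records rejection at `alpha`. When `1/R > alpha` the result is
#' exactly zero power with zero variance and no simulation is run.
#'
#' @param design A design object.
#' @param model An [effect_model()] describing the data-generating process.
#' @param statistic A [sced_statistic()] or name; defaults per family.
#' @param alpha Significance level.
#' @param n_sims Number of simulated experiments.
#' @param seed Optional integer seed governing the whole simulation.
#' @param tail Test tail (`"right"`, `"left"`, `"two_sided"`); changing
#'   criterion adherence tests are left-tailed.
#' @param method Inner-test method: `"auto"` uses the exhaustive test when
#'   `R <= exhaustive_cap`, Monte Carlo otherwise.
#' @param n_mc Inner Monte Carlo sample size.
#' @param exhaustive_cap Largest R handled exhaustively under
#'   `method = "auto"` (default `1e4`).
#' @param fixed_assignment Optional assignment held fixed as the truth in
#'   every replicate (sensitivity checks); the default redraws it, matching
#'   the randomization model under which the test is valid.
#' @param b_labels Labels receiving the scalar `delta` shift.
#' @return An object of class `sced_power_estimate` with the estimated
#'   power, Monte Carlo standard error, and the simulation settings.
#' @examples
#' d <- phase_design(c("A", "B", "A", "B"), 15, 3)
#' estimate_power(d, effect_model(delta = 2, sd = 1), n_sims = 100, seed = 1)
#' @export
estimate_power <- function(design, model, statistic = NULL, alpha = 0.05,
                           n_sims = 1000, seed = NULL,
                           tail = c("right", "left", "two_sided"),
                           method = c("auto", "exhaustive", "monte_carlo"),
                           n_mc = 1000, exhaustive_cap = 1e4,
                           fixed_assignment = NULL, b_labels = "B") {
  tail <- match.arg(tail)
  method <- match.arg(method)
  validate_design(design)
  if (!(alpha > 0 && alpha < 1)) abort_invalid("alpha must be in (0, 1)")
  if (n_sims < 1) abort_invalid("n_sims must be >= 1")
  if (is.null(statistic)) statistic <- default_statistic(design)
  if (is.character(statistic)) statistic <- sced_statistic(statistic)
  R <- count_assignments(design)
  if (R < 1) abort_invalid("the admissible set is empty")

  if (!has_nonzero_power(R, alpha)) {
    return(new_power_estimate(0L, n_sims, alpha, design, statistic, model,
                              seed, tail, "analytic", R))
  }

  if (method == "auto") method <- if (R <= exhaustive_cap) "exhaustive" else "monte_carlo"
  ref_set <- if (method == "exhaustive") {
    enumerate_assignments(design, cap = exhaustive_cap)
  } else {
    NULL
  }
  ref_assignments <- if (!is.null(ref_set)) assignment_column(design, ref_set)

  rejections <- with_seed(seed, {
    sum(vapply(seq_len(n_sims), function(i) {
      truth <- if (is.null(fixed_assignment)) {
        one <- sample_assignments(design, 1)
        assignment_column(design, one)[[1]]
      } else {
        normalize_assignment(design, fixed_assignment)
      }
      data <- if (design$family == "ccd") {
        generate_ccd_series(design, truth, model)
      } else {
        generate_series(design, truth, model, b_labels = b_labels)
      }
      criteria <- if (statistic$name == "ccd_mad") {
        resolve_ccd_criteria(design, data, truth)
      }
      evaluate <- make_stat_evaluator(data, design, statistic, criteria)
      obs <- evaluate(truth)
      values <- if (method == "exhaustive") {
        vapply(ref_assignments, evaluate, 1.0)
      } else {
        draws <- sample_assignments(design, n_mc - 1)
        c(vapply(assignment_column(design, draws), evaluate, 1.0), obs)
      }
      p <- switch(tail,
                  right = mean(ge_tol(values, obs)),
                  left = mean(le_tol(values, obs)),
                  two_sided = mean(ge_tol(abs(values), abs(obs))))
      p <= alpha
    }, TRUE))
  })
  new_power_estimate(rejections, n_sims, alpha, design, statistic, model,
                     seed, tail, method, R)
}

new_power_estimate <- function(rejections, n_sims, alpha, design, statistic,
                               model, seed, tail, method, R) {
  power <- rejections / n_sims
  structure(
    list(alpha = alpha, n_sims = as.integer(n_sims),
         rejections = as.integer(rejections), power = power,
         mc_stderr = if (method == "analytic") 0 else sqrt(power * (1 - power) / n_sims),
         design = design, statistic_name = statistic$name, effect = model,
         seed = seed, tail = tail, method = method, R = R),
    class = "sced_power_estimate"
  )
}

#' @export
print.sced_power_estimate <- function(x, ...) {
  cat("Randomization-test power estimate\n")
  cat("  design: ", x$design$family, ", R = ", format(x$R, big.mark = ","),
      "; statistic: ", x$statistic_name, " (", x$tail, " tail)\n", sep = "")
  if (x$method == "analytic") {
    cat("  minimal p-value 1/R = ", format(round(1 / x$R, 4)), " > alpha = ",
        x$alpha, ": power is exactly 0\n", sep = "")
  } else {
    cat("  effect: delta = ", paste(x$effect$delta, collapse = ","), ", sd = ",
        x$effect$sd, ", ar1 = ", x$effect$ar1, "\n", sep = "")
    cat("  power = ", round(x$power, 3), " (", x$rejections, "/", x$n_sims,
        " rejections at alpha = ", x$alpha, ", MC se ",
        round(x$mc_stderr, 4), ")\n", sep = "")
  }
  invisible(x)
}
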