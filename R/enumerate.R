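# Counting, exhaustive enumeration, and uniform sampling of the admissible
# treatment assignments of each design family.
#
# The number of admissible assignments R drives the whole inference: the
# lowest attainable randomization p-value is 1/R, so a design with fewer
# than 1/alpha assignments has zero power at level alpha.
#
# Canonical enumeration order is lexicographic (on the change/start vector
# for phase, multiple baseline, and changing criterion designs; on the
# label sequence for alternation designs). Monte Carlo reproducibility is
# governed solely by the seed, never by enumeration order.

#' Count admissible phase-design assignments
#'
#' Number of ways to partition `n` consecutive occasions into `k` ordered
#' phases of at least `m` occasions each: the number of compositions of `n`
#' into `k` parts each `>= m`, i.e., `choose(n - k*m + k - 1, k - 1)`.
#'
#' @param n Total occasions.
#' @param k Number of phases.
#' @param m Minimum phase length.
#' @return The count, as a double (counts can exceed integer range).
#' @examples
#' count_phase_assignments(24, 4, 3) # 455
#' @export
count_phase_assignments <- function(n, k, m) {
  if (k < 1 || m < 1) abort_invalid("k and m must be >= 1")
  if (n < k * m) abort_invalid("n = ", n, " < k*m = ", k * m)
  choose(n - k * m + k - 1, k - 1)
}

#' Count admissible multiple-baseline start assignments
#'
#' For `u` distinguishable units drawing intervention start occasions from
#' a window of width `W`: `W!/(W-u)!` ordered assignments when starts must
#' be pairwise distinct, `W^u` otherwise. A minimum stagger separation `s`
#' generalizes distinctness (`s = 1`): the count becomes
#' `u! * choose(W - (u-1)*(s-1), u)`.
#'
#' @param W Window width (number of admissible start occasions).
#' @param u Number of units.
#' @param distinct Require pairwise-distinct starts.
#' @param min_stagger Minimum separation between any two starts (only used
#'   when `distinct`).
#' @return The count, as a double.
#' @examples
#' count_mbd_assignments(22, 5) # 3160080
#' @export
count_mbd_assignments <- function(W, u, distinct = TRUE, min_stagger = 1L) {
  if (W < 1 || u < 1) abort_invalid("W and u must be >= 1")
  if (!distinct) return(W^u)
  if (W < u) abort_invalid("W = ", W, " < u = ", u, ": no distinct assignment exists")
  s <- as.integer(min_stagger)
  if (s < 1) abort_invalid("min_stagger must be >= 1 for distinct starts")
  eff <- W - (u - 1) * (s - 1)
  if (eff < u) return(0)
  factorial(u) * choose(eff, u)
}

#' Count admissible assignments of any design
#'
#' Closed-form (or product-form) size of the reference set of a design.
#' For alternating treatments designs the count is obtained by a dynamic
#' program over runs, since the run-length cap has no simple closed form.
#'
#' @param design A design object.
#' @return The count `R`, as a double.
#' @examples
#' count_assignments(phase_design(c("A", "B", "A", "B"), 24, 3)) # 455
#' count_assignments(atd_design(6, c(A = 3, B = 3), max_run = 2)) # 14
#' @export
count_assignments <- function(design) {
  validate_design(design)
  switch(
    design$family,
    phase = count_phase_assignments(design$n, length(design$pattern),
                                    design$min_phase_length),
    crd = if (design$unrestricted) {
      length(design$counts)^design$n
    } else {
      exp(lfactorial(design$n) - sum(lfactorial(design$counts))) |> round()
    },
    atd = count_atd(design$counts, design$max_run),
    rbd = factorial(length(design$treatments))^design$n_blocks,
    mbd = {
      W <- design$start_window[["latest"]] - design$start_window[["earliest"]] + 1
      count_mbd_assignments(W, design$n_units, design$distinct_starts,
                            design$min_stagger)
    },
    ccd = prod(vapply(design$candidate_changepoints, length, 1L))
  )
}

# dynamic program: sequences over the labels with fixed totals and maximal
# run length <= max_run; memoized on (remaining counts, last label, run len)
count_atd <- function(counts, max_run) {
  if (is.infinite(max_run)) {
    return(round(exp(lfactorial(sum(counts)) - sum(lfactorial(counts)))))
  }
  labs <- names(counts)
  memo <- new.env(parent = emptyenv())
  recurse <- function(rem, last, run) {
    if (all(rem == 0)) return(1)
    key <- paste(c(rem, last, run), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    total <- 0
    for (i in seq_along(labs)) {
      if (rem[i] == 0) next
      new_run <- if (i == last) run + 1 else 1
      if (new_run > max_run) next
      rem2 <- rem
      rem2[i] <- rem2[i] - 1L
      total <- total + recurse(rem2, i, new_run)
    }
    memo[[key]] <- total
    total
  }
  recurse(as.integer(counts), 0L, 0L)
}

#' Enumerate all admissible assignments of a design
#'
#' Produces the full reference set of assignments in canonical
#' (lexicographic) order, as one tibble row per assignment.
#'
#' @param design A design object.
#' @param cap Refuse to enumerate more than this many assignments
#'   (default `1e6`); use [count_assignments()] and Monte Carlo sampling
#'   for larger reference sets.
#' @return A tibble with column `assignment_id` plus, depending on the
#'   family: `labels` (collapsed display string) and `label_seq`
#'   (list-column of per-occasion label vectors) for phase and alternation
#'   families, with `change_points` (list-column) additionally for phase
#'   designs; `start_points` (list-column of per-unit start occasions) for
#'   multiple baseline designs; `change_points` (list-column) for changing
#'   criterion designs.
#' @examples
#' enumerate_assignments(atd_design(6, c(A = 3, B = 3), max_run = 2))
#' @export
enumerate_assignments <- function(design, cap = 1e6) {
  validate_design(design)
  R <- count_assignments(design)
  if (R > cap) {
    abort_invalid("reference set has ", format(R, big.mark = ","),
                  " assignments, above the enumeration cap of ", cap,
                  "; use count_assignments() or Monte Carlo sampling")
  }
  out <- switch(
    design$family,
    phase = enumerate_phase(design),
    crd = enumerate_crd(design),
    atd = enumerate_atd(design),
    rbd = enumerate_rbd(design),
    mbd = enumerate_mbd(design),
    ccd = enumerate_ccd(design)
  )
  if (nrow(out) != R) {
    # defensive: the closed-form count and the generator must agree
    abort_invalid("internal error: enumerated ", nrow(out),
                  " assignments but closed form gives ", R)
  }
  out$assignment_id <- seq_len(nrow(out))
  dplyr::relocate(out, "assignment_id")
}

# -- per-family enumeration ---------------------------------------------------

# compositions of n into k parts each >= m, in lexicographic order of the
# change-point vector, via the stars-and-bars bijection with (k-1)-subsets
compositions_min <- function(n, k, m) {
  if (k == 1) return(matrix(n, nrow = 1))
  slack <- n - k * m
  positions <- utils::combn(slack + k - 1, k - 1) # columns in lex order
  # subset -> weak composition of `slack`, then add m to each part
  parts <- apply(positions, 2, function(cut) {
    diff(c(0L, cut, slack + k)) - 1L + m
  })
  t(parts)
}

enumerate_phase <- function(design) {
  k <- length(design$pattern)
  comp <- compositions_min(design$n, k, design$min_phase_length)
  cps <- lapply(seq_len(nrow(comp)), function(i) {
    as.integer(cumsum(comp[i, ])[-k] + 1L)
  })
  seqs <- lapply(cps, labels_from_changepoints, n = design$n,
                 pattern = design$pattern)
  tibble::tibble(
    labels = vapply(seqs, labels_to_string, ""),
    label_seq = seqs,
    change_points = cps
  )
}

# all distinct permutations of a multiset of labels, lexicographic in the
# label order given
multiset_permutations <- function(counts) {
  labs <- names(counts)
  out <- list()
  recurse <- function(rem, prefix) {
    if (all(rem == 0)) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (i in seq_along(labs)) {
      if (rem[i] == 0) next
      rem2 <- rem
      rem2[i] <- rem2[i] - 1L
      recurse(rem2, c(prefix, labs[i]))
    }
  }
  recurse(as.integer(counts), character(0))
  out
}

max_run_length <- function(labels) max(rle(labels)$lengths)

enumerate_crd <- function(design) {
  labs <- names(design$counts)
  if (design$unrestricted) {
    grids <- rev(rep(list(labs), design$n))
    g <- do.call(expand.grid, c(grids, stringsAsFactors = FALSE))
    seqs <- lapply(seq_len(nrow(g)), function(i) rev(as.character(unlist(g[i, ]))))
  } else {
    seqs <- multiset_permutations(design$counts)
  }
  tibble::tibble(
    labels = vapply(seqs, labels_to_string, ""),
    label_seq = seqs
  )
}

enumerate_atd <- function(design) {
  seqs <- multiset_permutations(design$counts)
  keep <- vapply(seqs, function(s) max_run_length(s) <= design$max_run, TRUE)
  seqs <- seqs[keep]
  tibble::tibble(
    labels = vapply(seqs, labels_to_string, ""),
    label_seq = seqs
  )
}

# all permutations of a set, lexicographic
permutations_of <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

enumerate_rbd <- function(design) {
  perms <- permutations_of(design$treatments)
  idx <- cartesian_lex(rep(list(seq_along(perms)), design$n_blocks))
  seqs <- lapply(seq_len(nrow(idx)), function(i) {
    unlist(perms[idx[i, ]], use.names = FALSE)
  })
  tibble::tibble(
    labels = vapply(seqs, labels_to_string, ""),
    label_seq = seqs
  )
}

# cartesian product of index lists, first coordinate varying slowest
# (lexicographic order on rows)
cartesian_lex <- function(lists) {
  g <- do.call(expand.grid, c(rev(lists), KEEP.OUT.ATTRS = FALSE))
  as.matrix(g[, rev(seq_along(lists)), drop = FALSE])
}

enumerate_mbd <- function(design) {
  window <- seq(design$start_window[["earliest"]], design$start_window[["latest"]])
  grid <- cartesian_lex(rep(list(window), design$n_units))
  if (design$distinct_starts) {
    s <- design$min_stagger
    keep <- apply(grid, 1, function(v) {
      sv <- sort(v)
      all(diff(sv) >= s)
    })
    grid <- grid[keep, , drop = FALSE]
  }
  tibble::tibble(
    start_points = lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  )
}

enumerate_ccd <- function(design) {
  grid <- cartesian_lex(design$candidate_changepoints)
  tibble::tibble(
    change_points = lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
  )
}

# -- admissibility ------------------------------------------------------------

#' Test whether an assignment is admissible under a design
#'
#' @param design A design object.
#' @param assignment For phase and alternation designs, a per-occasion label
#'   vector (or collapsed string of single-character labels); for multiple
#'   baseline designs, an integer vector of per-unit start occasions; for
#'   changing criterion designs, an integer vector of per-boundary change
#'   points.
#' @return `TRUE` or `FALSE`.
#' @export
is_admissible <- function(design, assignment) {
  validate_design(design)
  switch(
    design$family,
    phase = {
      labels <- if (is.numeric(assignment)) {
        tryCatch(
          labels_from_changepoints(assignment, design$n, design$pattern),
          error = function(e) NULL
        )
      } else {
        string_to_labels(assignment)
      }
      if (is.null(labels) || length(labels) != design$n) return(FALSE)
      runs <- label_runs(labels)
      identical(as.character(runs$label), design$pattern) &&
        all(runs$length >= design$min_phase_length)
    },
    crd = {
      labels <- string_to_labels(assignment)
      if (length(labels) != design$n) return(FALSE)
      if (!all(labels %in% names(design$counts))) return(FALSE)
      if (design$unrestricted) return(TRUE)
      tab <- table(factor(labels, levels = names(design$counts)))
      all(as.integer(tab) == as.integer(design$counts))
    },
    atd = {
      labels <- string_to_labels(assignment)
      if (length(labels) != design$n) return(FALSE)
      tab <- table(factor(labels, levels = names(design$counts)))
      all(labels %in% names(design$counts)) &&
        all(as.integer(tab) == as.integer(design$counts)) &&
        max_run_length(labels) <= design$max_run
    },
    rbd = {
      labels <- string_to_labels(assignment)
      if (length(labels) != design$n) return(FALSE)
      t_per <- length(design$treatments)
      blocks <- split(labels, rep(seq_len(design$n_blocks), each = t_per))
      all(vapply(blocks, function(b) setequal(b, design$treatments) &&
                   !anyDuplicated(b), TRUE))
    },
    mbd = {
      starts <- as.integer(assignment)
      if (length(starts) != design$n_units) return(FALSE)
      w <- design$start_window
      if (any(starts < w[["earliest"]] | starts > w[["latest"]])) return(FALSE)
      if (design$distinct_starts) {
        all(diff(sort(starts)) >= design$min_stagger)
      } else TRUE
    },
    ccd = {
      cps <- as.integer(assignment)
      if (length(cps) != length(design$candidate_changepoints)) return(FALSE)
      all(mapply(function(cp, cand) cp %in% cand, cps,
                 design$candidate_changepoints)) &&
        !is.unsorted(cps, strictly = TRUE)
    }
  )
}

# -- uniform sampling ---------------------------------------------------------

#' Draw assignments uniformly at random from the admissible set
#'
#' Uses direct constructive samplers where the combinatorial structure
#' allows (compositions, permutations, products) and exact rejection
#' sampling from a uniform superset otherwise (run-length-restricted
#' alternation); both are exactly uniform over the admissible set.
#'
#' @param design A design object.
#' @param n_draws Number of assignments to draw.
#' @param seed Optional integer seed; with a seed the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return A tibble shaped like [enumerate_assignments()] output with
#'   `n_draws` rows (`assignment_id` numbers the draws).
#' @examples
#' sample_assignments(mbd_design(5, 55, c(15, 36)), n_draws = 3, seed = 1)
#' @export
sample_assignments <- function(design, n_draws = 1, seed = NULL) {
  validate_design(design)
  if (count_assignments(design) < 1) abort_invalid("the admissible set is empty")
  with_seed(seed, {
    draws <- lapply(seq_len(n_draws), function(i) sample_one(design))
    out <- switch(
      design$family,
      phase = tibble::tibble(
        labels = vapply(draws, function(d) labels_to_string(d$label_seq), ""),
        label_seq = lapply(draws, `[[`, "label_seq"),
        change_points = lapply(draws, `[[`, "change_points")
      ),
      crd = ,
      atd = ,
      rbd = tibble::tibble(
        labels = vapply(draws, function(d) labels_to_string(d$label_seq), ""),
        label_seq = lapply(draws, `[[`, "label_seq")
      ),
      mbd = tibble::tibble(start_points = lapply(draws, `[[`, "start_points")),
      ccd = tibble::tibble(change_points = lapply(draws, `[[`, "change_points"))
    )
    out$assignment_id <- seq_len(nrow(out))
    dplyr::relocate(out, "assignment_id")
  })
}

sample_one <- function(design) {
  switch(
    design$family,
    phase = {
      k <- length(design$pattern)
      m <- design$min_phase_length
      slack <- design$n - k * m
      # uniform composition via the stars-and-bars bijection
      cut <- sort(sample.int(slack + k - 1, k - 1))
      parts <- diff(c(0L, cut, slack + k)) - 1L + m
      cps <- as.integer(cumsum(parts)[-k] + 1L)
      list(change_points = cps,
           label_seq = labels_from_changepoints(cps, design$n, design$pattern))
    },
    crd = {
      labs <- names(design$counts)
      seq <- if (design$unrestricted) {
        sample(labs, design$n, replace = TRUE)
      } else {
        sample(rep(labs, times = design$counts))
      }
      list(label_seq = seq)
    },
    atd = {
      labs <- rep(names(design$counts), times = design$counts)
      for (try in seq_len(1e6)) {
        seq <- sample(labs)
        if (max_run_length(seq) <= design$max_run) return(list(label_seq = seq))
      }
      abort_invalid("rejection sampler failed: run-length constraint too tight")
    },
    rbd = {
      seq <- unlist(lapply(seq_len(design$n_blocks),
                           function(b) sample(design$treatments)),
                    use.names = FALSE)
      list(label_seq = seq)
    },
    mbd = {
      w <- design$start_window
      window <- seq(w[["earliest"]], w[["latest"]])
      u <- design$n_units
      if (!design$distinct_starts) {
        starts <- sample(window, u, replace = TRUE)
      } else {
        s <- design$min_stagger
        # sorted starts with consecutive gaps >= s correspond bijectively to
        # plain combinations from a shrunken window; permute over units
        eff <- length(window) - (u - 1) * (s - 1)
        base <- sort(sample.int(eff, u))
        sorted <- window[base + (seq_len(u) - 1L) * (s - 1L)]
        starts <- sorted[sample.int(u)]
      }
      list(start_points = as.integer(starts))
    },
    ccd = {
      cps <- vapply(design$candidate_changepoints, function(cand) {
        cand[sample.int(length(cand), 1)]
      }, 1L)
      list(change_points = as.integer(cps))
    }
  )
}
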