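# Internal helpers shared across the package.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the RNG seeded at `seed`, restoring the caller's RNG
#' state afterwards so that seeded calls do not perturb an enclosing
#' simulation. With `seed = NULL` the code runs against the current RNG
#' stream unchanged.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  genv <- globalenv()
  had_seed <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Relative tie tolerance for comparing statistic values: phase means are
# ratios of sums, so exact binary equality is fragile.
.tie_tol <- 1e-9

# values >= ref up to tie tolerance (vectorised over values)
ge_tol <- function(values, ref) {
  eps <- .tie_tol * pmax(1, abs(values), abs(ref))
  values >= ref - eps
}

# values <= ref up to tie tolerance
le_tol <- function(values, ref) {
  eps <- .tie_tol * pmax(1, abs(values), abs(ref))
  values <= ref + eps
}

abort_invalid <- function(..., class = "scedrand_invalid") {
  rlang::abort(paste0(...), class = class)
}

# collapse a label vector to the compact "AABAB" display form
labels_to_string <- function(labels) paste(labels, collapse = "")

# split "AABAB" into single-character labels; multi-character labels must be
# passed as vectors, not strings
string_to_labels <- function(x) {
  if (length(x) == 1 && nchar(x) > 1) strsplit(x, "", fixed = TRUE)[[1]] else x
}
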