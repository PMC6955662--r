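# Shared fixtures and independent brute-force oracles.
#
# The oracles enumerate admissible assignments by filtering an unrestricted
# superset, so they share no code with the package's constructive
# enumerators and closed-form counts.

# -- paper-shaped fixtures ----------------------------------------------------

fx_abab24 <- function() phase_design(c("A", "B", "A", "B"), n = 24, min_phase_length = 3)

fx_atd6 <- function() atd_design(n = 6, counts = c(A = 3, B = 3), max_run = 2)

fx_mbd55 <- function() mbd_design(n_units = 5, n = 55, start_window = c(15, 36))

# ten phases (baseline + nine criterion steps), two candidate change moments
# per boundary; criteria step down by five from a 311 baseline median
fx_ccd9 <- function() {
  ccd_design(
    phase_labels = LETTERS[1:10],
    candidate_changepoints = list(c(12, 13), c(19, 20), c(26, 27), c(36, 37),
                                  c(44, 45), c(54, 55), c(64, 65), c(77, 78),
                                  c(85, 86)),
    criteria = data.frame(phase_label = LETTERS[2:10],
                          lower = 311 - 5 * (1:9), upper = 311 - 5 * (1:9)),
    n = 95,
    direction = "decrease",
    baseline_criterion = "fixed",
    baseline_value = 311
  )
}

fx_ccd8 <- function() {
  d <- fx_ccd9()
  ccd_design(
    phase_labels = d$phase_labels[-10],
    candidate_changepoints = d$candidate_changepoints[1:8],
    criteria = d$criteria[1:8, ],
    n = 84,
    direction = "decrease",
    baseline_criterion = "fixed",
    baseline_value = 311
  )
}

# the exhaustively printed reference set for the six-occasion alternating
# treatments design with three occasions per condition and max run 2
atd6_reference_list <- c(
  "AABABB", "AABBAB", "ABAABB", "ABABAB", "ABABBA", "ABBAAB", "ABBABA",
  "BAABAB", "BAABBA", "BABAAB", "BABABA", "BABBAA", "BBAABA", "BBABAA"
)

# -- brute-force oracles ------------------------------------------------------

# all label sequences over `labs` of length n (unrestricted superset)
bf_all_sequences <- function(n, labs) {
  g <- do.call(expand.grid, c(rep(list(labs), n), stringsAsFactors = FALSE))
  lapply(seq_len(nrow(g)), function(i) as.character(unlist(g[i, ])))
}

bf_runs_ok <- function(seq, max_run) max(rle(seq)$lengths) <= max_run

bf_counts_ok <- function(seq, counts) {
  tab <- table(factor(seq, levels = names(counts)))
  all(as.integer(tab) == as.integer(counts))
}

# admissible phase-design label sequences by filtering the superset
bf_phase_sequences <- function(n, pattern, m) {
  labs <- unique(pattern)
  keep <- Filter(function(s) {
    r <- rle(s)
    identical(r$values, pattern) && all(r$lengths >= m)
  }, bf_all_sequences(n, labs))
  sort(vapply(keep, paste, "", collapse = ""))
}

# admissible fixed-totals alternation sequences (optionally run-limited)
bf_alternation_sequences <- function(n, counts, max_run = Inf) {
  keep <- Filter(function(s) bf_counts_ok(s, counts) && bf_runs_ok(s, max_run),
                 bf_all_sequences(n, names(counts)))
  sort(vapply(keep, paste, "", collapse = ""))
}

# admissible randomized-block sequences
bf_rbd_sequences <- function(n_blocks, treatments) {
  t_per <- length(treatments)
  keep <- Filter(function(s) {
    blocks <- split(s, rep(seq_len(n_blocks), each = t_per))
    all(vapply(blocks, function(b) setequal(b, treatments), TRUE))
  }, bf_all_sequences(n_blocks * t_per, treatments))
  sort(vapply(keep, paste, "", collapse = ""))
}

# admissible multiple-baseline start vectors
bf_mbd_starts <- function(window, u, distinct = TRUE, min_stagger = 1) {
  g <- do.call(expand.grid, rep(list(window), u))
  keep <- apply(g, 1, function(v) {
    if (!distinct) return(TRUE)
    all(diff(sort(v)) >= min_stagger)
  })
  g <- g[keep, , drop = FALSE]
  unname(lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ])))
}

# canonical string form of a start/change vector for set comparison
vec_key <- function(v) paste(v, collapse = ";")
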