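# Test statistics: phase-mean differences, pooled alternation differences,
# per-unit multiple-baseline differences, and criterion adherence.

test_that("phase means average within maximal runs, in temporal order", {
  pm <- phase_means(sced_series(1:6), "AAABBB")
  expect_equal(pm$mean, c(2, 5))
  expect_equal(pm$label, c("A", "B"))

  const <- phase_means(sced_series(rep(7, 12)), rep(c("A", "B", "A", "B"), each = 3))
  expect_equal(const$mean, rep(7, 4))

  # the four printed phase means of the 24-occasion withdrawal example
  y <- sced_series(rep(c(29.67, 63.67, 54.33, 85.67), each = 6))
  pm4 <- phase_means(y, rep(c("A", "B", "A", "B"), each = 6))
  expect_equal(pm4$mean, c(29.67, 63.67, 54.33, 85.67))

  expect_error(phase_means(sced_series(1:5), "AAABBB"), class = "scedrand_invalid")
})

test_that("phase_mean_diff sums B-phase means minus A-phase means", {
  y <- sced_series(rep(c(29.67, 63.67, 54.33, 85.67), each = 6))
  labs <- rep(c("A", "B", "A", "B"), each = 6)
  # from the printed rounded phase means the statistic is 65.34 (the source
  # reports 65.33 from unrounded raw data, unreachable from printed inputs)
  expect_equal(phase_mean_diff(y, labs, "BA"), 65.34)
  expect_equal(phase_mean_diff(y, labs, "AB"), -65.34)
  expect_equal(phase_mean_diff(y, labs, "abs"), 65.34)

  flat <- sced_series(rep(3, 6))
  expect_equal(phase_mean_diff(flat, "AAABBB", "BA"), 0)
  expect_equal(phase_mean_diff(flat, "AAABBB", "AB"), 0)

  expect_equal(phase_mean_diff(sced_series(c(0, 0, 0, 1, 1, 1)), "AAABBB", "BA"), 1)
  expect_error(phase_mean_diff(sced_series(1:6), "AAAAAA", "BA"),
               class = "scedrand_invalid")
})

test_that("alternation_mean_diff pools occasions across runs", {
  # printed condition means 3.97 and 3.89 give the printed statistic 0.08
  y <- sced_series(c(3.97, 3.89, 3.97, 3.89, 3.97, 3.89))
  expect_equal(alternation_mean_diff(y, "ABABAB"), 0.08)
  expect_equal(alternation_mean_diff(sced_series(1:6), "AAABBB"), -3)
  expect_equal(alternation_mean_diff(sced_series(rep(2, 4)), "ABAB"), 0)
  # pooled, not per-run: AABA pools the three A occasions
  y2 <- sced_series(c(1, 3, 10, 2))
  expect_equal(alternation_mean_diff(y2, "AABA"), mean(c(1, 3, 2)) - 10)
})

test_that("mbd_mean_diff averages per-unit intervention effects", {
  # the ten printed per-unit phase means reproduce the printed 1.61
  A <- c(2.81, 2.67, 1.86, 2.85, 2.96)
  B <- c(3.59, 3.46, 3.68, 4.97, 5.50)
  dat <- sced_series(lapply(1:5, function(u) c(rep(A[u], 3), rep(B[u], 4))))
  expect_equal(mbd_mean_diff(dat, rep(4L, 5)), 1.61)

  flat <- sced_series(list(u1 = rep(2, 6), u2 = rep(5, 6)))
  expect_equal(mbd_mean_diff(flat, c(3, 4)), 0)

  # single unit reduces to the two-phase mean difference
  one <- sced_series(c(1, 2, 3, 7, 8))
  expect_equal(mbd_mean_diff(one, 4L),
               phase_mean_diff(one, "AAABB", "BA"))
  expect_error(mbd_mean_diff(one, 1L), class = "scedrand_invalid")
  expect_error(mbd_mean_diff(one, 6L), class = "scedrand_invalid")
})

test_that("ccd_mad measures mean absolute deviation from phase criteria", {
  crit <- data.frame(phase_label = c("P1", "P2"), lower = c(10, 5), upper = c(10, 5))
  expect_equal(ccd_mad(sced_series(c(11, 9, 5, 7)), 3L, crit), 1) # (1+1+0+2)/4

  # perfect adherence scores zero
  expect_equal(ccd_mad(sced_series(c(10, 10, 5, 5)), 3L, crit), 0)
  # a constant offset d from every criterion scores d
  expect_equal(ccd_mad(sced_series(c(12, 12, 7, 7)), 3L, crit), 2)

  # range-bound criteria: zero inside the range, distance to the nearer bound
  rng <- data.frame(phase_label = c("P1", "P2"), lower = c(8, 4), upper = c(12, 6))
  expect_equal(ccd_mad(sced_series(c(9, 13, 5, 3)), 3L, rng), (0 + 1 + 0 + 1) / 4)
})

test_that("the baseline criterion is the observed baseline median, held fixed", {
  d <- ccd_design(c("A", "B"), list(c(5L, 6L)),
                  criteria = data.frame(phase_label = "B", lower = 3, upper = 3),
                  n = 8, baseline_criterion = "median_of_baseline")
  y <- sced_series(c(10, 12, 14, 20, 3, 3, 3, 3))
  crit <- resolve_ccd_criteria(d, y, observed_change_points = 5L)
  expect_equal(crit$lower[1], 13) # median of the four observed baseline values
  expect_equal(crit$lower, crit$upper)
  # the same table is used for candidate change points (not recomputed)
  ref <- build_reference(y, d, observed = 5L)
  crit6 <- resolve_ccd_criteria(d, y, observed_change_points = 5L)
  expect_equal(ccd_mad(y, 6L, crit6), ref$values[[2]])

  dn <- ccd_design(c("A", "B"), list(c(5L, 6L)),
                   criteria = data.frame(phase_label = "B", lower = 3, upper = 3),
                   n = 8, baseline_criterion = "none")
  expect_error(resolve_ccd_criteria(dn, y, 5L), class = "scedrand_invalid")
})

test_that("statistic invariances hold on random inputs", {
  set.seed(5)
  for (i in 1:20) {
    y <- sced_series(rnorm(12))
    labs <- labels_from_changepoints(sort(sample(2:12, 3)), 12, c("A", "B", "A", "B"))
    ba <- phase_mean_diff(y, labs, "BA")
    expect_equal(phase_mean_diff(y, labs, "abs"), abs(ba))
    expect_equal(phase_mean_diff(y, labs, "AB"), -ba)
    # adding a constant to every measurement leaves mean differences unchanged
    y_shift <- dplyr::mutate(y, value = value + 17.3)
    expect_equal(phase_mean_diff(y_shift, labs, "BA"), ba)
    expect_equal(alternation_mean_diff(y_shift, labs),
                 alternation_mean_diff(y, labs))
  }
  # ccd_mad is NOT shift invariant in the data alone, but is when criteria
  # shift along with the measurements
  crit <- data.frame(phase_label = c("P1", "P2"), lower = c(10, 5), upper = c(10, 5))
  y <- sced_series(c(11, 9, 5, 7))
  y_shift <- dplyr::mutate(y, value = value + 3)
  crit_shift <- dplyr::mutate(crit, lower = lower + 3, upper = upper + 3)
  expect_false(isTRUE(all.equal(ccd_mad(y_shift, 3L, crit), ccd_mad(y, 3L, crit))))
  expect_equal(ccd_mad(y_shift, 3L, crit_shift), ccd_mad(y, 3L, crit))
})

test_that("mbd statistic equals the mean of per-unit two-phase differences", {
  set.seed(11)
  dat <- sced_series(lapply(1:4, function(u) rnorm(15)))
  starts <- c(4L, 7L, 9L, 12L)
  per_unit <- vapply(1:4, function(u) {
    unit_id <- unique(dat$unit)[u]
    sub <- dplyr::filter(dat, unit == unit_id)
    labs <- c(rep("A", starts[u] - 1), rep("B", 15 - starts[u] + 1))
    phase_mean_diff(sced_series(sub$value), labs, "BA")
  }, 1.0)
  expect_equal(mbd_mean_diff(dat, starts), mean(per_unit))
})
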