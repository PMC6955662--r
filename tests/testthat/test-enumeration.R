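# Counting, enumeration, and uniform sampling of admissible assignments.

test_that("phase-design counts match the closed form and brute force", {
  expect_equal(count_phase_assignments(24, 4, 3), 455)
  expect_equal(count_phase_assignments(12, 4, 3), 1)
  # brute-force composition count for (14, 4, 3) is choose(5, 3) = 10
  expect_equal(count_phase_assignments(14, 4, 3), 10)
  expect_length(bf_phase_sequences(14, c("A", "B", "A", "B"), 3), 10)
  expect_error(count_phase_assignments(11, 4, 3), class = "scedrand_invalid")
})

test_that("phase enumeration yields every admissible sequence", {
  set455 <- enumerate_assignments(fx_abab24())
  expect_equal(nrow(set455), 455)
  expect_true("AAABBBAAABBBBBBBBBBBBBBB" %in% set455$labels)
  expect_true("AAAAAABBBBBBAAAAAABBBBBB" %in% set455$labels)
  expect_false(anyDuplicated(set455$labels) > 0)

  single <- enumerate_assignments(phase_design(c("A", "B", "A", "B"), 12, 3))
  expect_identical(single$labels, "AAABBBAAABBB")

  ab10 <- enumerate_assignments(phase_design(c("A", "B"), 10, 3))
  expect_equal(nrow(ab10), 5)
  expect_setequal(vapply(ab10$change_points, identity, 1L), 4:8)
  expect_setequal(ab10$labels, bf_phase_sequences(10, c("A", "B"), 3))
})

test_that("alternation enumeration matches the printed reference set and brute force", {
  atd <- enumerate_assignments(fx_atd6())
  expect_identical(atd$labels, atd6_reference_list) # element for element, in order
  expect_equal(count_assignments(fx_atd6()), 14)

  tiny <- enumerate_assignments(atd_design(2, c(A = 1, B = 1), max_run = 1))
  expect_identical(tiny$labels, c("AB", "BA"))

  crd <- enumerate_assignments(crd_design(4, c(A = 2, B = 2)))
  expect_equal(nrow(crd), 6)
  expect_setequal(crd$labels, bf_alternation_sequences(4, c(A = 2, B = 2)))

  unres <- enumerate_assignments(crd_design(3, c(A = 0, B = 0), unrestricted = TRUE))
  expect_equal(nrow(unres), 8)
  expect_equal(count_assignments(crd_design(3, c(A = 0, B = 0), unrestricted = TRUE)), 8)

  rbd <- rbd_design(5, c("A", "B", "C"))
  expect_equal(count_assignments(rbd), 7776) # (3!)^5
  rbd2 <- enumerate_assignments(rbd_design(2, c("A", "B", "C")))
  expect_equal(nrow(rbd2), 36)
  expect_setequal(rbd2$labels, bf_rbd_sequences(2, c("A", "B", "C")))

  # totals forcing a run above the cap give an empty reference set
  infeasible <- atd_design(6, c(A = 5, B = 1), max_run = 2)
  expect_equal(count_assignments(infeasible), 0)
  expect_equal(nrow(enumerate_assignments(infeasible)), 0)
})

test_that("multiple-baseline counts and enumeration honor distinctness and stagger", {
  expect_equal(count_mbd_assignments(22, 5), 3160080)
  expect_equal(count_mbd_assignments(2, 2), 2)
  expect_equal(count_mbd_assignments(3, 2), 6)
  expect_length(bf_mbd_starts(1:3, 2), 6)
  expect_equal(count_mbd_assignments(3, 2, distinct = FALSE), 9)
  expect_error(count_mbd_assignments(4, 5), class = "scedrand_invalid")

  # window width equal to units: all permutations of the window
  perms <- enumerate_assignments(mbd_design(3, 20, c(10, 12)))
  expect_equal(nrow(perms), 6)
  expect_setequal(vapply(perms$start_points, vec_key, ""),
                  vapply(bf_mbd_starts(10:12, 3), vec_key, ""))

  stag <- enumerate_assignments(mbd_design(2, 20, c(15, 17), min_stagger = 2))
  expect_setequal(vapply(stag$start_points, vec_key, ""), c("15;17", "17;15"))
  expect_equal(count_mbd_assignments(3, 2, min_stagger = 2), 2)

  # the realized staggered start vector of the 55-day five-unit design
  big <- fx_mbd55()
  expect_equal(count_assignments(big), 3160080)
  expect_true(is_admissible(big, c(17, 19, 22, 27, 28)))
})

test_that("changing-criterion enumeration is the product of candidate lists", {
  d9 <- fx_ccd9()
  expect_equal(count_assignments(d9), 512)
  set9 <- enumerate_assignments(d9)
  expect_equal(nrow(set9), 512)
  expect_true(vec_key(c(13, 20, 27, 37, 45, 55, 65, 78, 86)) %in%
                vapply(set9$change_points, vec_key, ""))
  expect_equal(count_assignments(fx_ccd8()), 256)

  singleton <- ccd_design(c("A", "B"), list(7L),
                          criteria = data.frame(phase_label = "B",
                                                lower = 5, upper = 5),
                          n = 12)
  expect_equal(count_assignments(singleton), 1)
})

test_that("closed-form counts equal brute-force enumeration sizes across families", {
  cases <- list(
    list(d = phase_design(c("A", "B", "A"), 11, 2),
         bf = length(bf_phase_sequences(11, c("A", "B", "A"), 2))),
    list(d = atd_design(7, c(A = 4, B = 3), max_run = 3),
         bf = length(bf_alternation_sequences(7, c(A = 4, B = 3), 3))),
    list(d = crd_design(6, c(A = 2, B = 4)),
         bf = length(bf_alternation_sequences(6, c(A = 2, B = 4)))),
    list(d = rbd_design(3, c("A", "B")),
         bf = length(bf_rbd_sequences(3, c("A", "B")))),
    list(d = mbd_design(3, 12, c(4, 9), min_stagger = 2),
         bf = length(bf_mbd_starts(4:9, 3, min_stagger = 2)))
  )
  for (case in cases) {
    expect_equal(count_assignments(case$d), case$bf)
    expect_equal(nrow(enumerate_assignments(case$d)), case$bf)
  }
})

test_that("enumerated sets contain no duplicates and only admissible assignments", {
  designs <- list(fx_atd6(), phase_design(c("A", "B", "A"), 10, 2),
                  mbd_design(3, 12, c(4, 9)), fx_ccd8())
  for (d in designs) {
    set <- enumerate_assignments(d)
    vec_col <- intersect(c("start_points", "change_points"), names(set))[1]
    col <- if ("labels" %in% names(set)) set$labels else {
      vapply(set[[vec_col]], vec_key, "")
    }
    expect_false(anyDuplicated(col) > 0)
    reps <- if ("label_seq" %in% names(set)) set$label_seq else
      set[[intersect(c("start_points", "change_points"), names(set))[1]]]
    expect_true(all(vapply(reps, function(a) is_admissible(d, a), TRUE)))
  }
})

test_that("sampling is uniform over the admissible set and respects constraints", {
  d <- fx_atd6()
  draws <- sample_assignments(d, n_draws = 10000, seed = 42)
  tab <- table(factor(draws$labels, levels = atd6_reference_list))
  expect_length(tab, 14)
  # chi-square goodness of fit against the uniform distribution
  gof <- suppressWarnings(stats::chisq.test(as.integer(tab)))
  expect_gt(gof$p.value, 0.001)

  # every sampled phase assignment satisfies the minimum phase length
  pd <- phase_design(c("A", "B", "A", "B"), 20, 3)
  ps <- sample_assignments(pd, n_draws = 200, seed = 1)
  expect_true(all(vapply(ps$label_seq, function(s) all(rle(s)$lengths >= 3), TRUE)))

  # every sampled multiple-baseline start vector is pairwise distinct
  ms <- sample_assignments(fx_mbd55(), n_draws = 200, seed = 1)
  expect_true(all(vapply(ms$start_points, function(v) !anyDuplicated(v), TRUE)))

  # stagger-constrained sampling stays admissible and uniform on a tiny set
  sd2 <- mbd_design(2, 20, c(15, 17), min_stagger = 2)
  sdraws <- sample_assignments(sd2, n_draws = 2000, seed = 3)
  keys <- vapply(sdraws$start_points, vec_key, "")
  expect_setequal(unique(keys), c("15;17", "17;15"))
  expect_gt(suppressWarnings(stats::chisq.test(table(keys)))$p.value, 0.001)

  # seeded draws are reproducible and do not disturb the caller's RNG
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(sample_assignments(d, 5, seed = 7)); after <- rnorm(1)
  expect_identical(before, after)
  expect_identical(sample_assignments(d, 5, seed = 7),
                   sample_assignments(d, 5, seed = 7))
})
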