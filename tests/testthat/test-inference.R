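# Reference distributions and randomization p-values.

# minimal hand-built reference object for p-value arithmetic
make_ref <- function(values, observed, method = "exhaustive") {
  structure(
    list(values = values, observed = observed, observed_assignment = NULL,
         R = length(values), method = method,
         n_mc = if (method == "monte_carlo") length(values) else NA_integer_,
         seed = NULL, statistic = sced_statistic("phase_mean_diff_BA"),
         design = NULL),
    class = "sced_reference"
  )
}

test_that("p-values count as-or-more-extreme values, observed included", {
  ref <- make_ref(c(1, 2, 3), observed = 2)
  expect_equal(randomization_pvalue(ref, "right")$p_value, 2 / 3)
  expect_equal(randomization_pvalue(ref, "left")$p_value, 2 / 3)

  same <- make_ref(rep(4.2, 10), observed = 4.2)
  for (tail in c("right", "left", "two_sided")) {
    expect_equal(randomization_pvalue(same, tail)$p_value, 1)
  }

  # two-sided uses the absolute-value statistic, not tail doubling
  ref2 <- make_ref(c(-3, -1, 0, 1, 2), observed = -3)
  expect_equal(randomization_pvalue(ref2, "two_sided")$p_value, 1 / 5)

  # algebraically tied values within floating tolerance count as ties
  a <- sum(c(0.1, 0.2)) / 2
  b <- 0.15
  ref3 <- make_ref(c(a, 1), observed = b)
  expect_equal(randomization_pvalue(ref3, "left")$p_value, 1 / 2)
})

test_that("exhaustive reference distributions cover every admissible assignment", {
  d <- fx_abab24()
  y <- sced_series(rep(c(0, 1, 0, 1), each = 6))
  ref <- build_reference(y, d, observed = c(7, 13, 19))
  expect_equal(length(ref$values), 455)
  expect_equal(ref$R, 455)
  expect_equal(ref$observed, 2)
  # the observed value is a member of the reference multiset
  expect_true(any(abs(ref$values - ref$observed) < 1e-12))

  # single admissible assignment: the reference set is just the observed
  d1 <- phase_design(c("A", "B", "A", "B"), 12, 3)
  y1 <- sced_series(rnorm(12))
  ref1 <- build_reference(y1, d1, observed = c(4, 7, 10))
  expect_equal(length(ref1$values), 1)
  expect_equal(randomization_pvalue(ref1, "right")$p_value, 1)

  expect_error(build_reference(y, d, observed = c(2, 13, 19)),
               class = "scedrand_invalid") # phase 1 shorter than the minimum
})

test_that("Monte Carlo references include the observed and are seed-reproducible", {
  d <- fx_mbd55()
  obs <- c(17, 19, 22, 27, 28)
  y <- generate_series(d, obs, effect_model(mu = 3, delta = 1, sd = 1), seed = 2)
  r1 <- build_reference(y, d, obs, method = "monte_carlo", n_mc = 500, seed = 9)
  r2 <- build_reference(y, d, obs, method = "monte_carlo", n_mc = 500, seed = 9)
  expect_identical(r1$values, r2$values)
  expect_equal(length(r1$values), 500)
  expect_equal(r1$values[500], r1$observed) # observed forced into the sample
  expect_gte(randomization_pvalue(r1, "right")$p_value, 1 / 500)

  # the cap forces Monte Carlo under method = "auto"
  auto <- build_reference(y, d, obs, method = "auto", n_mc = 200, seed = 1,
                          exhaustive_cap = 1000)
  expect_equal(auto$method, "monte_carlo")
  expect_error(build_reference(y, d, obs, method = "exhaustive",
                               exhaustive_cap = 1000),
               class = "scedrand_invalid")
})

test_that("fast reference evaluators agree with the exported statistics", {
  set.seed(21)
  # phase design
  pd <- phase_design(c("A", "B", "A", "B"), 16, 3)
  yp <- sced_series(rnorm(16))
  refp <- build_reference(yp, pd, observed = c(4, 8, 12))
  setp <- enumerate_assignments(pd)
  direct <- vapply(setp$label_seq, function(l) phase_mean_diff(yp, l, "BA"), 1.0)
  expect_equal(refp$values, direct)

  # alternation design
  ad <- atd_design(8, c(A = 4, B = 4), max_run = 2)
  ya <- sced_series(rnorm(8))
  obs_a <- enumerate_assignments(ad)$label_seq[[1]]
  refa <- build_reference(ya, ad, obs_a)
  directa <- vapply(enumerate_assignments(ad)$label_seq,
                    function(l) alternation_mean_diff(ya, l), 1.0)
  expect_equal(refa$values, directa)

  # multiple baseline
  md <- mbd_design(3, 15, c(5, 11))
  ym <- generate_series(md, c(5, 8, 11), effect_model(delta = 1), seed = 3)
  refm <- build_reference(ym, md, c(5, 8, 11))
  directm <- vapply(enumerate_assignments(md)$start_points,
                    function(s) mbd_mean_diff(ym, s), 1.0)
  expect_equal(refm$values, directm)

  # changing criterion
  cd <- fx_ccd8()
  obs_c <- c(13, 20, 27, 37, 45, 55, 65, 78)
  yc <- generate_ccd_series(cd, obs_c, effect_model(ccd_adherence_sd = 2), seed = 4)
  refc <- build_reference(yc, cd, obs_c)
  critc <- resolve_ccd_criteria(cd, yc, obs_c)
  directc <- vapply(enumerate_assignments(cd)$change_points,
                    function(cp) ccd_mad(yc, cp, critc), 1.0)
  expect_equal(refc$values, directc)
})

test_that("negating all values swaps the right and left tails", {
  set.seed(31)
  for (i in 1:10) {
    vals <- rnorm(50)
    obs <- sample(vals, 1)
    ref <- make_ref(vals, obs)
    neg <- make_ref(-vals, -obs)
    expect_equal(randomization_pvalue(ref, "right")$p_value,
                 randomization_pvalue(neg, "left")$p_value)
  }
})

test_that("exhaustive and Monte Carlo p-values agree on the 455-assignment design", {
  d <- fx_abab24()
  obs <- c(7, 13, 19)
  y <- generate_series(d, obs, effect_model(mu = 0, delta = 1.5, sd = 1), seed = 6)
  p_ex <- sced_test(y, d, obs, method = "exhaustive")$p_value
  p_mc <- sced_test(y, d, obs, method = "monte_carlo", n_mc = 1000, seed = 8)$p_value
  se <- sqrt(p_ex * (1 - p_ex) / 1000)
  expect_lt(abs(p_mc - p_ex), 3 * se + 1 / 1000)
})

test_that("test objects tidy, glance, and plot", {
  d <- phase_design(c("A", "B"), 10, 3)
  y <- sced_series(c(0, 0, 0, 0, 1, 1, 1, 1, 1, 1))
  t <- sced_test(y, d, observed = 5L)
  td <- tidy(t)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$p_value, 1 / 5)
  expect_true(td$reject == (td$p_value <= 0.05))
  gl <- glance(t)
  expect_equal(gl$R, 5)
  expect_equal(gl$minimal_p, 0.2)
  expect_s3_class(autoplot(t), "ggplot")
  ref <- attr(t, "reference")
  expect_s3_class(tidy(ref), "tbl_df")
  expect_equal(nrow(tidy(ref)), 5)
  expect_output(print(t), "Randomization test")
})
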