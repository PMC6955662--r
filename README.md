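# scedrand

Randomization designs and randomization tests for single-case experiments.

## The scientific problem

In a single-case experimental design (SCED) one unit — a person, a
classroom, a clinic — is measured repeatedly, and the experimenter controls
*when* conditions change rather than *who* receives which condition. If the
schedule of condition changes is randomized from an explicit set of
admissible assignments, the experiment supports a **randomization test**:
the observed test statistic is compared against the statistics that would
have been obtained under every other admissible assignment, and the p-value
is the proportion of reference statistics at least as extreme as the
observed one (the observed assignment always counts, so `p >= 1/R` where
`R` is the size of the reference set). The test's validity rests only on
the randomization actually performed — no normality, independence, or
random-sampling assumptions.

`scedrand` implements this machinery for four common SCED families:

| Family | Randomized quantity | Example constraint |
|---|---|---|
| Phase (ABAB, ...) | phase-change occasions | at least *m* measurements per phase |
| Alternation (CRD / ATD / RBD) | condition of each occasion | fixed totals, maximal run length, blocks |
| Multiple baseline | per-unit intervention start occasions | distinct starts in a window, minimum stagger |
| Changing criterion | phase-boundary occasions | one candidate list per boundary |

For each family the package provides exact counting
(`count_assignments()`), full enumeration (`enumerate_assignments()`),
exact-uniform sampling (`sample_assignments()`), test statistics
(summed/pooled mean differences and a criterion-adherence measure),
exhaustive or Monte Carlo inference (`sced_test()`), simulation-based power
analysis (`estimate_power()`), and a synthetic-data generator with level
shift, phase-restarting trend, and stationary AR(1) errors
(`generate_series()`).

Statistics, in standard notation, for a series `y_1, ..., y_n`:

- **Phase designs:** `T = sum over B phases of mean(y in phase) - sum over
  A phases of mean(y in phase)`, each maximal run of a label being one
  phase.
- **Alternation designs:** `T = mean(y on A occasions) - mean(y on B
  occasions)`, pooled across runs.
- **Multiple baseline:** `T = (1/u) * sum over units of (mean(y after
  start) - mean(y before start))`.
- **Changing criterion:** `T = (1/n) * sum |y_t - c(t)|`, where `c(t)` is
  the phase criterion (distance to the nearer bound for range criteria);
  smaller is better, so the test is left-tailed.

## Worked example

An ABAB withdrawal design over 24 occasions with at least three
measurements per phase admits 455 assignments of the three phase-change
points:

```r
library(scedrand)

design <- phase_design(c("A", "B", "A", "B"), n = 24, min_phase_length = 3)
count_assignments(design)
#> [1] 455
```

Simulate a series under the realized assignment (phases change at
occasions 7, 13, and 19) with a treatment effect of 25 points:

```r
y <- generate_series(design, assignment = c(7, 13, 19),
                     model = effect_model(mu = 30, delta = 25, sd = 8),
                     seed = 42)
y
#> # A tibble: 24 × 3
#>    unit  occasion value
#>    <chr>    <int> <dbl>
#>  1 unit1        1  41.0
#>  2 unit1        2  25.5
#>  3 unit1        3  32.9
#>  4 unit1        4  35.1
#>  5 unit1        5  33.2
#>  6 unit1        6  29.2
#>  7 unit1        7  67.1
#>  8 unit1        8  54.2
#>  9 unit1        9  71.1
#> 10 unit1       10  54.5
#> # ℹ 14 more rows
```

Run the exhaustive randomization test with the B-minus-A phase-mean
statistic:

```r
test <- sced_test(y, design, observed = c(7, 13, 19),
                  statistic = "phase_mean_diff_BA", tail = "right",
                  method = "exhaustive")
test
#> Randomization test
#>   statistic: phase_mean_diff_BA = 59.07
#>   reference: exhaustive, R = 455
#>   p-value (right tail): 0.004
#>   decision at alpha = 0.05: reject the null hypothesis of no treatment effect

tidy(test)
#> # A tibble: 1 × 8
#>   statistic          observed p_value tail      R method     alpha reject
#>   <chr>                 <dbl>   <dbl> <chr> <dbl> <chr>      <dbl> <lgl>
#> 1 phase_mean_diff_BA     59.1 0.00440 right   455 exhaustive  0.05 TRUE
```

Only 2 of the 455 reference statistics reach the observed value, so
`p = 2/455 ≈ 0.004`. `autoplot(test)` draws the reference distribution with
the observed statistic marked.

Power for a smaller standardized effect (`delta/sd = 1`):

```r
estimate_power(design, effect_model(delta = 1, sd = 1),
               statistic = "phase_mean_diff_BA",
               alpha = 0.05, n_sims = 200, seed = 7)
#> Randomization-test power estimate
#>   design: phase, R = 455; statistic: phase_mean_diff_BA (right tail)
#>   effect: delta = 1, sd = 1, ar1 = 0
#>   power = 0.46 (92/200 rejections at alpha = 0.05, MC se 0.0352)
```

A design whose reference set has fewer than 20 assignments cannot reject at
`alpha = 0.05` at all (the minimal attainable p-value `1/R` already exceeds
alpha); `estimate_power()` detects this and returns exactly zero power
without simulating.

A small command-line front end is installed at `inst/cli/sced`
(subcommands `enumerate`, `stat`, `test`, `power`, `simulate`), reading
series from CSV and writing JSON results.

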