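Package: scedrand
Title: Randomization Designs and Randomization Tests for Single-Case Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing randomized single-case
    experimental designs (SCEDs, also known as N-of-1 trials). Supports four
    design families - phase designs (e.g., ABAB withdrawal), alternation
    designs (completely randomized, alternating treatments, randomized
    block), multiple baseline designs with staggered intervention starts,
    and changing criterion designs. For each family the package counts,
    exhaustively enumerates, or uniformly samples the admissible treatment
    assignments, computes level-based test statistics (phase-mean
    differences, pooled condition-mean differences, mean absolute deviation
    from criteria), derives exact or Monte Carlo randomization p-values,
    and estimates statistical power by simulation. A synthetic-data
    generator produces series with configurable level shift, trend, noise,
    and lag-1 autocorrelation for design planning and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
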