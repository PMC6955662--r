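---
title: "Randomization tests for single-case experimental designs: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Randomization tests for single-case experimental designs: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scedrand)
```

## The model and the procedure

A single-case experiment measures one unit (or a small set of units)
repeatedly over `n` occasions; the experimenter randomizes the *schedule* of
condition changes rather than the allocation of subjects. Let `Omega` be the
set of admissible assignments fixed before the experiment, and let the
realized assignment be drawn uniformly from `Omega`. Under the sharp null
hypothesis of no treatment effect, the observed measurements `y` are fixed
and every assignment in `Omega` was equally likely to have produced the
observed pairing of measurements with conditions. The randomization test
therefore:

1. computes the test statistic `T(y, a*)` under the realized assignment
   `a*`;
2. recomputes `T(y, a)` for every `a` in `Omega` (or a Monte Carlo sample
   of it);
3. reports `p = #\{a : T(y, a) at least as extreme as T(y, a*)\} / R`,
   where `R = |Omega|`.

The observed assignment is always a member of the reference set, so the
count in step 3 is at least 1 and `p >= 1/R`. This is the standard
guarantee that makes the test exactly valid at any level `alpha`:
`P(p <= alpha) <= alpha` under the null, with no assumptions about the
error distribution, independence, or sampling of units. The package uses
the observed-inclusive "as or more extreme" rule throughout; a rule that
counted only strictly more extreme statistics, or that excluded the
observed assignment, would not be valid.

Two direct consequences drive the power analysis in `estimate_power()`:

- the minimal attainable p-value is `1/R` (`minimal_pvalue()`), and
- if `1/R > alpha` the test can never reject, so power is exactly zero.
  With `alpha = 0.05` this means any design with fewer than 20 admissible
  assignments is uninformative; `has_nonzero_power()` checks this and
  `estimate_power()` returns an analytic zero without simulating.

Ties are compared with a relative tolerance of `1e-9` (scaled by the larger
magnitude, with a floor at 1), so that statistics that are equal up to
floating-point noise — common with integer-valued data — are counted as
ties rather than split arbitrarily by rounding direction.

## The four randomization schemes and their counts

**Phase designs** (`phase_design()`). A fixed pattern of phases, e.g.
ABAB, over `n` occasions; the randomized quantities are the `k - 1` phase
change points, subject to each phase containing at least `m` measurements.
The admissible assignments are the compositions of `n` into `k` parts each
at least `m`, counted by the stars-and-bars formula

    R = choose(n - k*m + k - 1, k - 1).

For ABAB with `n = 24`, `m = 3` this gives `choose(15, 3) = 455`.
Enumeration and exact-uniform sampling both use the bijection between such
compositions and `(k-1)`-subsets of `n - k*m + k - 1` positions, so
sampling is constructive (no rejection).

**Alternation designs.** Here each occasion individually receives a
condition. Three variants:

- `crd_design()`: completely randomized with *fixed per-condition totals*
  (the default), `R = n! / (n_A! n_B! ...)`; an `unrestricted` option
  gives the `2^n` coin-flip scheme. Fixed totals are the package default
  because they guarantee every condition is observed and match how such
  experiments are usually scheduled; the unrestricted scheme is retained as
  an explicit option since both appear in practice and the choice changes
  `R`.
- `atd_design()`: alternating treatments with a maximal run length cap
  (default 2). No closed form exists under a run cap, so
  `count_assignments()` uses a memoized dynamic program over (remaining
  counts, last condition, current run length); `n = 6`, three per
  condition, max run 2 gives the familiar 14 sequences. Sampling is by
  rejection from the fixed-totals scheme, exact because acceptance is
  uniform over the admissible subset.
- `rbd_design()`: randomized blocks, an independent permutation of the `t`
  treatments within each of `b` blocks, `R = (t!)^b`.

**Multiple baseline designs** (`mbd_design()`). `u` units each switch from
baseline to intervention at a start occasion drawn from a common window of
`W` candidate days; starts must be pairwise distinct (and the unit order is
part of the assignment), giving `R = W! / (W - u)!`. Five units over a
22-day window give `22 * 21 * 20 * 19 * 18 = 3,160,080`. A generalization
enforces a minimum stagger `s` between consecutive (sorted) starts; the
count follows from the standard gap bijection,
`R = u! * choose(W - (u - 1)(s - 1), u)`, which reduces to the distinct
count at `s = 1`. Sampling uses the same bijection constructively: draw a
uniform `u`-subset of the shrunken window, re-inflate the gaps, then
permute units.

**Changing criterion designs** (`ccd_design()`). The phase sequence and
criterion schedule are fixed; each of the `k - 1` phase boundaries is
randomized within a small candidate list, so `R` is the product of the list
lengths. Two adjacent candidates per boundary give `2^9 = 512` assignments
for a ten-phase design and `2^8 = 256` for a nine-phase one. This
multiplicative structure is what makes the family testable at all: the
per-boundary lists are tiny, but their product clears the 20-assignment
floor quickly.

Counts are validated two ways in the test suite: every closed form or DP is
checked against an independent brute-force filter over the unconstrained
superset (e.g. all `label^n` sequences, all `W^u` start tuples), and
`enumerate_assignments()` defensively cross-checks its own row count
against `count_assignments()` at run time.

## Test statistics

All statistics target the *level* aspect of the effect — differences in
means — which is the aspect the generator manipulates and the one most
designs are powered for:

- **Phase designs:** the sum of B-phase means minus the sum of A-phase
  means, each maximal run of a label forming one phase (directions `BA`,
  `AB`, and `abs` are provided). Summing rather than averaging phase means
  follows the convention for withdrawal designs; it only rescales the
  statistic and leaves the p-value unchanged for balanced patterns.
- **Alternation designs:** the difference of *pooled* condition means
  (all A occasions vs all B occasions), not a mean of per-run means.
- **Multiple baseline:** the mean over units of (post-start mean minus
  pre-start mean).
- **Changing criterion:** the mean absolute deviation of each measurement
  from its phase criterion, with range criteria scored as the distance to
  the nearer bound (zero inside the range). Smaller means better adherence,
  so the test is left-tailed.

Monte Carlo references draw `n_mc - 1` assignments uniformly *with
replacement* and append the observed assignment, so the denominator is
`n_mc` and the validity guarantee is preserved exactly (this is the
standard Monte Carlo randomization-test construction; sampling without
replacement would require enumerating `Omega` anyway).

### The changing-criterion baseline

The baseline phase of a changing-criterion design has no experimenter-set
criterion. The package's convention (`baseline_criterion =
"median_of_baseline"`) scores baseline adherence against the median of the
*realized* baseline observations, computed once and held fixed across all
reference assignments. Recomputing the median separately for each candidate
assignment would make the criterion schedule itself depend on the
assignment, changing the hypothesis being tested; holding it fixed keeps
the reference statistics comparable and the test interpretable as "how
unusual is the observed adherence, given this fixed schedule". Alternatives
(`"fixed"` with a user value, or `"none"` to require a full user-supplied
criterion table) are available.

## The synthetic-data generator

`generate_series()` produces series from the model

    y_t = mu + delta * 1[occasion t is under treatment]
             + trend * (position of t within its phase - 1)
             + e_t,

where the trend restarts at every phase change and `e_t` follows a
stationary AR(1) process with lag-1 correlation `phi` and *marginal*
standard deviation `sd` (the innovation standard deviation is
`sd * sqrt(1 - phi^2)`, so changing `phi` does not change the marginal
noise scale — this keeps `delta / sd` interpretable as a standardized
effect size across autocorrelation settings). Noise is Gaussian only: the
randomization test itself is distribution-free, so the generator's role is
to provide a controlled, interpretable effect-size scale for power studies
rather than to model any particular outcome distribution. `delta` may be a
single B-shift or a named per-condition vector for multi-condition designs.
Changing-criterion series are generated separately
(`generate_ccd_series()`): measurements track the phase criterion midpoint
with Gaussian adherence noise.

`estimate_power()` redraws the true assignment uniformly from `Omega` in
every replicate — matching how the experiment would actually be randomized
— generates a series, runs the full test, and reports the rejection rate
with a binomial Monte Carlo standard error. The reference set is enumerated
once and reused across replicates when exhaustive inference is feasible.

Problem sizes used for the package's own simulation checks were chosen for
statistical resolution within a modest runtime: 2000 replicates for
null-validity and effect-recovery checks (binomial standard error about
0.005 at `alpha = 0.05`), 500 for distributional checks of the adherence
statistic, and an ABAB design with `n = 15`, minimum phase length 3
(`R = 20`, the smallest phase design with nonzero power at 0.05) for the
exact-validity check so the exhaustive test stays cheap inside the
simulation loop.

## Limitations

- Statistics address the level aspect only; trend, variability, overlap
  (e.g. NAP, Tau-U), and immediacy measures are out of scope.
- No confidence intervals by test inversion; the package reports p-values
  and power.
- The multiple-baseline scheme randomizes start *times* for a fixed
  unit-to-tier order; designs that also randomize the order of units across
  tiers can be expressed since permutations of units are distinct
  assignments, but unit-specific start windows are not supported.
- The generator's noise is Gaussian AR(1); heavier-tailed or count-valued
  outcomes must be supplied as user data (the inference functions accept
  any numeric series).
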