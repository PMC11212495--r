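---
title: "Methods: lifetime risk of maternal near miss, death and severe outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifetime risk of maternal near miss, death and severe outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltrmnm)
```

## The measure

A maternal near miss (MNM) is a woman who nearly died but survived a
complication of pregnancy, childbirth or the 42 days after termination of
pregnancy (WHO organ-dysfunction criteria).  Prevalence measures — the MNM
ratio (events per 1000 live births) or MNM rate (events per 1000
woman-years) — describe the risk attached to a single pregnancy or year.
They do not answer the question advocates and health planners actually ask:
*what is the chance that a girl who reaches age 15 will experience a
life-threatening maternal complication at some point in her reproductive
life?*  That cumulative probability depends on three things at once: the
per-birth risk, how many births a woman has (fertility), and whether she
survives through the reproductive ages at all (background mortality).

This package computes that cumulative measure — the lifetime risk of
maternal near miss (LTR-MNM) — together with its mortality analogue
(LTR-MD) and their union, the lifetime risk of severe maternal outcome
(LTR-SMO).  All three are synthetic-cohort period measures: the rates of a
single year are treated as if a cohort lived through them.

## Estimators

With five-year age groups indexed by start age $x$ and width $n = 5$, the
age-disaggregated estimator is

$$\mathrm{LTR} \;=\; \sum_{x=15}^{45} \mathrm{Ratio}_{x,n}\;
  f_{x,n}\; \frac{L_{x,n}}{l_{15}},$$

where $\mathrm{Ratio}_{x,n}$ is the per-birth event ratio, $f_{x,n}$ the
age-specific fertility rate per woman-year, $L_{x,n}$ the person-years
lived in $[x, x+n)$ from an abridged female life table, and $l_{15}$ the
survivors at exact age 15.  `ltr_age_specific()` implements this;
`ltr_from_rate()` is the equivalent form $\sum \mathrm{Rate}_{x,n}
L_{x,n}/l_{15}$ for event rates per woman-year.  The factor
$L_{x,n}/l_{15}$ (`survival_weights()`) is the expected number of years a
girl who reaches 15 lives in each interval, which is how competing
all-cause mortality enters.

When only an aggregate ratio for ages 15–49 is available, assuming a
constant per-birth risk gives

$$\mathrm{LTR} \;=\; {}_{35}\mathrm{Ratio}_{15}
  \sum_x f_{x,n}\frac{L_{x,n}}{l_{15}}
  \;=\; {}_{35}\mathrm{Ratio}_{15}\cdot \mathrm{NRR}\cdot
  \left(\frac{\mathrm{SRB}}{100}+1\right)\cdot\frac{l_0}{l_{15}},$$

because the net reproduction rate satisfies $\mathrm{NRR} = \sum f_{x,n}
(L_{x,n}/l_0)\,100/(100+\mathrm{SRB})$ for an age-constant sex ratio at
birth.  `ltr_summary()` implements the middle form, `ltr_summary_nrr()`
the right-hand shortcut, and the equality is exercised as a property test
(relative agreement $10^{-9}$ over 500 synthetic bundles).  The shortcut
matters in practice because NRR, SRB and $l_0/l_{15}$ are routinely
published even where full schedules are awkward to assemble.

The severe-outcome risk is plain addition, `ltr_smo()`:
$\mathrm{LTR_{SMO}} = \mathrm{LTR_{MD}} + \mathrm{LTR_{MNM}}$.  No
competing-risk correction is applied between the two component events —
the measure is a population average, and a correction would require
parity- and history-specific risks that surveillance data do not provide.
`one_in_n()` renders any of these risks in the conventional "1 in $n$"
form using nearest-integer rounding of the reciprocal, the only rule
consistent with all published renderings we reproduce (0.0263 → 38,
0.0282 → 35, 0.0333 → 30, 0.00702 → 142).

## Inputs, units and containers

The three containers are validated tibbles, so they compose with dplyr:

* `life_table()` — `age_start`, `age_interval`, `lx`, `Lx`, radix $l_0$
  (default 100 000).  Invariants: $l_x$ non-increasing, $0 \le l_x \le
  l_0$, and $n\,l_{x+n} \le L_{x,n} \le n\,l_x$.  `lx` may be `NA` where a
  source does not report it (published worked examples often print only
  $l_{15}$); checks apply wherever the needed pins exist.
* `fertility_schedule()` — `asfr`, accepted `per_woman` or `per_1000`.
* `morbidity_schedule()` — `cases`, `live_births` and/or `ratio`, accepted
  `per_birth`, `per_1000` or `per_100000`; an `event` label (`mnm`,
  `maternal_death`, `smo`) distinguishes uses without changing structure.

Every rate and ratio is normalised to a pure proportion exactly once, at
construction; downstream code never rescales.  Grid alignment between
schedules is strict equality of `(age_start, age_interval)` pairs — no
silent re-binning, since re-aggregation would corrupt the age-specific
route.  A computed risk $\ge 1$ is rejected with an explicit error: it can
only arise from a unit mistake (e.g. a per-1000 ratio passed as a
proportion), and returning it would be worse than stopping.

When both counts and a ratio column are supplied they are cross-checked
with a tolerance of 5% relative plus half an event per denominator.  The
allowance is deliberate: published tables round both counts and ratios,
and generated schedules carry exact calibrated ratios next to apportioned
integer counts, so exact equality is the wrong invariant.

## The Namibia 2019 fixture

`load_fixture("namibia2019")` ships the fully printed worked example: a
simulated J-shaped MNM schedule (546 cases over 68 001 live births,
aggregate ratio 8.03 per 1000), the World Population Prospects fertility
and person-years columns with $l_{15} = 95\,283$, and the published
scalars NRR 1.554, SRB 101, stillbirth rate 17.68 per 1000 total births
and maternal mortality ratio 223 per 100 000.  Two published numbers are
treated as inputs rather than recomputed targets, because their unrounded
sources are not recoverable from the printed table:

* the published NRR of 1.554 derives from unrounded schedules; the same
  sum over the *printed* (rounded) columns gives 1.558, which is what
  `nrr_from_schedules()` returns and what the tests assert against an
  independent spreadsheet-style oracle;
* the published LTR-MD of 0.00702 ("1 in 142") cannot be reproduced from
  the printed mortality ratio of 223 per 100 000 (that recomputation gives
  ≈ 0.0073), so the fixture carries 0.00702 as `ltr_md_published` and the
  severe-outcome check uses it as the printed component it is.

The fixture's ratio column is the printed one; in four rows it differs in
the second decimal from `cases/live_births` of the printed counts (again a
rounding artefact of the source table).  The printed ratios are
authoritative for the age-specific route, which is why the fixture stores
both columns and why the consistency check has the tolerance above.

## Simulated age patterns

Age-disaggregated MNM data are rare, so the package can generate plausible
age distributions of the ratio constrained to an observed aggregate level.
A `shape_family()` is seven positive relative-risk multipliers; six named
families are provided (`j_shape`, `u_shape`, `n_shape`, `constant`,
`increasing`, `decreasing`), each with an enforced qualitative invariant —
the J shape, for instance, must be elevated at 15–19, minimal at 20–24 and
strictly increasing thereafter, the profile the clinical literature
considers most plausible for near miss as for maternal death.

`ratios_from_shape()` calibrates the profile with a single scalar so the
births-weighted mean ratio equals the target exactly, then allocates the
implied integer case total by largest-remainder apportionment with ties
broken toward the youngest group — deterministic and total-conserving, so
a generated schedule's aggregate never drifts more than half an event from
the target.  The default multiplier vectors are fixed, documented choices
(e.g. J: 1.5, 0.8, 1.0, 1.9, 2.1, 2.6, 3.1); the qualitative shapes are
all the evidence supports, and these defaults were chosen once so that the
two anchors that can be checked against the worked example — the constant
pattern ("1 in 38") and the J pattern ("1 in 35") — are reproduced, with
all six families landing in the narrow 1-in-35 to 1-in-40 band.
`sensitivity_sweep()` tabulates all families at once; its message is that
the lifetime risk is fairly insensitive to the assumed age pattern when
the aggregate is held fixed, which is what licenses the summary shortcut.

`stillbirth_adjust()` converts total births to live births as
`births × (1 − SBR/1000)` (SBR is defined per 1000 *total* births; this
direction reproduces the fixture's 68 001 live births from ≈ 69 225 total),
rounding half-up per group.

### The synthetic bundle generator

`make_synthetic_bundle()` is the package's fixture engine for property
tests: it builds a life table (trapezoidal person-years over a mildly
increasing, jittered adult hazard), a fertility schedule (a broad
mid-peaked shape scaled to a target total fertility rate), and a morbidity
schedule via the shape machinery, all mutually consistent (the bundle's
NRR is recomputed from its own schedules).  Defaults emulate a
middle-income setting: total fertility 3.3, survival to 15 around 97%,
roughly 5% mortality across the reproductive ages at `mortality_level = 1`,
SRB 103, an aggregate near miss ratio of 8 per 1000 and 10 000 women per
age group.  All randomness flows from the single `seed` argument.

What the generator does *not* emulate: real fertility and mortality age
patterns in their full variety, correlation between fertility and
morbidity levels, heterogeneity between women (parity-specific or
history-dependent risk), or reporting error in surveillance counts.
Passing property tests on these bundles therefore demonstrates the
estimators' algebraic behaviour (equivalences, linearity, monotonicity,
conservation) on well-formed inputs — not that any substantive conclusion
transfers to a particular real population.

## Adjustments and uncertainty

`facility_adjust()` converts a facility-based ratio to a population-level
one by multiplying by the institutional delivery rate: the numerator of a
facility ratio is taken as complete (a woman with a true near miss would
not survive outside facility care) while the live-birth denominator misses
home births, so only the denominator needs inflating.  Below an
institutional delivery rate of 0.5 the function still computes but warns:
with mostly home births — especially with tertiary-only data — the
completeness assumption is doubtful and the adjusted ratio is best read as
an upper bound.

For sampling uncertainty, per-group counts are modelled as independent
Poisson observations.  Group counts can be single digits (the fixture has
11 cases at 45–49), so the frequentist interval is the exact Poisson
(Garwood) interval via gamma quantiles rather than a normal approximation;
`ratio_interval(0, n)` correctly returns a lower bound of exactly 0.
`ltr_interval()` propagates to the risk scale two ways:

* **summary route**: every estimator is linear and increasing in the
  aggregate ratio, so pushing the two interval endpoints through
  `ltr_summary()` is exact, no simulation needed;
* **age-specific route**: Monte Carlo over the seven independent counts
  (parametric bootstrap for `method = "poisson"`, a Jeffreys
  Gamma(count + ½) posterior for `method = "gamma"`), with percentile
  extraction.  `level = 0.8, method = "gamma"` yields the
  10th/90th-percentile "80% uncertainty interval" convention.  The
  default 10 000 draws give percentile noise well below the two
  significant figures at which such intervals are reported; a seeded run
  is bit-reproducible.

The Gamma-posterior option is a percentile-reporting convention, not a
claim of full Bayesian inference from surveillance microdata.  The
independence assumption across age groups — and the unmodelled clustering
of repeat near misses within women — are acknowledged limitations; the
result remains a population average.

## Numerical conventions and degenerate inputs

* Internal values are never rounded; display rounding (4 d.p. for risks,
  2 d.p. for ratios and weights) happens only at presentation, and the
  "1 in n" reciprocal uses half-up rounding.
* Internal consistency checks use a relative tolerance of $10^{-9}$;
  comparisons against published values use the published precision.
* Zero morbidity yields a risk of exactly 0 (and "1 in n" refuses it, as
  the reciprocal is undefined); $l_{15} = 0$, negative rates, misaligned
  grids and out-of-range scalars are distinct, named error classes
  (`ltrmnm_error_input`, `ltrmnm_error_grid`, `ltrmnm_error_usage`,
  `ltrmnm_error_domain`).

## Problem sizes in the checks

The test suite exercises the algebraic properties at sizes chosen to keep
the whole suite under a minute while leaving Monte Carlo noise far below
the asserted tolerances: 500 synthetic bundles for the summary/NRR
equivalence, 1000 seeded replicates for the 95%-interval coverage check
(asserted ≥ 93%, the binomial slack at 1000 replicates), 10 000 draws for
age-specific intervals, and 100 random schedules for the rate/ratio
identity.

## Worked example

```{r example}
b <- load_fixture("namibia2019")

ltr <- ltr_age_specific(b$morbidity, b$fertility, b$life_table)
glance(ltr)
tidy(ltr)

s <- summary_inputs(8.03, nrr = b$nrr, srb = b$srb,
                    l0 = lt_radix(b$life_table),
                    l15 = survivors_at(b$life_table, 15),
                    units = "per_1000")
glance(ltr_summary_nrr(s))

sensitivity_sweep(b$morbidity, b$fertility, b$life_table,
                  target_aggregate = 8.03)

tidy(ltr_interval(b$morbidity, b$fertility, b$life_table,
                  route = "summary"))
```
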