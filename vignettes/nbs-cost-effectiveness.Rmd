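---
title: "Modelling newborn-screening cost-effectiveness with nbscea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling newborn-screening cost-effectiveness with nbscea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbscea)
```

## The modelling problem

Adding a condition such as spinal muscular atrophy (SMA) or severe combined
immunodeficiency (SCID) to a newborn bloodspot screening panel trades a small
per-test cost, paid for every newborn, against large per-case differences in
treatment cost and outcome for the handful of affected babies: early
(pre-symptomatic) treatment — one-off gene therapy for SMA, early
hematopoietic stem cell transplant (HSCT) for SCID — against late treatment
after clinical presentation — recurring nusinersen therapy, late HSCT. The
natural evaluation design is a decision tree whose chance branches carry the
condition incidences, nested with a Markov cohort model per treatment arm,
evaluated from a government payer perspective over both a short (5-year) and
a long (60-year) horizon with 3% annual discounting. `nbscea` implements that
design as a small set of composable pieces: `markov_model()` /
`run_cohort()`, `decision_tree()` / `expected_values()` / `incremental()`,
`run_psa()`, `tornado()`, and the budget-impact functions.

## The cohort engine and its conventions

A `markov_model` is an ordered list of health states (per-*year* utility
weight and running cost, absorbing and death flags), a constant per-cycle
transition matrix, a cycle length in years, an initial distribution, and
one-off costs attached to event times in years. Several conventions deserve
explicit statement, because published evaluations rarely state them and they
change results at the margin:

* **Annual specification, cycle scaling.** Utilities and costs are specified
  per year and multiplied by the cycle length internally. The SMA models use
  6-month cycles and the SCID models 3-month cycles; annual specification
  keeps their configurations directly comparable.
* **Beginning-of-cycle accrual, no half-cycle correction.** State membership
  at the start of a cycle earns that cycle's utility and cost. This is the
  default of the mainstream decision-tree software this class of evaluation
  is usually built in. A `half_cycle_correction` flag implements the
  start/end-averaged variant, but it is off in every shipped fixture and
  result.
* **Continuous discounting.** Discount factors use exact fractional-year
  exponents, `(1+r)^(-t)` with `t` in years, so a 6-month cycle at 3% p.a.
  discounts by `1.03^-0.5` rather than by annual steps. With mixed cycle
  lengths in one tree this is the only convention in which two models agree
  on what "year 1" is worth.
* **One-off costs charge the survivors.** A gene-therapy infusion at entry or
  an HSCT at six months is a per-patient event: the amount is multiplied by
  the fraction of the cohort alive (non-death occupancy) at the last cycle
  boundary at or before the event time, and discounted at the event time.
  Events at or beyond the horizon are not charged.
* **Calendar-year aggregation.** Undiscounted costs are also binned by
  `floor(t)` into calendar years — the exact input shape of a budget-impact
  "Year 1 … Year 5" table.
* **Time-homogeneity is structural.** The transition matrix is constant over
  the whole process (the standard assumption when only short-term clinical
  data exist); the configuration schema has no time-varying form, so a
  time-varying model cannot be expressed by accident.

The engine is deterministic. Its correctness is checked two independent
ways in the test suite: closed forms (annuity-due for a never-dying state,
geometric series for constant-hazard survival, both to 1e-9) and a
microsimulation oracle (`brute_force_oracle()`) that samples individual
state paths and must agree with the cohort result within three standard
errors.

## The decision tree and zero-outcome branches

Per-newborn expected values are the incidence-weighted mixture of branch
outcomes plus the per-person screening cost charged at entry. Unaffected
newborns are represented as a branch with `model = NULL`, contributing no
modelled cost, QALY or life-year. This mirrors how the published per-newborn
tables are constructed — population QALYs of order 1e-4 per newborn are only
possible if the 99,989 unaffected per 100,000 contribute zero modelled
outcomes — and is cleaner than inventing a pseudo-state for healthy children.
Consequently the package's QALY/LY figures are *increments attributable to
the modelled conditions*, not whole-population expectancy.

Incremental results carry an explicit dominance label: ICERs are reported
only in the `"ratio"` case, since a negative ratio conflates "cheaper and
better" with "costlier and worse". Comparisons are pairwise between named
strategies; no efficiency frontier over more than two strategies is
computed, because evaluations of this design report pairwise ICERs.

## Probabilistic sensitivity analysis

Parameter uncertainty follows standard health-technology-assessment
practice: beta distributions for quantities on `[0, 1]` (probabilities,
utilities), gamma (or lognormal) for non-negative costs, each moment-matched
from a mean and standard error. Where no published spread exists the default
is SE = 20% of the mean — a choice, flagged here and in
`paperlike_parameter_specs()`, not an estimate. Three details matter:

* **Shared draws across strategies.** A `parameter_spec` carries a vector of
  tree paths, and one draw is written to all of them. Incidence must be the
  same in the screening and no-screening arm of a given iteration; sampling
  them independently would fabricate spurious incremental variance.
* **Probability coherence after a draw.** Setting an off-diagonal transition
  probability re-sets the row's diagonal to the remainder; if the remainder
  is negative the draw is rejected and redrawn (from a second RNG stream
  derived from `seed + 1`, so the result is reproducible no matter how many
  rejections occur), and the rejection count is reported. Costs are never
  clamped. Setting a branch probability rescales its siblings, so the
  unaffected branch absorbs an incidence change.
* **Dominance-aware interval endpoints.** Percentile intervals for the
  deltas are plain 2.5/97.5 empirical percentiles (inverse-CDF convention,
  matching a full sort). The ICER interval instead ranks iterations by net
  monetary benefit at the reporting threshold — raw ratios are not monotone
  across quadrants — and an endpoint falling in the win-win quadrant is
  reported as the label `"dominant"`, the way published tables print
  intervals like "(dominant, $46,753)".

A fully `fixed` specification degenerates to the deterministic result on
every iteration, which the tests assert exactly; this is the cheapest
end-to-end check that the PSA machinery adds nothing but the sampling.

## One-way sensitivity analysis

`one_way()` pins a parameter at each bound, re-evaluates the whole tree, and
restores nothing because trees are immutable values — the tests assert the
base case is bit-identical afterwards. The tornado sort metric defaults to
net monetary benefit at USD 35,000/QALY: ICER-based sorting is undefined
whenever a bound crosses into a dominance quadrant. Default bounds are
±20% of base case when none are supplied. Ties in swing are broken
lexicographically so output order is deterministic.

## Budget impact

Budget projections are undiscounted nominal cash flows for a 100,000-newborn
cohort over 5 years, staggered so a new cohort enters each year: programme
year `y` costs the cumulative sum of the cohort profile up to `y`. All
currency is handled in integer cents, and the staggering identity
`sum_y cumsum(v)[y] = sum_k (n-k+1) v[k]` is asserted inside
`staggered_totals()` on every call.

The packaged tables (`load_fixture_tables()`) transcribe the published
future/current cohort budgets. Published tables of this kind are printed to
the dollar from unrounded internals and do not quite reconcile; two cells
are therefore reconciled at load time, as documented in the function's help:
the corrupted year-1 total of the future panel is recomputed
(USD 14,883,907), and the late-SCID year-2 cell is carried as USD 57, the
unique value consistent with its row's printed total, the printed year-2
total, and the printed 5-year cohort total. Per-component printed totals are
never used in arithmetic. Grand totals are always derived from yearly
totals, giving one canonical summation order; a checksum on each panel's
5-year total guards the transcription. Budget vectors can also come from the
engine's calendar-year profiles (`budget_component_from_outcome()`), but
that model-driven mode cannot be validated against the published rows — the
mapping from health states to the published per-year decay profiles is not
recoverable — so the published-table mode is the reference path.

## The synthetic fixture: what it is and is not

The clinical parameters behind the published SMA/SCID evaluations
(transition probabilities, utilities, state costs) live in an appendix and
companion manuscript that are not publicly available. The shipped
`paperlike_fixture()` therefore carries the published *structural* constants
— 11 SMA states on 6-month cycles, 6 SCID states on 3-month cycles, 3%
discounting, 5/60-year horizons, SMA incidence 1/11,000, SCID incidence
1/65,000 (midpoint of the published 1/50,000–1/100,000 range, which is all
that is printed), gene therapy at USD 1.54M as a one-off at entry, one-off
HSCT costs, screening at USD 558,371 per 100,000 newborns — around
*synthetic* clinical parameters: severity-ordered utilities, tridiagonal
progression for SMA, a six-state transplant pathway for SCID with the late
arm facing higher infection mortality and a delayed, costlier transplant.

One scalar is calibrated rather than chosen: the clinical-SMA recurring
therapy cost multiplier is solved by `calibrate()` (bisection on a monotone
output) so that the 60-year per-newborn incremental cost equals −86 USD, the
published value, anchoring the fixture's magnitude. Everything else is fixed
by construction. The fixture reproduces the published *sign structure* — a
positive 5-year incremental cost (the upfront gene-therapy price dominates
early) with QALY gains, and 60-year dominance — and the right orders of
magnitude (its 5-year ICER lands near USD 620,000/QALY against the published
~500,000; its tornado is led by SMA incidence and therapy costs, as
published). It does **not** reproduce the published per-newborn values, and
passing tests on it demonstrate correct machinery under realistic structure,
not recovery of the published clinical model. Real screening data also
contain features the fixture omits entirely: false positives and screening
performance, family-history stratification of SCID, SMA type heterogeneity
and *SMN2* copy number, and any time-varying hazard.

`generate_random_model()` (Dirichlet-sampled rows, scalable death mass,
severity-ordered utilities) supplies the property tests: a thousand seeds
must produce valid models, traces must conserve mass and have monotone death
occupancy, and random small models must match the microsimulation oracle.

## Numerical choices and degenerate inputs

* Probability tolerances (row sums, initial distributions, branch sums) are
  1e-9; validation is report-style and never mutates.
* The configuration schema (YAML/JSON, `load_spec()`/`write_spec()`) rejects
  unknown keys at every level — a typo in a probability name must be an
  error, not a silently ignored key — and rejects horizons that are not
  integer multiples of every member cycle length.
* Bisection calibration requires a sign change over the bracket and stops on
  an output tolerance (default 1e-6) or after 100 iterations; the
  self-recovery tests demand 1e-6 relative accuracy on the knob.
* Zero-effect increments classify by cost sign; an all-zero increment is a
  ratio of 0. Percentile ranks snap away float noise in `(1-level)/2` before
  indexing.
* `proportion_cost_effective(..., wtp = Inf)` returns the fraction of
  iterations with a QALY gain, the documented limit of the NMB criterion.

## Problem sizes

The shipped analyses use the published design sizes: 1000 PSA iterations,
60-year horizons (120 SMA cycles, 240 SCID cycles), 100,000-path
microsimulation checks on small models, and a thousand random-model seeds in
the property tests. The whole test suite runs in well under a minute on a
single CPU; `scripts/acceptance.R` in about half a minute.

## Known limitations

Cohort-level expectation only (no individual-level microsimulation beyond
the test oracle); no tunnel states or time-varying matrices; pairwise
comparisons only; no value-of-information analysis or correlated parameter
sampling; single-currency accounting with an optional display-only
conversion scalar in the CLI; budget projections are undiscounted by design
and, as with any budget-impact analysis, increasingly imprecise at longer
range.
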