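# nbscea

Decision-analytic modelling of newborn bloodspot screening (NBS) programs:
cost-effectiveness and budget-impact analysis for adding rare conditions —
the shipped fixtures model spinal muscular atrophy (SMA, treated with one-off
gene therapy when screen-detected, recurring nusinersen when clinically
detected) and severe combined immunodeficiency (SCID, treated with early vs
late hematopoietic stem cell transplantation) — to an existing screening
panel.

The package is for health-economics analysts and screening-program evaluators
who need a reproducible, scriptable alternative to GUI modelling tools for
this class of evaluation.

## What it computes

**Markov cohort engine.** Each treatment arm is a time-homogeneous Markov
cohort model: states $s = 1,\dots,n$ with per-year utility weights $u_s$ and
running costs $c_s$, a constant per-cycle transition matrix $P$ (row
stochastic, absorbing death), and cycle length $\Delta$ in years (0.5 for the
SMA models, 0.25 for SCID). With occupancy $\pi_k = \pi_0 P^k$ at cycle start
$t_k = k\Delta$ and discount rate $r$ per annum,

$$\text{QALY} = \sum_k \sum_s \pi_{k,s}\, u_s\, \Delta\, (1+r)^{-t_k},
\qquad
\text{cost} = \sum_k \sum_s \pi_{k,s}\, c_s\, \Delta\, (1+r)^{-t_k}
 + \sum_e a_e\, \alpha(t_e)\, (1+r)^{-t_e},$$

where one-off costs $a_e$ (gene therapy at entry, HSCT at the transplant
time) are charged to the fraction $\alpha(t_e)$ of the cohort alive at the
event time. Life-years are the same sum over non-death states with $u_s = 1$.

**Decision tree.** Strategies (screen vs not screen) split into
incidence-weighted chance branches, each carrying a Markov model; unaffected
newborns are a zero-outcome branch, so per-newborn expected values are of
order incidence × per-patient outcome. A per-person screening cost is charged
at entry.

**CEA.** Incremental cost $\Delta C$ and effect $\Delta E$ between two named
strategies give the ICER $\Delta C / \Delta E$, with dominance handled
explicitly ($\Delta C < 0, \Delta E > 0$: *dominant*; the reverse:
*dominated*), net monetary benefit $\lambda\,\Delta E - \Delta C$ at a
willingness-to-pay threshold $\lambda$, and linear scaling to a birth cohort.

**PSA.** Joint Monte-Carlo sampling of parameters (beta for probabilities and
utilities, gamma/lognormal for costs, moment-matched from mean and standard
error), per-draw re-evaluation of the tree, CE-plane clouds, percentile
confidence intervals with dominance-aware ICER endpoints, CEACs, and the
proportion of iterations cost-effective at a threshold.

**One-way SA.** Tornado tables: each parameter pinned at a low/high bound
with everything else at base case, entries sorted by output swing.

**Budget impact.** Undiscounted yearly cash flows for a cohort of 100,000
newborns, staggered so one new cohort enters per year: the programme total in
year $y$ is the cumulative sum of the cohort profile, and the 5-year net
budget is future minus current programme. All budget arithmetic is carried in
integer cents.

## Worked example

```r
library(nbscea)

fx <- paperlike_fixture()          # synthetic SMA+SCID evaluation
ev <- expected_values(fx$tree)     # per-newborn outcomes, 60-year horizon
inc <- incremental(ev[[fx$intervention]], ev[[fx$comparator]])
print(inc)
#> incremental: cost -86.00, QALY +0.001343, LY +0.000865 -> dominant

scale_to_cohort(inc, 100000)$delta_cost
#> [1] -8600000

tabs <- load_fixture_tables()      # published budget tables, 100,000 newborns
fut <- staggered_totals(cohort_yearly_totals(tabs$future)$yearly_totals, 5)
cur <- staggered_totals(cohort_yearly_totals(tabs$current)$yearly_totals, 5)
net_budget(fut, cur)$total_difference_1m
#> [1] 35
```

Per newborn screened, the synthetic 60-year evaluation saves USD 86 and gains
0.0013 QALYs — screening *dominates* no screening — which scales to a saving
of USD 8.6M per 100,000 newborns. The staggered 5-year budget comparison
shows the screening programme needs an additional USD 35M up front, driven by
the one-off gene-therapy price.

A command-line interface wraps the same functions
(`inst/cli/nbscea.R run|psa|owsa|budget|fixtures --spec FILE --out DIR ...`);
outputs are full-precision CSV plus a JSON metadata sidecar carrying the
seed.

## Limitations

The clinical transition probabilities, utilities and state-cost values behind
the published SMA/SCID evaluations are not publicly available; the shipped
disease models are synthetic, calibrated only to the published *structure*
(state counts, cycle lengths, incidences, therapy price points) and the sign
pattern of the published results. See the methods vignette
(`vignettes/nbs-cost-effectiveness.Rmd`) for the modelling conventions and
their consequences.
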