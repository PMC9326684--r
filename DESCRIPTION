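Package: nbscea
Title: Cost-Effectiveness and Budget-Impact Modelling for Newborn Screening Programs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Decision-analytic modelling toolkit for evaluating the addition of
    conditions such as spinal muscular atrophy (SMA) and severe combined
    immunodeficiency (SCID) to newborn bloodspot screening panels. Provides a
    time-homogeneous Markov cohort engine with configurable cycle lengths,
    decision trees of incidence-weighted chance branches, discounted
    cost/QALY/life-year accumulation, incremental cost-effectiveness ratios
    with dominance handling, probabilistic sensitivity analysis with
    cost-effectiveness acceptability curves, one-way (tornado) sensitivity
    analysis, and a staggered-cohort budget-impact calculator with
    integer-cent arithmetic. Ships synthetic disease-model fixtures and
    transcriptions of published budget tables, plus a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
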