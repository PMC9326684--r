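# Budget-impact analysis with integer-cent arithmetic.
#
# Published budget tables are printed to the dollar and their roundings do
# not always reconcile; all internal sums here are carried in integer cents
# (exact in doubles far beyond any national budget) with one canonical
# summation order: cells -> yearly totals -> grand totals. Grand totals are
# never formed from independently rounded per-component totals.

to_cents <- function(x) round(x * 100)
from_cents <- function(x) x / 100

#' Define a budget component
#'
#' One line of a cohort budget table: a labelled group of persons (counts may
#' be fractional expected cases, e.g. 8.5 screen-detected SMA cases per
#' 100,000 newborns) and its undiscounted nominal cost in each projection
#' year.
#'
#' @param label Component label (e.g. `"Screened SMA"`).
#' @param n_persons Expected number of persons in the cohort.
#' @param yearly_costs Non-negative numeric vector of undiscounted costs, one
#'   entry per projection year.
#' @return Object of class `budget_component`.
#' @export
budget_component <- function(label, n_persons, yearly_costs) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label),
            is.numeric(n_persons), length(n_persons) == 1L, n_persons >= 0,
            is.numeric(yearly_costs), length(yearly_costs) >= 1L)
  if (any(yearly_costs < 0)) stop("yearly_costs must be >= 0", call. = FALSE)
  structure(list(label = label, n_persons = as.numeric(n_persons),
                 yearly_costs = as.numeric(yearly_costs)),
            class = "budget_component")
}

#' Build a budget component from a Markov outcome
#'
#' Model-driven mode: converts the calendar-year undiscounted cost profile of
#' a [run_cohort()] outcome (per person) into a [budget_component()] for
#' `n_persons` expected cases.
#'
#' @param label Component label.
#' @param n_persons Expected number of persons.
#' @param outcome An `nbs_outcome`.
#' @param n_years Number of projection years (taken from the front of the
#'   outcome's yearly profile).
#' @return A `budget_component`.
#' @export
budget_component_from_outcome <- function(label, n_persons, outcome, n_years) {
  stopifnot(inherits(outcome, "nbs_outcome"))
  yearly <- pad_to(outcome$yearly_undiscounted_costs, n_years)[seq_len(n_years)]
  budget_component(label, n_persons, yearly * n_persons)
}

#' Define a cohort budget table
#'
#' @param components List of [budget_component()] objects with equal-length
#'   yearly profiles.
#' @param cohort_size Cohort size the components describe (100,000 newborns
#'   in the shipped fixtures); component person counts must add up to it
#'   within printing tolerance (0.5).
#' @param program_label Free-text programme label.
#' @return Object of class `budget_table`.
#' @export
budget_table <- function(components, cohort_size, program_label = "") {
  stopifnot(is.list(components), length(components) >= 1L,
            all(vapply(components, inherits, logical(1), "budget_component")),
            is.numeric(cohort_size), length(cohort_size) == 1L, cohort_size > 0)
  lens <- vapply(components, function(c) length(c$yearly_costs), integer(1))
  if (length(unique(lens)) != 1L) {
    stop("components have inconsistent numbers of years", call. = FALSE)
  }
  n_tot <- sum(vapply(components, `[[`, numeric(1), "n_persons"))
  if (abs(n_tot - cohort_size) > 0.5) {
    stop(sprintf("component persons sum to %.2f, cohort size is %g",
                 n_tot, cohort_size), call. = FALSE)
  }
  structure(list(components = components, cohort_size = as.numeric(cohort_size),
                 program_label = program_label, n_years = lens[1L]),
            class = "budget_table")
}

#' Yearly and 5-year totals of one cohort's budget table
#'
#' Sums component cells into per-year totals, per-component totals, and the
#' cohort grand total. The grand total is the sum of the yearly totals
#' (equivalently of all cells) -- never of separately rounded component
#' totals, which is where published tables pick up off-by-one-dollar
#' artefacts. All arithmetic is exact in integer cents.
#'
#' @param table A [budget_table()].
#' @return List with `yearly_totals` (length `n_years`), `component_totals`
#'   (named), and `grand_total`, all in currency units.
#' @export
cohort_yearly_totals <- function(table) {
  stopifnot(inherits(table, "budget_table"))
  cells <- vapply(table$components, function(c) to_cents(c$yearly_costs),
                  numeric(table$n_years))
  cells <- matrix(cells, nrow = table$n_years)
  yearly <- rowSums(cells)
  comp <- colSums(cells)
  names(comp) <- vapply(table$components, `[[`, character(1), "label")
  list(yearly_totals = from_cents(yearly),
       component_totals = from_cents(comp),
       grand_total = from_cents(sum(yearly)))
}

#' Staggered-cohort programme totals
#'
#' One new birth cohort enters the programme each year and follows the same
#' yearly cost profile `v`; the cohort entering in year `c` contributes
#' `v[y - c + 1]` to programme year `y`. The programme total in year `y` is
#' therefore the cumulative sum of `v` up to `y`, and the grand total is also
#' `sum((n_years - k + 1) * v[k])`; both forms are computed and asserted
#' equal to the cent.
#'
#' @param cohort_yearly Per-cohort yearly cost vector (currency units).
#' @param n_years Number of programme years (`<= length(cohort_yearly)`).
#' @return List with `program_year_totals`, `cohort_totals` (cohort `c` runs
#'   `n_years - c + 1` years), and `grand_total`.
#' @export
staggered_totals <- function(cohort_yearly, n_years) {
  stopifnot(is.numeric(cohort_yearly), length(cohort_yearly) >= 1L,
            is.numeric(n_years), length(n_years) == 1L, n_years >= 1)
  n_years <- as.integer(n_years)
  if (n_years > length(cohort_yearly)) {
    stop("n_years exceeds the cohort profile length", call. = FALSE)
  }
  v <- to_cents(cohort_yearly[seq_len(n_years)])
  program <- cumsum(v)
  cohorts <- vapply(seq_len(n_years),
                    function(c) sum(v[seq_len(n_years - c + 1L)]), numeric(1))
  grand <- sum(program)
  grand_alt <- sum((n_years - seq_len(n_years) + 1L) * v)
  stopifnot(grand == grand_alt)  # staggering identity, exact in cents
  list(program_year_totals = from_cents(program),
       cohort_totals = from_cents(cohorts),
       grand_total = from_cents(grand))
}

#' Net budget impact of a future programme over the current one
#'
#' Elementwise and total differences between two [staggered_totals()]
#' outputs, plus the rounded figures used in narrative reporting (nearest
#' 0.1 million and nearest million).
#'
#' @param future,current Outputs of [staggered_totals()] over the same
#'   number of years.
#' @return List with `yearly_differences`, `total_difference`,
#'   `total_difference_0.1m`, `total_difference_1m`.
#' @export
net_budget <- function(future, current) {
  stopifnot(is.list(future), is.list(current))
  f <- to_cents(future$program_year_totals)
  c_ <- to_cents(current$program_year_totals)
  if (length(f) != length(c_)) {
    stop("programmes cover different numbers of years", call. = FALSE)
  }
  diff_yearly <- f - c_
  total <- to_cents(future$grand_total) - to_cents(current$grand_total)
  list(yearly_differences = from_cents(diff_yearly),
       total_difference = from_cents(total),
       total_difference_0.1m = round(from_cents(total) / 1e6, 1),
       total_difference_1m = round(from_cents(total) / 1e6))
}

#' Share of one component in the cohort's 5-year budget
#'
#' Component total divided by the cohort grand total (both in exact cents),
#' with the integer-percent rounding used in narrative reporting -- e.g. a
#' screening line of ~USD 558,000 against a USD 17M cohort budget is "3%".
#'
#' @param component Component label present in `table`.
#' @param table A [budget_table()].
#' @return List with `fraction` and `percent` (rounded to nearest integer).
#' @export
component_share <- function(component, table) {
  stopifnot(inherits(table, "budget_table"),
            is.character(component), length(component) == 1L)
  labels <- vapply(table$components, `[[`, character(1), "label")
  hit <- which(labels == component)
  if (length(hit) != 1L) {
    stop("unknown component label: ", component, call. = FALSE)
  }
  tot <- cohort_yearly_totals(table)
  frac <- to_cents(tot$component_totals[[hit]]) / to_cents(tot$grand_total)
  list(fraction = frac, percent = round(100 * frac))
}
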