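# Small model builders shared across tests.

# One alive state (never dies) plus an unreachable death state.
single_alive_model <- function(annual_cost = 100, annual_utility = 1,
                               cycle = 1) {
  markov_model(
    list(health_state("alive", annual_utility = annual_utility,
                      annual_cost = annual_cost),
         health_state("dead", is_absorbing = TRUE, is_death = TRUE)),
    matrix(c(1, 0, 0, 1), 2, byrow = TRUE),
    cycle_length_years = cycle)
}

# Alive state with per-cycle survival p, absorbing death.
survival_model <- function(p_survive, annual_cost = 0, annual_utility = 1,
                           cycle = 1, one_off_costs = NULL) {
  markov_model(
    list(health_state("alive", annual_utility = annual_utility,
                      annual_cost = annual_cost),
         health_state("dead", is_absorbing = TRUE, is_death = TRUE)),
    matrix(c(p_survive, 1 - p_survive, 0, 1), 2, byrow = TRUE),
    cycle_length_years = cycle, one_off_costs = one_off_costs)
}

# A tiny two-strategy tree: intervention pays `cost` upfront for a branch
# with incidence p; comparator does nothing.
toy_incidence_tree <- function(p = 1 / 11000, cost = 1.54e6, horizon = 5,
                               rate = 0, fixed_cost = 0,
                               utility = 1, p_survive = 1) {
  affected <- survival_model(p_survive, annual_utility = utility,
                             one_off_costs = data.frame(time_years = 0,
                                                        amount = cost))
  untreated <- survival_model(p_survive, annual_utility = utility / 2)
  decision_tree(
    list(strategy("screen",
                  list(chance_branch(p, affected, "affected"),
                       chance_branch(1 - p, NULL, "healthy")),
                  fixed_per_person_cost = fixed_cost),
         strategy("no screen",
                  list(chance_branch(p, untreated, "affected"),
                       chance_branch(1 - p, NULL, "healthy")))),
    discount_rate_annual = rate, horizon_years = horizon)
}

# Cached paperlike fixture: calibration makes it mildly expensive, and many
# test files only read from it.
paperlike_cached <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- paperlike_fixture(1)
    fx
  }
})

expect_outcome_close <- function(a, b, tol = 1e-9) {
  for (f in c("discounted_cost", "discounted_qaly", "discounted_ly",
              "undiscounted_cost", "undiscounted_qaly", "undiscounted_ly")) {
    expect_equal(a[[f]], b[[f]], tolerance = tol, ignore_attr = TRUE)
  }
}
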