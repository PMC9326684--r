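test_that("discount factors follow the compound-interest definition", {
  expect_identical(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03, tolerance = 1e-12)
  # closed form evaluated independently through log/exp
  expect_equal(discount_factor(2, 0.03), exp(-2 * log(1.03)),
               tolerance = 1e-12)
  expect_equal(discount_factor(0.5, 0.03), exp(-0.5 * log(1.03)),
               tolerance = 1e-12)
  expect_error(discount_factor(-1, 0.03), "non-negative")
  expect_error(discount_factor(1, -0.01), "non-negative")
})

test_that("a never-dying cohort accrues an annuity-due", {
  m <- single_alive_model(annual_cost = 100, annual_utility = 1, cycle = 1)
  res0 <- run_cohort(m, 3, 0)
  expect_equal(res0$outcome$undiscounted_cost, 300)
  expect_equal(res0$outcome$undiscounted_qaly, 3)
  expect_equal(res0$outcome$undiscounted_ly, 3)
  expect_equal(res0$outcome$discounted_cost, 300)

  # annuity-due closed form: sum_{k=0}^{2} 1.03^-k = (1 - 1.03^-3)/(1 - 1.03^-1)
  res <- run_cohort(m, 3, 0.03)
  annuity <- (1 - 1.03^-3) / (1 - 1.03^-1)
  expect_equal(res$outcome$discounted_cost, 100 * annuity, tolerance = 1e-9)
  expect_equal(res$outcome$discounted_qaly, annuity, tolerance = 1e-9)

  # half-year cycles with exact fractional-year exponents
  m2 <- single_alive_model(annual_cost = 100, cycle = 0.5)
  res2 <- run_cohort(m2, 2, 0.03)
  expect_equal(res2$outcome$discounted_cost,
               100 * 0.5 * sum(1.03^-(c(0, 0.5, 1, 1.5))), tolerance = 1e-9)
})

test_that("life-years under constant hazard match the geometric series", {
  p <- 0.85
  m <- survival_model(p, cycle = 0.5)
  n_cyc <- 12L
  res <- run_cohort(m, 6, 0)
  expect_equal(res$outcome$undiscounted_ly,
               0.5 * sum(p^(0:(n_cyc - 1L))), tolerance = 1e-9)
  # QALY = utility * LY here
  expect_equal(res$outcome$undiscounted_qaly, res$outcome$undiscounted_ly,
               tolerance = 1e-12)
})

test_that("traces conserve mass, death only grows, discounting only shrinks", {
  for (seed in 1:25) {
    m <- generate_random_model(n_states = 2 + seed %% 5, cycle_length_years = 0.5,
                               seed = seed)
    res <- run_cohort(m, 10, 0.03)
    occ <- res$trace$occupancy
    expect_equal(rowSums(occ), rep(1, nrow(occ)), tolerance = 1e-9)
    death_col <- occ[, ncol(occ)]
    expect_true(all(diff(death_col) >= -1e-12))
    out <- res$outcome
    expect_lte(out$discounted_cost, out$undiscounted_cost + 1e-9)
    expect_lte(out$discounted_qaly, out$undiscounted_qaly + 1e-9)
    expect_lte(out$discounted_ly, out$undiscounted_ly + 1e-9)
    expect_lte(out$discounted_qaly, out$discounted_ly + 1e-9)
    expect_equal(sum(out$yearly_undiscounted_costs), out$undiscounted_cost,
                 tolerance = 1e-6)
  }
})

test_that("one-off costs are charged to the fraction alive at the event time", {
  p <- 0.8
  m <- survival_model(p, cycle = 1,
                      one_off_costs = data.frame(time_years = 2, amount = 1000))
  res <- run_cohort(m, 5, 0.03)
  expect_equal(res$outcome$discounted_cost, 1000 * p^2 * 1.03^-2,
               tolerance = 1e-9)
  expect_equal(res$outcome$undiscounted_cost, 1000 * p^2, tolerance = 1e-9)
  # charged into calendar year 3 (floor(2) + 1)
  expect_equal(res$outcome$yearly_undiscounted_costs,
               c(0, 0, 1000 * p^2, 0, 0), tolerance = 1e-9)

  # an event at or beyond the horizon is not charged
  m_late <- survival_model(p, cycle = 1,
                           one_off_costs = data.frame(time_years = 5,
                                                      amount = 1000))
  expect_equal(run_cohort(m_late, 5, 0)$outcome$discounted_cost, 0)
})

test_that("undiscounted costs aggregate by calendar year", {
  m <- single_alive_model(annual_cost = 120, cycle = 0.5)
  res <- run_cohort(m, 2, 0)
  # two half-cycles of 60 in each of the two years
  expect_equal(res$outcome$yearly_undiscounted_costs, c(120, 120))
})

test_that("horizon must be an integer multiple of the cycle length", {
  m <- single_alive_model(cycle = 0.4)
  expect_error(run_cohort(m, 5, 0.03), "integer multiple")
  expect_silent(run_cohort(m, 4, 0.03))
})

test_that("half-cycle correction averages adjacent boundaries", {
  p <- 0.8
  m <- survival_model(p, cycle = 1)
  res <- run_cohort(m, 3, 0.03, half_cycle_correction = TRUE)
  surv <- p^(0:3)
  w <- (surv[1:3] + surv[2:4]) / 2
  expect_equal(res$outcome$discounted_ly,
               sum(w * 1.03^-(c(0.5, 1.5, 2.5))), tolerance = 1e-9)
})

test_that("the microsimulation oracle agrees with the cohort engine", {
  # deterministic chain: exact agreement
  det <- markov_model(
    list(health_state("a", annual_utility = 0.9, annual_cost = 10),
         health_state("b", annual_utility = 0.5, annual_cost = 20),
         health_state("dead", is_absorbing = TRUE, is_death = TRUE)),
    matrix(c(0, 1, 0,
             0, 0, 1,
             0, 0, 1), 3, byrow = TRUE), 1)
  coh <- run_cohort(det, 3, 0.03)$outcome
  sim <- brute_force_oracle(det, 3, 0.03, n_individuals = 10, seed = 1)
  expect_outcome_close(sim$outcome, coh, tol = 1e-12)

  # stochastic toy: agreement within 3 standard errors
  m <- survival_model(0.9, annual_cost = 1000, annual_utility = 0.8,
                      cycle = 0.5,
                      one_off_costs = data.frame(time_years = 1, amount = 500))
  coh <- run_cohort(m, 5, 0.03)$outcome
  sim <- brute_force_oracle(m, 5, 0.03, n_individuals = 50000, seed = 7)
  expect_lt(abs(sim$outcome$discounted_cost - coh$discounted_cost),
            3 * sim$se$discounted_cost)
  expect_lt(abs(sim$outcome$discounted_qaly - coh$discounted_qaly),
            3 * sim$se$discounted_qaly)
  expect_lt(abs(sim$outcome$discounted_ly - coh$discounted_ly),
            3 * sim$se$discounted_ly)

  expect_error(brute_force_oracle(m, 5, 0.03, n_individuals = 0, seed = 1),
               ">= 1")
})
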