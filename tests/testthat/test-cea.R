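test_that("strategy expectation is the incidence-weighted branch mixture", {
  m <- single_alive_model(annual_cost = 100, annual_utility = 0.9)
  base <- run_cohort(m, 3, 0.03)$outcome

  # single branch at p = 1 plus a fixed screening cost
  t1 <- decision_tree(
    list(strategy("s", list(chance_branch(1, m, "all")),
                  fixed_per_person_cost = 7)),
    discount_rate_annual = 0.03, horizon_years = 3)
  ev <- expected_values(t1)
  expect_equal(ev$s$discounted_cost, base$discounted_cost + 7,
               tolerance = 1e-12)
  expect_equal(ev$s$undiscounted_cost, base$undiscounted_cost + 7,
               tolerance = 1e-12)
  expect_equal(ev$s$discounted_qaly, base$discounted_qaly, tolerance = 1e-12)

  # two identical branches at p = 0.5 are the same as one branch
  t2 <- decision_tree(
    list(strategy("s", list(chance_branch(0.5, m, "a"),
                            chance_branch(0.5, m, "b")),
                  fixed_per_person_cost = 7)),
    discount_rate_annual = 0.03, horizon_years = 3)
  expect_outcome_close(expected_values(t2)$s, ev$s, tol = 1e-12)
})

test_that("a rare branch with an upfront therapy prices out per newborn", {
  affected <- survival_model(1, one_off_costs = data.frame(time_years = 0,
                                                           amount = 1.54e6))
  tree <- decision_tree(
    list(strategy("screen",
                  list(chance_branch(1 / 11000, affected, "case"),
                       chance_branch(10999 / 11000, NULL, "healthy")))),
    discount_rate_annual = 0.03, horizon_years = 5)
  ev <- expected_values(tree)
  expect_equal(ev$screen$discounted_cost, 1.54e6 / 11000, tolerance = 1e-9)
  expect_equal(ev$screen$discounted_cost, 140, tolerance = 1e-9)
})

test_that("incremental results classify dominance as published", {
  # published 60-year per-newborn deltas: cost saving with QALY gain
  inc <- incremental_from_deltas(-86.00, 0.00095, 0.00137)
  expect_identical(inc$label, "dominant")
  expect_true(is.na(inc$icer_qaly))

  inc2 <- incremental_from_deltas(10, 0.001)
  expect_identical(inc2$label, "ratio")
  expect_equal(inc2$icer_qaly, 10000)

  expect_identical(incremental_from_deltas(10, -0.001)$label, "dominated")
  expect_identical(incremental_from_deltas(10, 0)$label, "dominated")
  expect_identical(incremental_from_deltas(-10, 0)$label, "dominant")
  zero <- incremental_from_deltas(0, 0)
  expect_identical(zero$label, "ratio")
  expect_equal(zero$icer_qaly, 0)
})

test_that("incremental deltas are antisymmetric", {
  set.seed(11)
  for (i in 1:10) {
    a <- run_cohort(generate_random_model(3, 1, seed = i), 4, 0.03)$outcome
    b <- run_cohort(generate_random_model(3, 1, seed = i + 100), 4, 0.03)$outcome
    ab <- incremental(a, b)
    ba <- incremental(b, a)
    expect_equal(ab$delta_cost, -ba$delta_cost, tolerance = 1e-12)
    expect_equal(ab$delta_qaly, -ba$delta_qaly, tolerance = 1e-12)
    expect_equal(ab$delta_ly, -ba$delta_ly, tolerance = 1e-12)
  }
})

test_that("per-cohort scaling is linear and keeps labels and ICERs", {
  inc <- incremental_from_deltas(-86.00, 0.00095, 0.00137)
  big <- scale_to_cohort(inc, 100000)
  expect_equal(big$delta_qaly, 95)
  expect_equal(big$delta_ly, 137)
  expect_equal(big$delta_cost, -8.6e6)
  expect_identical(big$label, "dominant")

  same <- scale_to_cohort(inc, 1)
  expect_equal(same, inc)

  withratio <- incremental_from_deltas(10, 0.001)
  scaled <- scale_to_cohort(withratio, 1000)
  expect_equal(scaled$icer_qaly, withratio$icer_qaly)

  out <- run_cohort(single_alive_model(annual_cost = 50), 2, 0)$outcome
  expect_equal(scale_to_cohort(out, 10)$undiscounted_cost,
               10 * out$undiscounted_cost)
  expect_error(scale_to_cohort(inc, 0), "positive")
})

test_that("net monetary benefit implements wtp * dQALY - dcost", {
  inc <- incremental_from_deltas(-86, 0.00095)
  expect_equal(net_monetary_benefit(inc, 35000), 35000 * 0.00095 + 86)
  expect_equal(net_monetary_benefit(inc, 0), 86)
  expect_equal(net_monetary_benefit(incremental_from_deltas(0, 0), 50000), 0)
  expect_error(net_monetary_benefit(inc, -1), "non-negative")
})

test_that("dominance implies a definite NMB sign at every threshold", {
  wtps <- c(0, 1000, 35000, 1e6)
  dominant <- incremental_from_deltas(-50, 0.001)
  dominated <- incremental_from_deltas(50, -0.001)
  for (w in wtps) {
    expect_gt(net_monetary_benefit(dominant, w), 0)
    expect_lt(net_monetary_benefit(dominated, w), 0)
  }
  # in quadrants I/III the NMB sign agrees with the ICER-vs-threshold rule
  inc <- incremental_from_deltas(10, 0.001)  # ICER 10,000
  expect_gt(net_monetary_benefit(inc, 20000), 0)
  expect_lt(net_monetary_benefit(inc, 5000), 0)
})
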