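test_that("published cohort year totals recompute from the component cells", {
  tabs <- load_fixture_tables()
  fut <- cohort_yearly_totals(tabs$future)
  cur <- cohort_yearly_totals(tabs$current)
  expect_equal(fut$yearly_totals[1],
               558371 + 13759906 + 318122 + 245120 + 2388)
  expect_equal(fut$yearly_totals[1], 14883907)
  expect_equal(fut$yearly_totals[2:5], c(666227, 523731, 473746, 444931))
  expect_equal(fut$grand_total, 16992542)
  expect_equal(cur$yearly_totals[1], 4824852 + 382024 + 49024)
  expect_equal(cur$yearly_totals[1], 5255900)
  expect_equal(cur$grand_total, 12484349)
  expect_equal(unname(fut$component_totals["Screened SMA"]), 15368005)
})

test_that("an all-zero budget table totals to zero", {
  tab <- budget_table(list(budget_component("nothing", 100, rep(0, 5))),
                      cohort_size = 100)
  tot <- cohort_yearly_totals(tab)
  expect_equal(tot$yearly_totals, rep(0, 5))
  expect_equal(tot$grand_total, 0)
})

test_that("staggered programme totals are cumulative sums of the profile", {
  tabs <- load_fixture_tables()
  fut <- staggered_totals(cohort_yearly_totals(tabs$future)$yearly_totals, 5)
  cur <- staggered_totals(cohort_yearly_totals(tabs$current)$yearly_totals, 5)
  expect_equal(fut$program_year_totals[1], 14883907)
  expect_equal(fut$program_year_totals[2], 14883907 + 666227)
  expect_equal(fut$program_year_totals[2], 15550134)
  expect_equal(cur$grand_total, 45432231)
  # cohort c runs for n - c + 1 years
  expect_equal(fut$cohort_totals[1], 16992542)
  expect_equal(fut$cohort_totals[5], 14883907)

  simple <- staggered_totals(c(1, 0, 0), 3)
  expect_equal(simple$program_year_totals, c(1, 1, 1))
  expect_equal(simple$grand_total, 3)

  expect_error(staggered_totals(c(1, 2), 3), "exceeds")
})

test_that("the staggering identity holds to the cent on random profiles", {
  set.seed(99)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    v <- round(stats::runif(n, 0, 2e7), 2)  # random cent-valued costs
    st <- staggered_totals(v, n)
    alt <- sum((n - seq_len(n) + 1) * round(v * 100))
    expect_identical(round(st$grand_total * 100), alt)
    expect_equal(st$program_year_totals, cumsum(v), tolerance = 1e-12)
  }
})

test_that("budget arithmetic is exact in integer cents", {
  # classic binary-float trap: 0.10 + 0.20
  tab <- budget_table(list(budget_component("a", 1, c(0.10, 0)),
                           budget_component("b", 1, c(0.20, 0))),
                      cohort_size = 2)
  expect_identical(cohort_yearly_totals(tab)$grand_total, 0.3)
})

test_that("net budget differences reproduce the published narrative", {
  tabs <- load_fixture_tables()
  fut_y <- cohort_yearly_totals(tabs$future)$yearly_totals
  cur_y <- cohort_yearly_totals(tabs$current)$yearly_totals

  # single cohort over 5 years
  one_f <- list(program_year_totals = fut_y, grand_total = sum(fut_y))
  one_c <- list(program_year_totals = cur_y, grand_total = sum(cur_y))
  nb1 <- net_budget(one_f, one_c)
  expect_equal(nb1$total_difference, 16992542 - 12484349)
  expect_equal(nb1$total_difference, 4508193)
  expect_equal(nb1$total_difference_0.1m, 4.5)

  # staggered programme over 5 years
  nb <- net_budget(staggered_totals(fut_y, 5), staggered_totals(cur_y, 5))
  expect_equal(nb$total_difference_1m, 35)

  # identical programmes cancel exactly
  same <- net_budget(staggered_totals(fut_y, 5), staggered_totals(fut_y, 5))
  expect_true(all(same$yearly_differences == 0))
  expect_identical(same$total_difference, 0)
})

test_that("component shares use exact totals and integer-percent rounding", {
  tabs <- load_fixture_tables()
  sh <- component_share("Screening", tabs$future)
  expect_equal(sh$fraction, 558371 / 16992542, tolerance = 1e-12)
  expect_equal(sh$percent, 3)

  solo <- budget_table(list(budget_component("only", 10, c(5, 5))),
                       cohort_size = 10)
  expect_equal(component_share("only", solo)$percent, 100)

  with_zero <- budget_table(list(budget_component("paid", 5, c(10, 0)),
                                 budget_component("free", 5, c(0, 0))),
                            cohort_size = 10)
  expect_equal(component_share("free", with_zero)$percent, 0)
  expect_error(component_share("ghost", with_zero), "unknown component")
})

test_that("budget tables enforce shape and person-count invariants", {
  expect_error(budget_table(list(budget_component("a", 1, c(1, 2)),
                                 budget_component("b", 1, c(1, 2, 3))),
                            cohort_size = 2),
               "inconsistent")
  expect_error(budget_table(list(budget_component("a", 1, c(1, 2))),
                            cohort_size = 50),
               "cohort size")
  expect_error(budget_component("a", 1, c(-1, 2)), ">= 0")
})

test_that("model outcomes feed the budget module directly", {
  m <- survival_model(0.9, annual_cost = 1000, cycle = 0.5,
                      one_off_costs = data.frame(time_years = 0, amount = 5e4))
  out <- run_cohort(m, 5, 0)$outcome
  comp <- budget_component_from_outcome("cases", 8.5, out, 5)
  expect_length(comp$yearly_costs, 5)
  expect_equal(sum(comp$yearly_costs), 8.5 * out$undiscounted_cost,
               tolerance = 1e-6)
  # year 1 carries the one-off plus the first two half-cycles
  expect_gt(comp$yearly_costs[1], comp$yearly_costs[2])
})
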