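fake_psa <- function(dc, dq, dl = rep(0, length(dc)), seed = 1L) {
  structure(list(iterations = data.frame(delta_cost = dc, delta_qaly = dq,
                                         delta_ly = dl),
                 seed = seed, n_iter = length(dc), n_resampled = 0L),
            class = "psa_result")
}

test_that("moment-matched sampling hits the requested means", {
  n <- 1e5
  specs <- list(parameter_spec("p", "beta", mean = 0.2, spread = 0.05),
                parameter_spec("c", "gamma", mean = 1000, spread = 200),
                parameter_spec("l", "lognormal", mean = 50, spread = 10),
                parameter_spec("u", "uniform", spread = c(2, 4)),
                parameter_spec("f", "fixed", mean = 5))
  d <- sample_parameters(specs, n, seed = 123)
  expect_equal(dim(d), c(n, 5L))
  expect_lt(abs(mean(d[, "p"]) - 0.2), 3 * 0.05 / sqrt(n))
  expect_lt(abs(mean(d[, "c"]) - 1000), 3 * 200 / sqrt(n))
  expect_lt(abs(mean(d[, "l"]) - 50), 3 * 10 / sqrt(n))
  expect_lt(abs(mean(d[, "u"]) - 3), 3 * (2 / sqrt(12)) / sqrt(n))
  expect_true(all(d[, "f"] == 5))
  expect_true(all(d[, "p"] >= 0 & d[, "p"] <= 1))
  expect_true(all(d[, "c"] >= 0))

  # same seed, same draws
  expect_identical(sample_parameters(specs, 100, seed = 9),
                   sample_parameters(specs, 100, seed = 9))
})

test_that("infeasible moment matching is refused", {
  expect_error(parameter_spec("p", "beta", mean = 0, spread = 0.1),
               "infeasible")
  expect_error(parameter_spec("p", "beta", mean = 0.5, spread = 0.6),
               "too large")
  expect_error(parameter_spec("c", "gamma", mean = 0, spread = 1),
               "infeasible")
  expect_error(sample_parameters(list(), 10, 1))
})

test_that("a fully fixed PSA reproduces the deterministic result", {
  tree <- toy_incidence_tree(p = 0.01, cost = 1e5, horizon = 4, rate = 0.03,
                             fixed_cost = 3)
  ev <- expected_values(tree)
  det <- incremental(ev$screen, ev$`no screen`)
  specs <- list(
    parameter_spec("cost", "fixed", mean = 1e5,
                   paths = "strategies[screen].branches[affected].model.one_off_costs[1].amount"),
    parameter_spec("screening", "fixed", mean = 3,
                   paths = "strategies[screen].fixed_per_person_cost"))
  res <- run_psa(tree, specs, n_iter = 20, seed = 4, "screen", "no screen")
  expect_equal(res$n_iter, 20L)
  expect_true(all(abs(res$iterations$delta_cost - det$delta_cost) < 1e-12))
  expect_true(all(abs(res$iterations$delta_qaly - det$delta_qaly) < 1e-12))
  expect_identical(res$n_resampled, 0L)
})

test_that("PSA runs are reproducible for a given seed", {
  tree <- toy_incidence_tree(p = 0.01, cost = 1e5, horizon = 4, rate = 0.03)
  specs <- list(
    parameter_spec("cost", "gamma", mean = 1e5, spread = 2e4,
                   paths = "strategies[screen].branches[affected].model.one_off_costs[1].amount"),
    parameter_spec("incidence", "beta", mean = 0.01, spread = 0.002,
                   paths = sprintf("strategies[%s].branches[affected].probability",
                                   c("screen", "no screen"))))
  a <- run_psa(tree, specs, 50, seed = 77, "screen", "no screen")
  b <- run_psa(tree, specs, 50, seed = 77, "screen", "no screen")
  expect_identical(a$iterations, b$iterations)
  # sampled incidence actually moves the cloud
  expect_gt(stats::sd(a$iterations$delta_cost), 0)
})

test_that("invalid transition draws are rejected and resampled, not clamped", {
  m <- markov_model(
    list(health_state("a", annual_utility = 0.9),
         health_state("b", annual_utility = 0.5),
         health_state("dead", is_absorbing = TRUE, is_death = TRUE)),
    matrix(c(0.55, 0.15, 0.30,
             0, 0.9, 0.1,
             0, 0, 1), 3, byrow = TRUE), 1)
  tree <- decision_tree(
    list(strategy("one", list(chance_branch(1, m, "all"))),
         strategy("two", list(chance_branch(1, single_alive_model(), "all")))),
    discount_rate_annual = 0, horizon_years = 4)
  # sampled a->b mass frequently exceeds 0.7, leaving a negative diagonal
  specs <- list(parameter_spec(
    "pab", "beta", mean = 0.6, spread = 0.15,
    paths = "strategies[one].branches[all].model.transition_matrix[1,2]"))
  res <- run_psa(tree, specs, 200, seed = 5, "one", "two")
  expect_gt(res$n_resampled, 0)
  expect_equal(nrow(res$iterations), 200)
  expect_true(all(is.finite(res$iterations$delta_cost)))
})

test_that("the cost-effective proportion counts positive-NMB iterations", {
  # constructed cloud: 970 of 1000 iterations with NMB > 0 at wtp 35,000
  dq <- rep(0.001, 1000)
  dc <- c(rep(10, 970), rep(50, 30))  # NMB = 35 - dc
  res <- fake_psa(dc, dq)
  expect_equal(proportion_cost_effective(res, 35000), 0.97)

  all_dom <- fake_psa(rep(-5, 100), rep(0.01, 100))
  expect_equal(proportion_cost_effective(all_dom, 0), 1)
  expect_equal(proportion_cost_effective(all_dom, 35000), 1)

  # wtp = Inf limit: fraction with a QALY gain
  mixed <- fake_psa(c(-5, 5, 5), c(0.01, -0.01, 0.02))
  expect_equal(proportion_cost_effective(mixed, Inf), 2 / 3)
  expect_error(proportion_cost_effective(mixed, -1), "non-negative")
})

test_that("percentile intervals match an explicit full sort", {
  set.seed(42)
  dc <- stats::runif(500, -100, 100)
  dq <- stats::runif(500, -0.01, 0.01)
  res <- fake_psa(dc, dq)
  ci <- percentile_ci(res)
  # independent oracle: sort and index at ceil(p * n)
  s <- sort(dc)
  expect_equal(ci$delta_cost, c(s[ceiling(0.025 * 500)], s[ceiling(0.975 * 500)]))
  s <- sort(dq)
  expect_equal(ci$delta_qaly, c(s[ceiling(0.025 * 500)], s[ceiling(0.975 * 500)]))

  # degenerate cloud
  degen <- fake_psa(rep(3, 50), rep(0.001, 50))
  cid <- percentile_ci(degen)
  expect_equal(cid$delta_cost, c(3, 3))
  expect_equal(cid$delta_qaly, c(0.001, 0.001))

  expect_error(percentile_ci(fake_psa(1:10, 1:10)), "at least")
})

test_that("ICER interval endpoints in win-win/lose-lose quadrants get labels", {
  # all iterations gain QALYs; costs straddle zero -> best end is dominant
  dq <- rep(0.002, 200)
  dc <- seq(-100, 100, length.out = 200)
  ci <- percentile_ci(fake_psa(dc, dq))
  expect_equal(ci$icer$high, "dominant")     # high NMB end: cost saving
  expect_true(is.numeric(ci$icer$low))       # low NMB end: a real ratio
  expect_gt(ci$icer$low, 0)

  # cloud straddling dominated and dominant quadrants
  dc2 <- c(rep(-50, 100), rep(50, 100))
  dq2 <- c(rep(0.001, 100), rep(-0.001, 100))
  ci2 <- percentile_ci(fake_psa(dc2, dq2))
  expect_equal(ci2$icer$low, "dominated")
  expect_equal(ci2$icer$high, "dominant")
})

test_that("the CEAC is the thresholdwise acceptance curve", {
  dq <- c(rep(0.001, 80), rep(0.0005, 20))
  dc <- c(rep(20, 80), rep(30, 20))
  res <- fake_psa(dc, dq)
  grid <- c(0, 20000, 40000, 60000, 80000)
  curve <- ceac(res, grid)
  expect_equal(nrow(curve), length(grid))
  expect_equal(curve$fraction,
               vapply(grid, function(w) proportion_cost_effective(res, w),
                      numeric(1)))
  # all QALY deltas positive: acceptance is monotone in the threshold
  expect_true(all(diff(curve$fraction) >= 0))
  empty <- ceac(res, numeric(0))
  expect_equal(nrow(empty), 0)
  expect_error(ceac(res, c(2, 1)), "ascending")
})
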