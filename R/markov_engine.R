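#' Discount factor at an annual rate
#'
#' Present-value factor `(1 + rate)^(-t)` with exact fractional-year
#' exponents, so a 6-month cycle at 3% p.a. discounts by `1.03^-0.5`; this
#' continuous convention is the least surprising when models with different
#' cycle lengths share one tree.
#'
#' @param t_years Time in years (vectorised, must be >= 0).
#' @param rate_annual Annual discount rate as a fraction (>= 0).
#' @return Numeric vector of discount factors.
#' @export
#' @examples
#' discount_factor(1, 0.03)  # 1/1.03
discount_factor <- function(t_years, rate_annual) {
  if (!is.numeric(t_years) || any(t_years < 0)) {
    stop("t_years must be non-negative", call. = FALSE)
  }
  if (!is.numeric(rate_annual) || length(rate_annual) != 1L || rate_annual < 0) {
    stop("rate_annual must be a single non-negative number", call. = FALSE)
  }
  (1 + rate_annual)^(-t_years)
}

new_outcome <- function(discounted_cost, discounted_qaly, discounted_ly,
                        undiscounted_cost, undiscounted_qaly, undiscounted_ly,
                        yearly_undiscounted_costs) {
  structure(
    list(discounted_cost = discounted_cost,
         discounted_qaly = discounted_qaly,
         discounted_ly = discounted_ly,
         undiscounted_cost = undiscounted_cost,
         undiscounted_qaly = undiscounted_qaly,
         undiscounted_ly = undiscounted_ly,
         yearly_undiscounted_costs = yearly_undiscounted_costs),
    class = "nbs_outcome")
}

#' @export
print.nbs_outcome <- function(x, ...) {
  cat(sprintf("outcome: cost %.2f (undisc %.2f), QALY %.6f, LY %.6f\n",
              x$discounted_cost, x$undiscounted_cost,
              x$discounted_qaly, x$discounted_ly))
  invisible(x)
}

outcome_zero <- function(n_years) {
  new_outcome(0, 0, 0, 0, 0, 0, rep(0, n_years))
}

pad_to <- function(v, n) c(v, rep(0, max(0L, n - length(v))))

outcome_add <- function(a, b) {
  n <- max(length(a$yearly_undiscounted_costs), length(b$yearly_undiscounted_costs))
  new_outcome(a$discounted_cost + b$discounted_cost,
              a$discounted_qaly + b$discounted_qaly,
              a$discounted_ly + b$discounted_ly,
              a$undiscounted_cost + b$undiscounted_cost,
              a$undiscounted_qaly + b$undiscounted_qaly,
              a$undiscounted_ly + b$undiscounted_ly,
              pad_to(a$yearly_undiscounted_costs, n) +
                pad_to(b$yearly_undiscounted_costs, n))
}

outcome_scale <- function(a, s) {
  new_outcome(a$discounted_cost * s, a$discounted_qaly * s, a$discounted_ly * s,
              a$undiscounted_cost * s, a$undiscounted_qaly * s,
              a$undiscounted_ly * s, a$yearly_undiscounted_costs * s)
}

n_cycles_for <- function(model, horizon_years) {
  k <- horizon_years / model$cycle_length_years
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("horizon %g years is not an integer multiple of cycle length %g",
                 horizon_years, model$cycle_length_years), call. = FALSE)
  }
  as.integer(round(k))
}

# Occupancy row index of the last cycle boundary at or before time t.
boundary_index <- function(t, cycle, n_rows) {
  min(n_rows, floor(t / cycle + 1e-9) + 1L)
}

#' Run a deterministic Markov cohort simulation
#'
#' Propagates the cohort distribution through the transition matrix and
#' accumulates discounted and undiscounted costs, QALYs and life-years.
#' Accrual is beginning-of-cycle: state membership at the start of cycle `k`
#' (time `t_k = k * cycle_length`) earns that cycle's utility and cost,
#' discounted by [discount_factor()] at `t_k`. Life-years accrue in all
#' non-death states. One-off costs at time `t` are charged as
#' `amount * (fraction alive at t) * discount_factor(t)`, where the alive
#' fraction is read from the last cycle boundary at or before `t`; events at
#' or beyond the horizon are not charged. Undiscounted costs are also
#' aggregated by calendar year (`floor(t)`), which is the input the
#' budget-impact module consumes.
#'
#' An optional half-cycle correction (averaging start- and end-of-cycle
#' occupancy, discounted at mid-cycle) is available but off by default; all
#' shipped fixtures use the beginning-of-cycle convention.
#'
#' @param model A valid [markov_model()].
#' @param horizon_years Simulation horizon; integer multiple of the cycle
#'   length.
#' @param rate_annual Annual discount rate (fraction).
#' @param half_cycle_correction Logical, default `FALSE`.
#' @return List with `trace` (class `markov_trace`: `occupancy` matrix with
#'   one row per cycle boundary, `times_years`) and `outcome`
#'   (class `nbs_outcome`).
#' @export
run_cohort <- function(model, horizon_years, rate_annual,
                       half_cycle_correction = FALSE) {
  stopifnot(inherits(model, "markov_model"))
  rep <- validate_model(model)
  if (!is_valid(rep)) {
    stop("invalid model:\n", paste0("  - ", rep, collapse = "\n"), call. = FALSE)
  }
  if (!is.numeric(horizon_years) || length(horizon_years) != 1L || horizon_years <= 0) {
    stop("horizon_years must be a single positive number", call. = FALSE)
  }
  n_cyc <- n_cycles_for(model, horizon_years)
  cl <- model$cycle_length_years
  n <- length(model$states)
  P <- model$transition_matrix

  occ <- matrix(0, nrow = n_cyc + 1L, ncol = n,
                dimnames = list(NULL, state_ids(model)))
  occ[1L, ] <- model$initial_distribution
  for (k in seq_len(n_cyc)) {
    occ[k + 1L, ] <- occ[k, ] %*% P
  }
  times <- (0:n_cyc) * cl

  util <- state_field(model, "annual_utility")
  cost <- state_field(model, "annual_cost")
  alive <- as.numeric(!death_mask(model))

  if (half_cycle_correction) {
    w <- (occ[seq_len(n_cyc), , drop = FALSE] +
            occ[seq_len(n_cyc) + 1L, , drop = FALSE]) / 2
    t_acc <- times[seq_len(n_cyc)] + cl / 2
  } else {
    w <- occ[seq_len(n_cyc), , drop = FALSE]
    t_acc <- times[seq_len(n_cyc)]
  }
  df <- discount_factor(t_acc, rate_annual)

  cost_rate <- as.numeric(w %*% cost) * cl    # cost accrued in each cycle
  qaly_rate <- as.numeric(w %*% util) * cl
  ly_rate <- as.numeric(w %*% alive) * cl

  d_cost <- sum(cost_rate * df)
  d_qaly <- sum(qaly_rate * df)
  d_ly <- sum(ly_rate * df)
  u_cost <- sum(cost_rate)
  u_qaly <- sum(qaly_rate)
  u_ly <- sum(ly_rate)

  n_years <- as.integer(ceiling(horizon_years - 1e-9))
  yearly <- rep(0, n_years)
  yr <- pmin(n_years, floor(t_acc + 1e-9) + 1L)
  for (k in seq_len(n_cyc)) yearly[yr[k]] <- yearly[yr[k]] + cost_rate[k]

  if (nrow(model$one_off_costs)) {
    for (i in seq_len(nrow(model$one_off_costs))) {
      t_ev <- model$one_off_costs$time_years[i]
      amt <- model$one_off_costs$amount[i]
      if (t_ev >= horizon_years - 1e-9 && t_ev > 0) next
      idx <- boundary_index(t_ev, cl, n_cyc + 1L)
      frac_alive <- sum(occ[idx, ] * alive)
      d_cost <- d_cost + amt * frac_alive * discount_factor(t_ev, rate_annual)
      u_cost <- u_cost + amt * frac_alive
      y <- pmin(n_years, floor(t_ev + 1e-9) + 1L)
      yearly[y] <- yearly[y] + amt * frac_alive
    }
  }

  trace <- structure(list(occupancy = occ, times_years = times,
                          state_ids = state_ids(model)),
                     class = "markov_trace")
  list(trace = trace,
       outcome = new_outcome(d_cost, d_qaly, d_ly, u_cost, u_qaly, u_ly, yearly))
}

#' Microsimulation oracle for the cohort engine
#'
#' Samples `n_individuals` independent state paths through the model and
#' averages per-individual outcomes computed with the same accrual and
#' discounting conventions as [run_cohort()]. By the law of large numbers the
#' mean converges to the cohort result; the returned standard errors support
#' agreement checks at a few SE. Intended for small models in tests -- the
#' cohort engine itself never samples.
#'
#' @param model A valid [markov_model()].
#' @param horizon_years Horizon (integer multiple of cycle length).
#' @param rate_annual Annual discount rate.
#' @param n_individuals Number of simulated paths (>= 1).
#' @param seed RNG seed for reproducibility.
#' @return List with `outcome` (mean outcome, class `nbs_outcome`) and `se`
#'   (standard errors of the discounted cost/QALY/LY means).
#' @export
brute_force_oracle <- function(model, horizon_years, rate_annual,
                               n_individuals, seed) {
  stopifnot(inherits(model, "markov_model"))
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 1) {
    stop("n_individuals must be >= 1", call. = FALSE)
  }
  n_ind <- as.integer(n_individuals)
  rep <- validate_model(model)
  if (!is_valid(rep)) {
    stop("invalid model:\n", paste0("  - ", rep, collapse = "\n"), call. = FALSE)
  }
  n_cyc <- n_cycles_for(model, horizon_years)
  cl <- model$cycle_length_years
  n <- length(model$states)
  P <- model$transition_matrix

  set.seed(seed)
  # paths[i, k] = state of individual i at cycle boundary k-1
  paths <- matrix(0L, nrow = n_ind, ncol = n_cyc + 1L)
  paths[, 1L] <- sample.int(n, n_ind, replace = TRUE,
                            prob = model$initial_distribution)
  for (k in seq_len(n_cyc)) {
    cur <- paths[, k]
    nxt <- integer(n_ind)
    for (s in unique(cur)) {
      idx <- which(cur == s)
      nxt[idx] <- sample.int(n, length(idx), replace = TRUE, prob = P[s, ])
    }
    paths[, k + 1L] <- nxt
  }

  util <- state_field(model, "annual_utility")
  cost <- state_field(model, "annual_cost")
  alive <- as.numeric(!death_mask(model))
  t_acc <- (seq_len(n_cyc) - 1L) * cl
  df <- discount_factor(t_acc, rate_annual)

  d_cost <- d_qaly <- d_ly <- u_cost <- u_qaly <- u_ly <- numeric(n_ind)
  for (k in seq_len(n_cyc)) {
    s <- paths[, k]
    d_cost <- d_cost + cost[s] * cl * df[k]
    d_qaly <- d_qaly + util[s] * cl * df[k]
    d_ly <- d_ly + alive[s] * cl * df[k]
    u_cost <- u_cost + cost[s] * cl
    u_qaly <- u_qaly + util[s] * cl
    u_ly <- u_ly + alive[s] * cl
  }

  n_years <- as.integer(ceiling(horizon_years - 1e-9))
  yearly <- rep(0, n_years)
  yr <- pmin(n_years, floor(t_acc + 1e-9) + 1L)
  cost_by_cycle <- vapply(seq_len(n_cyc),
                          function(k) mean(cost[paths[, k]]) * cl, numeric(1))
  for (k in seq_len(n_cyc)) yearly[yr[k]] <- yearly[yr[k]] + cost_by_cycle[k]

  if (nrow(model$one_off_costs)) {
    for (i in seq_len(nrow(model$one_off_costs))) {
      t_ev <- model$one_off_costs$time_years[i]
      amt <- model$one_off_costs$amount[i]
      if (t_ev >= horizon_years - 1e-9 && t_ev > 0) next
      idx <- boundary_index(t_ev, cl, n_cyc + 1L)
      is_alive <- alive[paths[, idx]]
      d_cost <- d_cost + amt * is_alive * discount_factor(t_ev, rate_annual)
      u_cost <- u_cost + amt * is_alive
      y <- pmin(n_years, floor(t_ev + 1e-9) + 1L)
      yearly[y] <- yearly[y] + amt * mean(is_alive)
    }
  }

  se <- function(x) stats::sd(x) / sqrt(n_ind)
  list(outcome = new_outcome(mean(d_cost), mean(d_qaly), mean(d_ly),
                             mean(u_cost), mean(u_qaly), mean(u_ly), yearly),
       se = list(discounted_cost = se(d_cost),
                 discounted_qaly = se(d_qaly),
                 discounted_ly = se(d_ly)))
}
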