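#' Define a health state
#'
#' A health state carries the utility weight and running cost earned by cohort
#' members occupying it. Utilities and costs are specified *per year* and are
#' scaled by the model's cycle length internally, so models with different
#' cycle lengths (e.g. 6-month SMA cycles vs 3-month SCID cycles) stay
#' comparable.
#'
#' @param id Short unique key (string).
#' @param name Free-text label; defaults to `id`.
#' @param annual_utility QALY weight per year alive in the state, in `[-1, 1]`.
#' @param annual_cost Cost accrued per year in the state (nominal currency
#'   units; reported as USD 2018 by the CLI).
#' @param is_absorbing Logical; an absorbing state keeps all of its occupancy.
#' @param is_death Logical; death states accrue no life-years, must be
#'   absorbing, and must have zero utility and cost.
#' @return An object of class `health_state`.
#' @export
#' @examples
#' health_state("well", annual_utility = 1)
health_state <- function(id, name = id, annual_utility = 0, annual_cost = 0,
                         is_absorbing = FALSE, is_death = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(name), length(name) == 1L,
            is.numeric(annual_utility), length(annual_utility) == 1L,
            is.numeric(annual_cost), length(annual_cost) == 1L,
            is.logical(is_absorbing), length(is_absorbing) == 1L,
            is.logical(is_death), length(is_death) == 1L)
  structure(
    list(id = id, name = name,
         annual_utility = as.numeric(annual_utility),
         annual_cost = as.numeric(annual_cost),
         is_absorbing = isTRUE(is_absorbing),
         is_death = isTRUE(is_death)),
    class = "health_state")
}

#' Define a Markov cohort model
#'
#' The simulable unit: an ordered set of health states, a constant (time
#' homogeneous) per-cycle transition matrix, and optional one-off costs
#' attached to calendar times. One-off costs (e.g. a gene-therapy infusion at
#' entry, a transplant at six months) are charged to the fraction of the
#' cohort alive -- i.e. not in a death state -- at the event time.
#'
#' @param states List of [health_state()] objects; column/row order of
#'   `transition_matrix` follows this order.
#' @param transition_matrix Square numeric matrix of per-cycle transition
#'   probabilities, row = from, column = to. Rows must sum to 1.
#' @param cycle_length_years Positive cycle length in years (0.5 for the SMA
#'   models, 0.25 for SCID).
#' @param initial_distribution Probability vector over states at time 0.
#'   Defaults to all mass in the first state.
#' @param one_off_costs Data frame with columns `time_years` and `amount`, or
#'   `NULL` for none.
#' @param label Free-text model label.
#' @return An object of class `markov_model`.
#' @seealso [validate_model()], [run_cohort()]
#' @export
markov_model <- function(states, transition_matrix, cycle_length_years,
                         initial_distribution = NULL, one_off_costs = NULL,
                         label = "") {
  stopifnot(is.list(states), length(states) >= 1L,
            all(vapply(states, inherits, logical(1), "health_state")),
            is.matrix(transition_matrix), is.numeric(transition_matrix),
            is.numeric(cycle_length_years), length(cycle_length_years) == 1L,
            is.character(label), length(label) == 1L)
  n <- length(states)
  if (is.null(initial_distribution)) {
    initial_distribution <- c(1, rep(0, n - 1L))
  }
  stopifnot(is.numeric(initial_distribution), length(initial_distribution) == n)
  if (is.null(one_off_costs)) {
    one_off_costs <- data.frame(time_years = numeric(0), amount = numeric(0))
  }
  stopifnot(is.data.frame(one_off_costs),
            all(c("time_years", "amount") %in% names(one_off_costs)))
  one_off_costs <- one_off_costs[, c("time_years", "amount"), drop = FALSE]
  ids <- vapply(states, `[[`, character(1), "id")
  dimnames(transition_matrix) <- list(ids, ids)
  names(initial_distribution) <- ids
  structure(
    list(states = states,
         transition_matrix = transition_matrix,
         cycle_length_years = as.numeric(cycle_length_years),
         initial_distribution = as.numeric(stats::setNames(initial_distribution, ids)),
         one_off_costs = one_off_costs,
         label = label),
    class = "markov_model")
}

state_ids <- function(model) vapply(model$states, `[[`, character(1), "id")
state_field <- function(model, field) vapply(model$states, `[[`, numeric(1), field)
death_mask <- function(model) vapply(model$states, `[[`, logical(1), "is_death")
absorbing_mask <- function(model) vapply(model$states, `[[`, logical(1), "is_absorbing")

PROB_TOL <- 1e-9

#' Validate a Markov model
#'
#' Report-style validation: returns a character vector of violated invariants
#' (empty means valid) and never raises or mutates. Checked invariants:
#' unique state ids; utilities in `[-1, 1]`; death implies absorbing; death
#' states carry zero utility and cost; transition rows are probability vectors
#' summing to 1 within 1e-9; absorbing rows are identity rows; the initial
#' distribution is a probability vector; positive cycle length; non-negative
#' one-off event times.
#'
#' @param model A [markov_model()].
#' @return Character vector of violation messages, class `validation_report`.
#' @export
#' @examples
#' m <- markov_model(
#'   list(health_state("well", annual_utility = 1),
#'        health_state("dead", is_absorbing = TRUE, is_death = TRUE)),
#'   matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE), 1)
#' validate_model(m)  # character(0)
validate_model <- function(model) {
  stopifnot(inherits(model, "markov_model"))
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)

  ids <- state_ids(model)
  if (anyDuplicated(ids)) note("state ids are not unique")
  for (s in model$states) {
    if (s$annual_utility < -1 || s$annual_utility > 1) {
      note(sprintf("state '%s': annual_utility %.4g outside [-1, 1]", s$id, s$annual_utility))
    }
    if (s$is_death && !s$is_absorbing) {
      note(sprintf("state '%s': death state must be absorbing", s$id))
    }
    if (s$is_death && s$annual_utility != 0) {
      note(sprintf("state '%s': death state must have zero utility", s$id))
    }
    if (s$is_death && s$annual_cost != 0) {
      note(sprintf("state '%s': death state must have zero cost", s$id))
    }
  }

  P <- model$transition_matrix
  n <- length(model$states)
  if (!all(dim(P) == c(n, n))) {
    note(sprintf("transition matrix is %dx%d, expected %dx%d",
                 nrow(P), ncol(P), n, n))
  } else {
    if (any(P < 0 | P > 1)) note("transition probabilities outside [0, 1]")
    rs <- rowSums(P)
    off <- which(abs(rs - 1) > PROB_TOL)
    for (i in off) note(sprintf("row %d ('%s') sums to %.10f, not 1", i, ids[i], rs[i]))
    for (i in which(absorbing_mask(model))) {
      e <- replace(rep(0, n), i, 1)
      if (any(abs(P[i, ] - e) > PROB_TOL)) {
        note(sprintf("absorbing state '%s' does not have an identity row", ids[i]))
      }
    }
  }

  d <- model$initial_distribution
  if (any(d < -PROB_TOL)) note("initial distribution has negative entries")
  if (abs(sum(d) - 1) > PROB_TOL) {
    note(sprintf("initial distribution sums to %.10f, not 1", sum(d)))
  }

  if (!(model$cycle_length_years > 0)) note("cycle_length_years must be positive")
  if (nrow(model$one_off_costs) && any(model$one_off_costs$time_years < 0)) {
    note("one-off cost with negative event time")
  }

  structure(bad, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0) cat("valid: no invariant violations\n")
  else cat(paste0("- ", x, collapse = "\n"), "\n")
  invisible(x)
}

#' Is a validation report clean?
#' @param report A `validation_report` from [validate_model()].
#' @return `TRUE` when no invariant is violated.
#' @export
is_valid <- function(report) length(report) == 0L

#' Define a chance branch of a strategy
#'
#' A branch pairs an incidence probability with the Markov model followed by
#' newborns on that branch. `model = NULL` denotes a zero-outcome branch:
#' members accrue no modelled costs, QALYs or life-years. This is how
#' unaffected newborns are represented -- per-newborn expected outcomes then
#' reflect only the modelled conditions, which is why population-level QALYs
#' per newborn are of order 1e-4.
#'
#' @param probability Branch probability in `[0, 1]` (e.g. an SMA incidence
#'   of 1/11,000 live births).
#' @param model A [markov_model()] or `NULL`.
#' @param label Free-text label.
#' @return Object of class `chance_branch`.
#' @export
chance_branch <- function(probability, model = NULL, label = "") {
  stopifnot(is.numeric(probability), length(probability) == 1L,
            probability >= 0, probability <= 1,
            is.null(model) || inherits(model, "markov_model"),
            is.character(label), length(label) == 1L)
  structure(list(probability = as.numeric(probability), model = model,
                 label = label),
            class = "chance_branch")
}

#' Define a screening strategy
#'
#' @param name Strategy name (e.g. "future NBS with SMA and SCID").
#' @param branches List of [chance_branch()]; probabilities must sum to 1.
#' @param fixed_per_person_cost Cost charged at time zero to every person
#'   entering the strategy (the screening test cost); must be non-negative.
#' @return Object of class `nbs_strategy`.
#' @export
strategy <- function(name, branches, fixed_per_person_cost = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.list(branches), length(branches) >= 1L,
            all(vapply(branches, inherits, logical(1), "chance_branch")),
            is.numeric(fixed_per_person_cost), length(fixed_per_person_cost) == 1L)
  structure(list(name = name, branches = branches,
                 fixed_per_person_cost = as.numeric(fixed_per_person_cost)),
            class = "nbs_strategy")
}

#' Define a decision tree
#'
#' The top-level comparison: two or more strategies, a common annual discount
#' rate, and a time horizon that must be an integer multiple of every member
#' model's cycle length.
#'
#' @param strategies List of [strategy()] objects (at least 2 for a
#'   comparison; a single strategy is allowed for plain evaluation).
#' @param discount_rate_annual Annual discount rate as a fraction (0.03).
#' @param horizon_years Time horizon in years (5 or 60 in the shipped
#'   fixtures).
#' @return Object of class `decision_tree`.
#' @export
decision_tree <- function(strategies, discount_rate_annual = 0.03,
                          horizon_years) {
  stopifnot(is.list(strategies), length(strategies) >= 1L,
            all(vapply(strategies, inherits, logical(1), "nbs_strategy")),
            is.numeric(discount_rate_annual), length(discount_rate_annual) == 1L,
            is.numeric(horizon_years), length(horizon_years) == 1L)
  tree <- structure(
    list(strategies = strategies,
         discount_rate_annual = as.numeric(discount_rate_annual),
         horizon_years = as.numeric(horizon_years)),
    class = "decision_tree")
  rep <- validate_tree(tree)
  if (!is_valid(rep)) {
    stop("invalid decision tree:\n", paste0("  - ", rep, collapse = "\n"),
         call. = FALSE)
  }
  tree
}

#' Validate a decision tree
#'
#' Checks tree-level invariants (non-negative discount rate and fixed costs,
#' positive horizon, horizon divisible by every cycle length, branch
#' probabilities summing to 1 per strategy, unique strategy names) and folds
#' in every member model's [validate_model()] report.
#'
#' @param tree A `decision_tree` (or the bare list before construction).
#' @return A `validation_report` character vector.
#' @export
validate_tree <- function(tree) {
  bad <- character(0)
  note <- function(msg) bad <<- c(bad, msg)
  if (tree$discount_rate_annual < 0) note("discount_rate_annual must be >= 0")
  if (!(tree$horizon_years > 0)) note("horizon_years must be positive")
  nm <- vapply(tree$strategies, `[[`, character(1), "name")
  if (anyDuplicated(nm)) note("strategy names are not unique")
  for (st in tree$strategies) {
    if (st$fixed_per_person_cost < 0) {
      note(sprintf("strategy '%s': fixed_per_person_cost must be >= 0", st$name))
    }
    ps <- vapply(st$branches, `[[`, numeric(1), "probability")
    if (abs(sum(ps) - 1) > PROB_TOL) {
      note(sprintf("strategy '%s': branch probabilities sum to %.10f, not 1",
                   st$name, sum(ps)))
    }
    for (br in st$branches) {
      if (is.null(br$model)) next
      k <- tree$horizon_years / br$model$cycle_length_years
      if (abs(k - round(k)) > PROB_TOL) {
        note(sprintf(
          "strategy '%s', branch '%s': horizon %g is not an integer multiple of cycle length %g",
          st$name, br$label, tree$horizon_years, br$model$cycle_length_years))
      }
      mrep <- validate_model(br$model)
      if (!is_valid(mrep)) {
        note(sprintf("strategy '%s', branch '%s' model '%s': %s",
                     st$name, br$label, br$model$label,
                     paste(mrep, collapse = "; ")))
      }
    }
  }
  structure(bad, class = "validation_report")
}

# ---- spec file (YAML / JSON) schema -----------------------------------------

check_keys <- function(x, allowed, required, context) {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown)) {
    stop(sprintf("%s: unknown key(s): %s", context,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("%s: missing required key(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

state_from_list <- function(x, context) {
  check_keys(x, c("id", "name", "annual_utility", "annual_cost",
                  "is_absorbing", "is_death"),
             c("id"), context)
  health_state(id = x$id,
               name = if (is.null(x$name)) x$id else x$name,
               annual_utility = x$annual_utility %||% 0,
               annual_cost = x$annual_cost %||% 0,
               is_absorbing = isTRUE(x$is_absorbing),
               is_death = isTRUE(x$is_death))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

model_from_list <- function(x, context) {
  check_keys(x, c("label", "cycle_length_years", "states", "transition_matrix",
                  "initial_distribution", "one_off_costs"),
             c("cycle_length_years", "states", "transition_matrix",
               "initial_distribution"), context)
  states <- lapply(seq_along(x$states), function(i) {
    state_from_list(x$states[[i]], sprintf("%s: states[%d]", context, i))
  })
  n <- length(states)
  rows <- x$transition_matrix
  if (length(rows) != n) {
    stop(sprintf("%s: transition_matrix has %d rows, expected %d",
                 context, length(rows), n), call. = FALSE)
  }
  P <- do.call(rbind, lapply(rows, function(r) as.numeric(unlist(r))))
  if (ncol(P) != n) {
    stop(sprintf("%s: transition_matrix rows must have %d entries", context, n),
         call. = FALSE)
  }
  ooc <- NULL
  if (!is.null(x$one_off_costs) && length(x$one_off_costs)) {
    ooc <- do.call(rbind, lapply(seq_along(x$one_off_costs), function(i) {
      e <- x$one_off_costs[[i]]
      check_keys(e, c("time_years", "amount"), c("time_years", "amount"),
                 sprintf("%s: one_off_costs[%d]", context, i))
      data.frame(time_years = as.numeric(e$time_years),
                 amount = as.numeric(e$amount))
    }))
  }
  markov_model(states = states, transition_matrix = P,
               cycle_length_years = as.numeric(x$cycle_length_years),
               initial_distribution = as.numeric(unlist(x$initial_distribution)),
               one_off_costs = ooc,
               label = x$label %||% "")
}

branch_from_list <- function(x, context) {
  check_keys(x, c("probability", "model", "label"), c("probability"), context)
  model <- if (is.null(x$model)) NULL else model_from_list(x$model, paste0(context, ": model"))
  chance_branch(probability = as.numeric(x$probability), model = model,
                label = x$label %||% "")
}

strategy_from_list <- function(x, context) {
  check_keys(x, c("name", "fixed_per_person_cost", "branches"),
             c("name", "branches"), context)
  branches <- lapply(seq_along(x$branches), function(i) {
    branch_from_list(x$branches[[i]], sprintf("%s: branches[%d]", context, i))
  })
  strategy(name = x$name, branches = branches,
           fixed_per_person_cost = as.numeric(x$fixed_per_person_cost %||% 0))
}

#' Load a decision-tree specification file
#'
#' Reads a YAML (`.yaml`/`.yml`) or JSON (`.json`) model specification into a
#' validated [decision_tree()]. Unknown keys are rejected at every level --
#' a silent typo in a probability name is the dominant configuration failure
#' mode. Transition matrices are given row-major, ordered as `states`, and
#' must be constant over time (the schema has no time-varying form).
#'
#' @param path Path to the specification file.
#' @return A validated `decision_tree`.
#' @seealso [write_spec()] for the inverse; the package vignette documents the
#'   schema.
#' @export
load_spec <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("spec file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported spec extension '.", ext, "' (use .yaml, .yml or .json)",
         call. = FALSE))
  check_keys(raw, c("discount_rate_annual", "horizon_years", "strategies"),
             c("discount_rate_annual", "horizon_years", "strategies"),
             basename(path))
  strategies <- lapply(seq_along(raw$strategies), function(i) {
    strategy_from_list(raw$strategies[[i]], sprintf("strategies[%d]", i))
  })
  # decision_tree() runs validate_tree() and stops with the violation list
  decision_tree(strategies = strategies,
                discount_rate_annual = as.numeric(raw$discount_rate_annual),
                horizon_years = as.numeric(raw$horizon_years))
}

state_to_list <- function(s) {
  list(id = s$id, name = s$name, annual_utility = s$annual_utility,
       annual_cost = s$annual_cost, is_absorbing = s$is_absorbing,
       is_death = s$is_death)
}

model_to_list <- function(m) {
  list(label = m$label,
       cycle_length_years = m$cycle_length_years,
       states = lapply(m$states, state_to_list),
       transition_matrix = lapply(seq_len(nrow(m$transition_matrix)),
                                  function(i) as.numeric(m$transition_matrix[i, ])),
       initial_distribution = as.numeric(m$initial_distribution),
       one_off_costs = if (nrow(m$one_off_costs) == 0) list() else
         lapply(seq_len(nrow(m$one_off_costs)), function(i) {
           list(time_years = m$one_off_costs$time_years[i],
                amount = m$one_off_costs$amount[i])
         }))
}

tree_to_list <- function(tree) {
  list(discount_rate_annual = tree$discount_rate_annual,
       horizon_years = tree$horizon_years,
       strategies = lapply(tree$strategies, function(st) {
         list(name = st$name,
              fixed_per_person_cost = st$fixed_per_person_cost,
              branches = lapply(st$branches, function(br) {
                list(probability = br$probability,
                     label = br$label,
                     model = if (is.null(br$model)) NULL else model_to_list(br$model))
              }))
       }))
}

#' Write a decision tree to a specification file
#'
#' Inverse of [load_spec()]: `load_spec(write_spec(tree, path))` reproduces
#' the tree field by field. Format follows the file extension (YAML or JSON).
#'
#' @param tree A `decision_tree`.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_spec <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  ext <- tolower(tools::file_ext(path))
  x <- tree_to_list(tree)
  switch(ext,
    yaml = , yml = yaml::write_yaml(x, path, precision = 15L),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                                null = "null", pretty = TRUE),
    stop("unsupported spec extension '.", ext, "'", call. = FALSE))
  invisible(path)
}
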