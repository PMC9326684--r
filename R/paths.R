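# Parameter paths
#
# PSA and one-way sensitivity analysis address individual numbers inside a
# decision tree by a dotted path, e.g.
#   strategies[1].fixed_per_person_cost
#   strategies[future NBS].branches[sma].probability
#   strategies[2].branches[1].model.states[3].annual_cost
#   strategies[1].branches[1].model.transition_matrix[2,3]
#   strategies[1].branches[1].model.one_off_costs[1].amount
# Indices are 1-based integers or (for strategies/branches/states) the
# strategy name, branch label or state id.

split_path <- function(path) {
  stopifnot(is.character(path), length(path) == 1L, nzchar(path))
  tokens <- character(0)
  depth <- 0L
  cur <- ""
  for (ch in strsplit(path, "")[[1]]) {
    if (ch == "[") depth <- depth + 1L
    if (ch == "]") depth <- depth - 1L
    if (ch == "." && depth == 0L) {
      tokens <- c(tokens, cur); cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  c(tokens, cur)
}

parse_token <- function(tok, path) {
  m <- regmatches(tok, regexec("^([a-zA-Z_][a-zA-Z0-9_]*)(\\[(.+)\\])?$", tok))[[1]]
  if (length(m) == 0) {
    stop(sprintf("cannot parse path component '%s' in '%s'", tok, path),
         call. = FALSE)
  }
  idx <- if (nzchar(m[4])) trimws(strsplit(m[4], ",", fixed = TRUE)[[1]]) else character(0)
  list(field = m[2], index = idx)
}

match_index <- function(idx, items, labels, what, path) {
  num <- suppressWarnings(as.integer(idx))
  if (!is.na(num)) {
    if (num < 1L || num > length(items)) {
      stop(sprintf("%s index %d out of range in '%s'", what, num, path),
           call. = FALSE)
    }
    return(num)
  }
  hit <- which(labels == idx)
  if (length(hit) != 1L) {
    stop(sprintf("%s '%s' not found (or ambiguous) in '%s'", what, idx, path),
         call. = FALSE)
  }
  hit
}

# Walk to the parent of the addressed value; returns a list of index chains
# so tree_set can assign without deparse/eval tricks.
resolve_path <- function(tree, path) {
  toks <- lapply(split_path(path), parse_token, path = path)
  steps <- list()   # each: list(key = <[[ key>, matrix = c(i, j) or NULL)
  node <- tree
  expect_one_index <- function(tk) {
    if (length(tk$index) != 1L) {
      stop(sprintf("'%s' needs exactly one index in '%s'", tk$field, path),
           call. = FALSE)
    }
  }
  i <- 1L
  while (i <= length(toks)) {
    tk <- toks[[i]]
    if (inherits(node, "decision_tree")) {
      if (tk$field == "strategies") {
        expect_one_index(tk)
        j <- match_index(tk$index, node$strategies,
                         vapply(node$strategies, `[[`, character(1), "name"),
                         "strategy", path)
        steps <- c(steps, list(list(key = "strategies"), list(key = j)))
        node <- node$strategies[[j]]
      } else if (tk$field %in% c("discount_rate_annual", "horizon_years")) {
        steps <- c(steps, list(list(key = tk$field)))
        node <- node[[tk$field]]
      } else {
        stop(sprintf("unknown tree field '%s' in '%s'", tk$field, path),
             call. = FALSE)
      }
    } else if (inherits(node, "nbs_strategy")) {
      if (tk$field == "branches") {
        expect_one_index(tk)
        j <- match_index(tk$index, node$branches,
                         vapply(node$branches, `[[`, character(1), "label"),
                         "branch", path)
        steps <- c(steps, list(list(key = "branches"), list(key = j)))
        node <- node$branches[[j]]
      } else if (tk$field == "fixed_per_person_cost") {
        steps <- c(steps, list(list(key = tk$field)))
        node <- node[[tk$field]]
      } else {
        stop(sprintf("unknown strategy field '%s' in '%s'", tk$field, path),
             call. = FALSE)
      }
    } else if (inherits(node, "chance_branch")) {
      if (tk$field == "model") {
        if (is.null(node$model)) {
          stop(sprintf("branch has no model in '%s'", path), call. = FALSE)
        }
        steps <- c(steps, list(list(key = "model")))
        node <- node$model
      } else if (tk$field == "probability") {
        steps <- c(steps, list(list(key = tk$field)))
        node <- node[[tk$field]]
      } else {
        stop(sprintf("unknown branch field '%s' in '%s'", tk$field, path),
             call. = FALSE)
      }
    } else if (inherits(node, "markov_model")) {
      if (tk$field == "states") {
        expect_one_index(tk)
        j <- match_index(tk$index, node$states,
                         vapply(node$states, `[[`, character(1), "id"),
                         "state", path)
        steps <- c(steps, list(list(key = "states"), list(key = j)))
        node <- node$states[[j]]
      } else if (tk$field == "transition_matrix") {
        if (length(tk$index) != 2L) {
          stop(sprintf("transition_matrix needs [row,col] in '%s'", path),
               call. = FALSE)
        }
        ij <- suppressWarnings(as.integer(tk$index))
        n <- nrow(node$transition_matrix)
        if (any(is.na(ij)) || any(ij < 1L) || any(ij > n)) {
          stop(sprintf("transition_matrix index out of range in '%s'", path),
               call. = FALSE)
        }
        steps <- c(steps, list(list(key = "transition_matrix", matrix = ij)))
        node <- node$transition_matrix[ij[1], ij[2]]
      } else if (tk$field == "one_off_costs") {
        expect_one_index(tk)
        j <- suppressWarnings(as.integer(tk$index))
        if (is.na(j) || j < 1L || j > nrow(node$one_off_costs)) {
          stop(sprintf("one_off_costs index out of range in '%s'", path),
               call. = FALSE)
        }
        if (i == length(toks)) {
          stop(sprintf("one_off_costs[%d] needs a trailing .time_years or .amount in '%s'",
                       j, path), call. = FALSE)
        }
        nxt <- toks[[i + 1L]]
        if (!nxt$field %in% c("time_years", "amount")) {
          stop(sprintf("unknown one-off field '%s' in '%s'", nxt$field, path),
               call. = FALSE)
        }
        steps <- c(steps, list(list(key = "one_off_costs", frame = c(j, nxt$field))))
        node <- node$one_off_costs[[nxt$field]][j]
        i <- i + 1L
      } else if (tk$field == "initial_distribution") {
        expect_one_index(tk)
        j <- suppressWarnings(as.integer(tk$index))
        if (is.na(j) || j < 1L || j > length(node$initial_distribution)) {
          stop(sprintf("initial_distribution index out of range in '%s'", path),
               call. = FALSE)
        }
        steps <- c(steps, list(list(key = "initial_distribution", vec = j)))
        node <- node$initial_distribution[j]
      } else if (tk$field %in% c("cycle_length_years")) {
        steps <- c(steps, list(list(key = tk$field)))
        node <- node[[tk$field]]
      } else {
        stop(sprintf("unknown model field '%s' in '%s'", tk$field, path),
             call. = FALSE)
      }
    } else if (inherits(node, "health_state")) {
      if (!tk$field %in% c("annual_utility", "annual_cost")) {
        stop(sprintf("unknown state field '%s' in '%s'", tk$field, path),
             call. = FALSE)
      }
      steps <- c(steps, list(list(key = tk$field)))
      node <- node[[tk$field]]
    } else {
      stop(sprintf("path '%s' descends past a terminal value", path),
           call. = FALSE)
    }
    i <- i + 1L
  }
  if (!is.numeric(node) || length(node) != 1L) {
    stop(sprintf("path '%s' does not address a single numeric value", path),
         call. = FALSE)
  }
  list(steps = steps, value = as.numeric(node))
}

assign_steps <- function(obj, steps, value) {
  if (length(steps) == 0L) return(value)
  st <- steps[[1L]]
  if (!is.null(st$matrix)) {
    obj[[st$key]][st$matrix[1], st$matrix[2]] <- value
    return(obj)
  }
  if (!is.null(st$vec)) {
    obj[[st$key]][st$vec] <- value
    return(obj)
  }
  if (!is.null(st$frame)) {
    j <- as.integer(st$frame[1])
    obj[[st$key]][[st$frame[2]]][j] <- value
    return(obj)
  }
  obj[[st$key]] <- assign_steps(obj[[st$key]], steps[-1L], value)
  obj
}

#' Read a parameter value from a decision tree by path
#'
#' @param tree A `decision_tree`.
#' @param path Dotted parameter path (see [tree_set_param()] for the
#'   grammar).
#' @return The addressed numeric value.
#' @export
tree_get <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  resolve_path(tree, path)$value
}

# Condition signalled when a transition-row rebalance is infeasible; run_psa
# catches it and resamples the draw.
invalid_row_error <- function(msg) {
  structure(class = c("nbs_invalid_row", "error", "condition"),
            list(message = msg, call = NULL))
}

#' Set a parameter in a decision tree, keeping probabilities coherent
#'
#' Returns a modified copy (trees are immutable values); the base case is
#' never touched. Path grammar:
#' `strategies[i|name].branches[j|label].model.<field>`, where `<field>` is
#' `states[k|id].annual_cost` / `.annual_utility`,
#' `transition_matrix[row,col]`, `one_off_costs[k].amount` / `.time_years`,
#' `initial_distribution[k]` or `cycle_length_years`; strategy-level fields
#' `fixed_per_person_cost` and `branches[j].probability`; tree-level
#' `discount_rate_annual` and `horizon_years`.
#'
#' Probability coherence rules:
#' * setting an off-diagonal transition cell re-sets the row's diagonal to
#'   the remainder `1 - sum(off-diagonal)`; an infeasible (negative)
#'   remainder signals an error of class `nbs_invalid_row`, which the PSA
#'   turns into a reject-and-resample;
#' * setting a diagonal cell rescales the off-diagonal entries
#'   proportionally to the remaining mass;
#' * setting a branch probability rescales the sibling branches
#'   proportionally so the strategy's branches still sum to 1 (an incidence
#'   increase is absorbed by the unaffected branch).
#'
#' @param tree A `decision_tree`.
#' @param path Parameter path.
#' @param value New numeric value.
#' @return A modified `decision_tree`.
#' @export
tree_set_param <- function(tree, path, value) {
  stopifnot(inherits(tree, "decision_tree"),
            is.numeric(value), length(value) == 1L)
  res <- resolve_path(tree, path)
  steps <- res$steps
  last <- steps[[length(steps)]]

  if (!is.null(last$matrix)) {
    # locate the owning model and rebalance its row
    model_steps <- steps[-length(steps)]
    model <- tree
    for (st in model_steps) model <- model[[st$key]]
    P <- model$transition_matrix
    i <- last$matrix[1]; j <- last$matrix[2]
    if (value < 0 || value > 1) {
      stop(sprintf("transition probability %g outside [0, 1] in '%s'",
                   value, path), call. = FALSE)
    }
    if (i == j) {
      off <- setdiff(seq_len(ncol(P)), i)
      s <- sum(P[i, off])
      if (s == 0) {
        if (abs(value - 1) > PROB_TOL) {
          stop(invalid_row_error(sprintf(
            "row %d has no off-diagonal mass to rescale in '%s'", i, path)))
        }
      } else {
        P[i, off] <- P[i, off] * (1 - value) / s
      }
      P[i, j] <- value
    } else {
      P[i, j] <- value
      off <- setdiff(seq_len(ncol(P)), i)
      rem <- 1 - sum(P[i, off])
      if (rem < -PROB_TOL) {
        stop(invalid_row_error(sprintf(
          "row %d: off-diagonal mass %.6f exceeds 1 after setting '%s'",
          i, sum(P[i, off]), path)))
      }
      P[i, i] <- max(rem, 0)
    }
    model$transition_matrix <- P
    return(assign_model(tree, model_steps, model))
  }

  if (identical(last$key, "probability")) {
    branch_steps <- steps[seq_len(length(steps) - 1L)]
    strat_steps <- branch_steps[seq_len(length(branch_steps) - 2L)]
    j <- branch_steps[[length(branch_steps)]]$key
    strat <- tree
    for (st in strat_steps) strat <- strat[[st$key]]
    if (value < 0 || value > 1) {
      stop(sprintf("branch probability %g outside [0, 1] in '%s'", value, path),
           call. = FALSE)
    }
    ps <- vapply(strat$branches, `[[`, numeric(1), "probability")
    others <- setdiff(seq_along(ps), j)
    s <- sum(ps[others])
    if (s == 0) {
      if (abs(value - 1) > PROB_TOL) {
        stop(sprintf("no sibling branch can absorb probability change in '%s'",
                     path), call. = FALSE)
      }
    } else {
      for (k in others) {
        strat$branches[[k]]$probability <- ps[k] * (1 - value) / s
      }
    }
    strat$branches[[j]]$probability <- value
    return(assign_model(tree, strat_steps, strat))
  }

  assign_steps(tree, steps, value)
}

assign_model <- function(tree, steps, replacement) {
  if (length(steps) == 0L) return(replacement)
  assign_steps_obj(tree, steps, replacement)
}

assign_steps_obj <- function(obj, steps, replacement) {
  if (length(steps) == 1L) {
    obj[[steps[[1L]]$key]] <- replacement
    return(obj)
  }
  obj[[steps[[1L]]$key]] <-
    assign_steps_obj(obj[[steps[[1L]]$key]], steps[-1L], replacement)
  obj
}
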