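#' Define an uncertain parameter for sensitivity analysis
#'
#' Each spec names one uncertain quantity, the distribution it is drawn from,
#' and the tree path(s) the drawn value is written to. A single draw may be
#' applied to several paths at once -- e.g. a condition's incidence must take
#' the same sampled value in the screening and the no-screening strategy.
#'
#' Distributions are moment-matched from `(mean, spread)`: `beta` for
#' quantities with support `[0, 1]` (probabilities, utilities), `gamma` and
#' `lognormal` for non-negative quantities (costs), `uniform` with
#' `spread = c(low, high)`, and `fixed` which always returns the mean.
#'
#' @param name Identifier; also the default path.
#' @param distribution One of `"beta"`, `"gamma"`, `"lognormal"`,
#'   `"uniform"`, `"fixed"`.
#' @param mean Base-case value (distribution mean), except for `uniform`.
#' @param spread Standard error, or `c(low, high)` for `uniform`.
#' @param paths Character vector of tree paths the draw is applied to;
#'   defaults to `name`.
#' @return Object of class `parameter_spec`.
#' @export
parameter_spec <- function(name, distribution, mean = NULL, spread = NULL,
                           paths = name) {
  distribution <- match.arg(distribution,
                            c("beta", "gamma", "lognormal", "uniform", "fixed"))
  stopifnot(is.character(name), length(name) == 1L,
            is.character(paths), length(paths) >= 1L)
  if (distribution == "uniform") {
    if (is.null(spread) || length(spread) != 2L || spread[1] > spread[2]) {
      stop("uniform needs spread = c(low, high)", call. = FALSE)
    }
    if (is.null(mean)) mean <- base::mean(spread)
  } else {
    if (is.null(mean)) stop("mean is required", call. = FALSE)
    if (distribution != "fixed" && (is.null(spread) || length(spread) != 1L ||
                                    spread < 0)) {
      stop("spread must be a single non-negative standard error", call. = FALSE)
    }
  }
  spec <- structure(list(name = name, distribution = distribution,
                         mean = as.numeric(mean),
                         spread = if (is.null(spread)) NULL else as.numeric(spread),
                         paths = paths),
                    class = "parameter_spec")
  check_moments(spec)
  spec
}

check_moments <- function(spec) {
  m <- spec$mean
  v <- if (length(spec$spread) == 1L) spec$spread^2 else NULL
  switch(spec$distribution,
    beta = {
      if (m < 0 || m > 1) stop("beta mean must be in [0, 1]", call. = FALSE)
      if (v > 0) {
        if (m == 0 || m == 1) {
          stop(sprintf("'%s': beta moment matching infeasible (mean %g with positive spread)",
                       spec$name, m), call. = FALSE)
        }
        if (v >= m * (1 - m)) {
          stop(sprintf("'%s': beta spread %g too large for mean %g",
                       spec$name, spec$spread, m), call. = FALSE)
        }
      }
    },
    gamma = {
      if (m < 0) stop("gamma mean must be >= 0", call. = FALSE)
      if (v > 0 && m == 0) {
        stop(sprintf("'%s': gamma moment matching infeasible (mean 0 with positive spread)",
                     spec$name), call. = FALSE)
      }
    },
    lognormal = {
      if (m <= 0 && v > 0) {
        stop(sprintf("'%s': lognormal needs a positive mean", spec$name),
             call. = FALSE)
      }
    })
  invisible(spec)
}

draw_spec <- function(spec, n) {
  m <- spec$mean
  switch(spec$distribution,
    fixed = rep(m, n),
    uniform = stats::runif(n, spec$spread[1], spec$spread[2]),
    beta = {
      v <- spec$spread^2
      if (v == 0) return(rep(m, n))
      k <- m * (1 - m) / v - 1
      stats::rbeta(n, m * k, (1 - m) * k)
    },
    gamma = {
      v <- spec$spread^2
      if (v == 0) return(rep(m, n))
      stats::rgamma(n, shape = m^2 / v, rate = m / v)
    },
    lognormal = {
      v <- spec$spread^2
      if (v == 0) return(rep(m, n))
      s2 <- log(1 + v / m^2)
      stats::rlnorm(n, meanlog = log(m) - s2 / 2, sdlog = sqrt(s2))
    })
}

#' Sample parameter draws for a PSA
#'
#' Draws `n_iter` values for each spec, reproducibly for a given seed;
#' columns are drawn spec by spec in list order.
#'
#' @param specs List of [parameter_spec()] objects.
#' @param n_iter Number of iterations (>= 1).
#' @param seed Integer RNG seed.
#' @return Numeric matrix, `n_iter` rows, one named column per spec.
#' @export
sample_parameters <- function(specs, n_iter, seed) {
  stopifnot(is.list(specs), length(specs) >= 1L,
            all(vapply(specs, inherits, logical(1), "parameter_spec")))
  if (!is.numeric(n_iter) || length(n_iter) != 1L || n_iter < 1) {
    stop("n_iter must be >= 1", call. = FALSE)
  }
  n_iter <- as.integer(n_iter)
  set.seed(as.integer(seed))
  draws <- vapply(specs, draw_spec, numeric(n_iter), n = n_iter)
  draws <- matrix(draws, nrow = n_iter)
  colnames(draws) <- vapply(specs, `[[`, character(1), "name")
  draws
}

apply_draws <- function(tree, specs, values) {
  for (k in seq_along(specs)) {
    for (p in specs[[k]]$paths) {
      tree <- tree_set_param(tree, p, values[k])
    }
  }
  tree
}

#' Run a probabilistic sensitivity analysis
#'
#' For each Monte-Carlo iteration, the tree is rebuilt with one joint
#' parameter draw, both strategies are re-evaluated through the Markov
#' engine, and the incremental deltas are recorded. A draw that produces an
#' invalid model (e.g. a transition row whose off-diagonal mass exceeds 1
#' after sampling) is rejected and redrawn -- costs are never silently
#' clamped; the number of resampled draws is reported in `n_resampled`.
#' Resampling uses an RNG stream derived from `seed + 1`, so results are
#' reproducible regardless of how many rejections occur.
#'
#' @param tree Base-case [decision_tree()].
#' @param specs List of [parameter_spec()] objects.
#' @param n_iter Number of iterations (the shipped analyses use 1000).
#' @param seed Integer seed.
#' @param intervention,comparator Strategy names in `tree`.
#' @param horizon_years Optional horizon override.
#' @return Object of class `psa_result`: `iterations` data frame
#'   (`delta_cost`, `delta_qaly`, `delta_ly`), `seed`, `n_iter`,
#'   `n_resampled`.
#' @export
run_psa <- function(tree, specs, n_iter, seed, intervention, comparator,
                    horizon_years = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  nm <- vapply(tree$strategies, `[[`, character(1), "name")
  if (!intervention %in% nm) stop("unknown intervention strategy: ", intervention,
                                  call. = FALSE)
  if (!comparator %in% nm) stop("unknown comparator strategy: ", comparator,
                                call. = FALSE)
  draws <- sample_parameters(specs, n_iter, seed)
  n_iter <- nrow(draws)
  dc <- dq <- dl <- numeric(n_iter)
  n_resampled <- 0L

  # separate, deterministic stream for rejected draws
  resample_rng <- local({
    set.seed(as.integer(seed) + 1L)
    get(".Random.seed", envir = globalenv())
  })
  redraw <- function() {
    old <- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", resample_rng, envir = globalenv())
    v <- vapply(specs, draw_spec, numeric(1L), n = 1L)
    resample_rng <<- get(".Random.seed", envir = globalenv())
    assign(".Random.seed", old, envir = globalenv())
    v
  }

  for (i in seq_len(n_iter)) {
    vals <- draws[i, ]
    for (attempt in seq_len(100L)) {
      t2 <- tryCatch(apply_draws(tree, specs, vals), nbs_invalid_row = function(e) e)
      ok <- !inherits(t2, "condition") && is_valid(validate_tree(t2))
      if (ok) break
      n_resampled <- n_resampled + 1L
      vals <- redraw()
      if (attempt == 100L) {
        stop("PSA draw rejected 100 times; check parameter spreads", call. = FALSE)
      }
    }
    ev <- expected_values(t2, horizon_years)
    inc <- incremental(ev[[intervention]], ev[[comparator]])
    dc[i] <- inc$delta_cost; dq[i] <- inc$delta_qaly; dl[i] <- inc$delta_ly
  }
  structure(list(iterations = data.frame(delta_cost = dc, delta_qaly = dq,
                                         delta_ly = dl),
                 seed = as.integer(seed), n_iter = n_iter,
                 n_resampled = n_resampled),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %d, %d draws resampled)\n",
              x$n_iter, x$seed, x$n_resampled))
  cat(sprintf("mean deltas: cost %+.2f, QALY %+.6f, LY %+.6f\n",
              mean(x$iterations$delta_cost), mean(x$iterations$delta_qaly),
              mean(x$iterations$delta_ly)))
  invisible(x)
}

#' Proportion of PSA iterations that are cost-effective
#'
#' Fraction of iterations with positive net monetary benefit
#' `wtp * dQALY - dcost > 0`. Win-win iterations (more health at lower cost,
#' the lower-right quadrant of the CE plane) count automatically at any
#' threshold. In the `wtp = Inf` limit the criterion reduces to the fraction
#' of iterations with a QALY gain.
#'
#' @param result A `psa_result`.
#' @param wtp Willingness to pay per QALY (>= 0, may be `Inf`).
#' @return Fraction in `[0, 1]`.
#' @export
proportion_cost_effective <- function(result, wtp) {
  stopifnot(inherits(result, "psa_result"))
  if (nrow(result$iterations) == 0L) stop("empty PSA result", call. = FALSE)
  if (!is.numeric(wtp) || length(wtp) != 1L || wtp < 0) {
    stop("wtp must be a single non-negative number", call. = FALSE)
  }
  it <- result$iterations
  if (is.infinite(wtp)) return(mean(it$delta_qaly > 0))
  mean(wtp * it$delta_qaly - it$delta_cost > 0)
}

pctile <- function(x, p) {
  # inverse empirical CDF (matches an explicit full sort)
  as.numeric(stats::quantile(x, probs = p, type = 1, names = FALSE))
}

#' Percentile confidence intervals for PSA deltas
#'
#' 2.5th/97.5th (for `level = 0.95`) percentiles of the incremental cost,
#' QALY and life-year clouds, plus an ICER interval. Because raw cost/effect
#' ratios are not monotone across the quadrants of the CE plane, the ICER
#' interval is taken from the iterations ranked by net monetary benefit at
#' `wtp`: the iterations at the lower and upper percentile ranks are
#' converted to an ICER, and an endpoint that falls in the win-win quadrant
#' (cost saving with QALY gain) is reported as the label `"dominant"`
#' rather than a meaningless negative ratio (a lose-lose endpoint likewise
#' prints `"dominated"`).
#'
#' @param result A `psa_result` with at least `1/((1-level)/2)` iterations.
#' @param level Interval level, default 0.95.
#' @param wtp Threshold used to rank iterations for the ICER interval.
#' @return List with `delta_cost`, `delta_qaly`, `delta_ly` (each
#'   `c(low, high)`) and `icer` (list of `low`/`high`, numeric or label).
#' @export
percentile_ci <- function(result, level = 0.95, wtp = 35000) {
  stopifnot(inherits(result, "psa_result"))
  n <- nrow(result$iterations)
  # snap away float noise (1 - 0.95 is not exactly 0.05) so the percentile
  # rank index is stable
  tail_p <- round((1 - level) / 2, 10)
  if (n < ceiling(1 / tail_p)) {
    stop(sprintf("need at least %d iterations for a %.0f%% interval, got %d",
                 ceiling(1 / tail_p), level * 100, n), call. = FALSE)
  }
  it <- result$iterations
  probs <- c(tail_p, 1 - tail_p)
  icer_at <- function(row) {
    dc <- row$delta_cost; dq <- row$delta_qaly
    if (dc < 0 && dq > 0) return("dominant")
    if (dc > 0 && dq < 0) return("dominated")
    if (dq == 0) return(NA_real_)
    dc / dq
  }
  nmb <- wtp * it$delta_qaly - it$delta_cost
  ord <- order(nmb)
  # low NMB = worst value end of the interval
  lo_idx <- ord[max(1L, ceiling(tail_p * n))]
  hi_idx <- ord[max(1L, ceiling((1 - tail_p) * n))]
  list(delta_cost = pctile(it$delta_cost, probs),
       delta_qaly = pctile(it$delta_qaly, probs),
       delta_ly = pctile(it$delta_ly, probs),
       icer = list(low = icer_at(it[lo_idx, ]),
                   high = icer_at(it[hi_idx, ])))
}

#' Cost-effectiveness acceptability curve
#'
#' Evaluates [proportion_cost_effective()] on an ascending grid of
#' willingness-to-pay thresholds.
#'
#' @param result A `psa_result`.
#' @param wtp_grid Ascending numeric vector of thresholds.
#' @return Data frame with columns `wtp` and `fraction`.
#' @export
ceac <- function(result, wtp_grid) {
  stopifnot(inherits(result, "psa_result"), is.numeric(wtp_grid))
  if (is.unsorted(wtp_grid)) stop("wtp_grid must be ascending", call. = FALSE)
  if (length(wtp_grid) == 0L) {
    return(data.frame(wtp = numeric(0), fraction = numeric(0)))
  }
  data.frame(wtp = wtp_grid,
             fraction = vapply(wtp_grid,
                               function(w) proportion_cost_effective(result, w),
                               numeric(1)))
}
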