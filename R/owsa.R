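#' One-way sensitivity analysis of a single parameter
#'
#' Re-evaluates the full decision tree twice with the parameter pinned at its
#' low and high bound (everything else at base case) and records the chosen
#' output at each bound. Trees are immutable values, so the base case is
#' untouched afterwards. The default output is net monetary benefit at the
#' willingness-to-pay threshold, because the ICER is undefined or changes
#' meaning across quadrants of the CE plane; `output = "icer"` is available
#' for conventional tornado reporting and yields `NA` at a bound where the
#' comparison is dominant/dominated.
#'
#' @param tree Base-case [decision_tree()].
#' @param parameter A path string (see [tree_set_param()]), a character
#'   vector of paths moved together, or a [parameter_spec()] whose `paths`
#'   are used.
#' @param low,high Parameter bounds (`low <= high`).
#' @param output `"nmb"` (default) or `"icer"`.
#' @param intervention,comparator Strategy names.
#' @param wtp Threshold for the NMB output (default 35,000 per QALY).
#' @param horizon_years Optional horizon override.
#' @return Object of class `tornado_entry` with `parameter`, `low_value`,
#'   `high_value`, `output_at_low`, `output_at_high`, `swing`.
#' @export
one_way <- function(tree, parameter, low, high, output = c("nmb", "icer"),
                    intervention, comparator, wtp = 35000,
                    horizon_years = NULL) {
  output <- match.arg(output)
  stopifnot(inherits(tree, "decision_tree"),
            is.numeric(low), length(low) == 1L,
            is.numeric(high), length(high) == 1L)
  if (low > high) stop("low must be <= high", call. = FALSE)
  if (inherits(parameter, "parameter_spec")) {
    paths <- parameter$paths
    pname <- parameter$name
  } else {
    stopifnot(is.character(parameter), length(parameter) >= 1L)
    paths <- parameter
    pname <- parameter[1L]
  }

  eval_at <- function(value) {
    t2 <- tree
    for (p in paths) t2 <- tree_set_param(t2, p, value)
    rep <- validate_tree(t2)
    if (!is_valid(rep)) {
      stop(sprintf("parameter '%s' = %g makes the tree invalid: %s",
                   pname, value, paste(rep, collapse = "; ")), call. = FALSE)
    }
    ev <- expected_values(t2, horizon_years)
    inc <- incremental(ev[[intervention]], ev[[comparator]])
    if (output == "nmb") {
      net_monetary_benefit(inc, wtp)
    } else {
      if (inc$label == "ratio") inc$icer_qaly else NA_real_
    }
  }

  at_low <- eval_at(low)
  at_high <- eval_at(high)
  structure(list(parameter = pname, low_value = low, high_value = high,
                 output_at_low = at_low, output_at_high = at_high,
                 swing = abs(at_high - at_low), output = output),
            class = "tornado_entry")
}

#' Tornado-diagram data from one-way sensitivity analyses
#'
#' Runs [one_way()] for every parameter in `ranges` and returns the entries
#' sorted by swing, largest first (ties broken by parameter name for
#' determinism), together with the base-case output -- the "expected value"
#' line of a tornado diagram. When `ranges` entries are `NULL`, bounds
#' default to +/-20% of the base-case value.
#'
#' @param tree Base-case [decision_tree()].
#' @param ranges Named list: name -> `c(low, high)` or `NULL` for the
#'   +/-20% default. Names must be paths, unless matched in `params`.
#' @param intervention,comparator Strategy names.
#' @param output `"nmb"` or `"icer"`.
#' @param wtp NMB threshold.
#' @param params Optional named list of [parameter_spec()] objects (or path
#'   vectors) so `ranges` can use friendly names.
#' @param horizon_years Optional horizon override.
#' @return List with `entries` (data frame sorted by descending swing),
#'   `base_output`, and `output`.
#' @export
tornado <- function(tree, ranges, intervention, comparator,
                    output = c("nmb", "icer"), wtp = 35000, params = NULL,
                    horizon_years = NULL) {
  output <- match.arg(output)
  stopifnot(is.list(ranges), length(ranges) >= 1L, !is.null(names(ranges)))

  lookup <- function(nm) {
    if (!is.null(params) && nm %in% names(params)) params[[nm]] else nm
  }
  base_value <- function(par) {
    p <- if (inherits(par, "parameter_spec")) par$paths[1L] else par[1L]
    tree_get(tree, p)
  }

  ev <- expected_values(tree, horizon_years)
  inc <- incremental(ev[[intervention]], ev[[comparator]])
  base_output <- if (output == "nmb") {
    net_monetary_benefit(inc, wtp)
  } else if (inc$label == "ratio") inc$icer_qaly else NA_real_

  entries <- lapply(names(ranges), function(nm) {
    par <- lookup(nm)
    rg <- ranges[[nm]]
    if (is.null(rg)) {
      b <- base_value(par)
      rg <- sort(c(0.8 * b, 1.2 * b))
    }
    e <- one_way(tree, par, rg[1], rg[2], output = output,
                 intervention = intervention, comparator = comparator,
                 wtp = wtp, horizon_years = horizon_years)
    e$parameter <- nm
    e
  })

  tab <- data.frame(
    parameter = vapply(entries, `[[`, character(1), "parameter"),
    low_value = vapply(entries, `[[`, numeric(1), "low_value"),
    high_value = vapply(entries, `[[`, numeric(1), "high_value"),
    output_at_low = vapply(entries, `[[`, numeric(1), "output_at_low"),
    output_at_high = vapply(entries, `[[`, numeric(1), "output_at_high"),
    swing = vapply(entries, `[[`, numeric(1), "swing"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$swing, tab$parameter), , drop = FALSE]
  rownames(tab) <- NULL
  list(entries = tab, base_output = base_output, output = output)
}
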