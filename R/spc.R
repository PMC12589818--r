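#' Moving ranges of a chronological series
#'
#' The moving range is the absolute difference between consecutive
#' observations, `|x[i] - x[i-1]|`; its average scales the control limits
#' of an individuals chart.
#'
#' @param values Numeric series of length >= 2, chronological order.
#' @return Numeric vector of length `n - 1`, all entries >= 0.
#' @examples
#' moving_ranges(c(5, 3, 6, 2))
#' @export
moving_ranges <- function(values) {
  if (length(values) < 2L) {
    cli::cli_abort("At least 2 values are required; got {length(values)}.")
  }
  abs(diff(values))
}

#' Individuals / moving-range control chart
#'
#' Builds an individuals (X-mR) control chart for longitudinal QA
#' monitoring of single observations per time point. The centerline is the
#' arithmetic mean of the charted values, and the control limits are
#' `centerline +/- 2.660 * mR-bar` where `mR-bar` is the average moving
#' range (2.660 = 3/d2 for moving ranges of span 2). Points outside
#' \[LCL, UCL\] violate rule 1 (beyond limits).
#'
#' By default centerline and limits are estimated from the whole series
#' (retrospective, phase-I charting). For prospective monitoring — e.g.
#' detecting a drift or step change against an established baseline — set
#' `baseline_n` to estimate centerline and limits from the first
#' `baseline_n` points only, then judge every point against them.
#'
#' For passing-rate data the UCL may exceed 100; it is reported unclamped
#' (clamping is a display concern, see [autoplot.spc_chart()]).
#'
#' @param values Numeric series (>= 2 values) in chronological order.
#' @param dates Optional vector of dates aligned with `values`.
#' @param baseline_n Optional number of leading points used to estimate
#'   the centerline and limits (default: all points).
#'
#' @return An object of class `spc_chart`: list with `values`, `dates`,
#'   `centerline`, `mr_bar`, `ucl`, `lcl`, `baseline_n` and `beyond_limits`
#'   (logical per-point rule-1 flags). Use [tidy()] for a per-point tibble,
#'   [glance()] for a one-row summary, [spc_flags()] for rule evaluation.
#' @examples
#' chart <- spc_chart(c(10, 12, 11, 13))
#' glance(chart)
#' @export
spc_chart <- function(values, dates = NULL, baseline_n = NULL) {
  if (length(values) < 2L) {
    cli::cli_abort("At least 2 values are required; got {length(values)}.")
  }
  if (!is.null(dates) && length(dates) != length(values)) {
    cli::cli_abort("{.arg dates} must align with {.arg values}.")
  }
  if (is.null(baseline_n)) {
    base <- values
  } else {
    baseline_n <- as.integer(baseline_n)
    if (baseline_n < 2L || baseline_n > length(values)) {
      cli::cli_abort("{.arg baseline_n} must be between 2 and {length(values)}.")
    }
    base <- values[seq_len(baseline_n)]
  }
  mr_bar <- mean(moving_ranges(base))
  centerline <- mean(base)
  ucl <- centerline + SPC_CONSTANT * mr_bar
  lcl <- centerline - SPC_CONSTANT * mr_bar
  structure(
    list(
      values = values,
      dates = dates,
      centerline = centerline,
      mr_bar = mr_bar,
      ucl = ucl,
      lcl = lcl,
      baseline_n = baseline_n,
      beyond_limits = values > ucl | values < lcl
    ),
    class = "spc_chart"
  )
}

#' @export
print.spc_chart <- function(x, ...) {
  cat(sprintf(
    paste0("<individuals chart> n = %d, centerline = %.4g, mR-bar = %.4g,\n",
           "  UCL = %.4g, LCL = %.4g, %d point(s) beyond limits\n"),
    length(x$values), x$centerline, x$mr_bar, x$ucl, x$lcl,
    sum(x$beyond_limits)
  ))
  invisible(x)
}

#' Evaluate out-of-control rules on a control chart
#'
#' Rule 1 (a point beyond the control limits) is always evaluated. Two
#' classical run rules can be enabled: `run_of_8` (8 consecutive points on
#' the same side of the centerline) and `trend_of_6` (6 consecutive
#' strictly monotone points, i.e. 5 consecutive rises or falls). Both are
#' off by default: limit breaches are the only rule assumed in routine QA
#' alerting here.
#'
#' @param chart An [spc_chart()] object.
#' @param rules Character vector from `c("beyond_limits", "run_of_8",
#'   "trend_of_6")`; `"beyond_limits"` is always included.
#' @return A tibble with one row per (point, triggered rule): `index`,
#'   `value`, `rule`.
#' @examples
#' chart <- spc_chart(c(10, 12, 11, 13, 2))
#' spc_flags(chart)
#' @export
spc_flags <- function(chart, rules = "beyond_limits") {
  stopifnot(inherits(chart, "spc_chart"))
  rules <- union("beyond_limits", match.arg(
    rules, c("beyond_limits", "run_of_8", "trend_of_6"), several.ok = TRUE
  ))
  v <- chart$values
  n <- length(v)
  out <- list(tibble::tibble(
    index = which(chart$beyond_limits),
    value = v[chart$beyond_limits],
    rule = "beyond_limits"
  ))
  if ("run_of_8" %in% rules && n >= 8) {
    side <- sign(v - chart$centerline)
    hits <- logical(n)
    for (i in 8:n) {
      w <- side[(i - 7):i]
      if (all(w == 1) || all(w == -1)) hits[i] <- TRUE
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      index = which(hits), value = v[hits], rule = "run_of_8"
    )
  }
  if ("trend_of_6" %in% rules && n >= 6) {
    step <- sign(diff(v))
    hits <- logical(n)
    for (i in 6:n) {
      w <- step[(i - 5):(i - 1)]
      if (all(w == 1) || all(w == -1)) hits[i] <- TRUE
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      index = which(hits), value = v[hits], rule = "trend_of_6"
    )
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$index, .data$rule)
}
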