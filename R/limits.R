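#' Summarize a QA process
#'
#' Computes the process statistics that parameterize the tolerance width:
#' count, mean, sample standard deviation (n - 1 denominator, the process
#' capability convention) and the process target (100% for passing rates,
#' 0% for dose differences).
#'
#' @param values Numeric series of QA results (percent); at least two
#'   finite values are required for the SD to be defined.
#' @param target Process target value `T`.
#' @return One-row tibble: `n`, `mean`, `sd`, `target`.
#' @examples
#' process_summary(c(98, 100), target = 100)
#' @export
process_summary <- function(values, target = 100) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    cli::cli_abort("At least 2 finite values are required; got {length(values)}.")
  }
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = sd(values),
    target = target
  )
}

#' Tolerance width of a QA process
#'
#' The tolerance width is the span between the upper and lower intervention
#' thresholds of a QA process:
#' `delta_A = beta * sqrt(sd^2 + (mean - target)^2)`,
#' combining random spread and systematic offset from the target. It is
#' nondecreasing in both, and scales linearly with `beta` (default 6, the
#' TG-218 process-capability choice).
#'
#' @param mean Process mean, or a one-row summary from [process_summary()]
#'   (in which case `sd` and `target` are taken from it).
#' @param sd Process standard deviation (sample, n - 1).
#' @param target Process target `T` (100 for passing rates, 0 for dose
#'   difference).
#' @param beta Positive width constant.
#' @return Numeric tolerance width(s), in the channel's percent units.
#' @examples
#' delta_a(mean = 99.4, sd = 1.3, target = 100, beta = 6)
#' delta_a(process_summary(c(98, 100)))
#' @export
delta_a <- function(mean, sd = NULL, target = 100, beta = 6) {
  if (is.data.frame(mean)) {
    summary <- mean
    mean <- summary$mean
    sd <- summary$sd
    target <- summary$target
  }
  if (!is.numeric(beta) || any(beta <= 0)) {
    cli::cli_abort("{.arg beta} must be positive.")
  }
  beta * sqrt(sd^2 + (mean - target)^2)
}

#' Action limit from a tolerance width
#'
#' The action limit marks results that demand intervention. For
#' passing-rate channels it is the lower threshold of acceptable results,
#' `AL = 100 - delta_A / 2` (one-sided: only low passing rates are
#' actionable). For the dose-difference channel the limits are symmetric
#' about the target 0, `+/- delta_A / 2`; the lower bound is returned and
#' the upper bound is its negation.
#'
#' @param delta_a Nonnegative tolerance width(s) from [delta_a()].
#' @param channel `"gamma"` (passing rate) or `"dose"` (dose difference).
#' @return The (lower) action limit, in percent.
#' @examples
#' action_limit(delta_a(mean = 99.4, sd = 1.3))
#' @export
action_limit <- function(delta_a, channel = c("gamma", "dose")) {
  channel <- match.arg(channel)
  if (any(delta_a < 0, na.rm = TRUE)) {
    cli::cli_abort("{.arg delta_a} must be >= 0.")
  }
  if (channel == "gamma") 100 - delta_a / 2 else -delta_a / 2
}

#' Tolerance limit from process behaviour
#'
#' The tolerance limit bounds ordinary process behaviour and warns before
#' the action limit is reached. It is derived from the individuals
#' control chart over the chronologically ordered series: the lower
#' control limit `centerline - 2.660 * mean moving range` (see
#' [spc_chart()]). Because the average moving range depends on the
#' observation order, so does the tolerance limit. For the two-sided
#' dose-difference channel the upper counterpart is
#' `centerline + 2.660 * mR-bar` (`side = "upper"`).
#'
#' @param values Numeric series in chronological order (>= 2 values).
#' @param side `"lower"` (default; the actionable side for passing rates)
#'   or `"upper"`.
#' @return The tolerance limit, in percent.
#' @examples
#' tolerance_limit(c(98, 100, 99, 97))
#' @export
tolerance_limit <- function(values, side = c("lower", "upper")) {
  side <- match.arg(side)
  values <- values[is.finite(values)]
  if (length(values) < 2L) {
    cli::cli_abort("At least 2 finite values are required; got {length(values)}.")
  }
  mr_bar <- mean(moving_ranges(values))
  cl <- mean(values)
  if (side == "lower") cl - SPC_CONSTANT * mr_bar else cl + SPC_CONSTANT * mr_bar
}

#' Action and tolerance limits per stratum
#'
#' Derives a limit set (tolerance width, action limit, tolerance limit)
#' for each stratum of a PSQA cohort on one measurement channel. Records
#' are ordered chronologically within stratum (ties broken by input row
#' order) before the order-sensitive tolerance limit is computed.
#'
#' Strata with fewer than `min_n` records are flagged `"provisional"` but
#' their limits are still reported; strata where the tolerance limit falls
#' below the action limit are flagged `"TL_below_AL"` (possible in
#' practice, not an error). Strata with fewer than 2 usable values are
#' dropped with a warning. Missing channel values are excluded.
#'
#' @param records Tibble of PSQA records.
#' @param group_by Character vector of stratification columns:
#'   `"site"`, `"facility"`, or `c("facility", "site")`.
#' @param channel Measurement channel (see [channel_column()]); default
#'   the mandatory 3%/3mm criterion.
#' @param beta Tolerance-width constant, default 6.
#' @param min_n Minimum records per stratum before limits are considered
#'   established (default 20).
#' @param target Process target; default 100 for gamma channels, 0 for
#'   dose difference.
#'
#' @return A tibble of class `tg218_limits`: the grouping columns plus
#'   `channel`, `n`, `mean`, `sd`, `delta_A`, `AL`, `TL` (and `AL_upper`,
#'   `TL_upper` for the two-sided dose channel) and `flags`
#'   (semicolon-separated advisories, `""` if none).
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' tg218_limits(cohort$records, group_by = "site")
#' @export
tg218_limits <- function(records, group_by = "site", channel = "3%/3mm",
                         beta = 6, min_n = 20, target = NULL) {
  stopifnot(is.data.frame(records))
  group_by <- match.arg(group_by, c("site", "facility"), several.ok = TRUE)
  col <- channel_column(channel)
  if (!col %in% names(records)) {
    cli::cli_abort("Channel column {.field {col}} not present in records.")
  }
  target <- target %||% channel_target(col)
  is_gamma <- channel_is_gamma(col)

  records <- dplyr::mutate(records, .row = dplyr::row_number())
  grouped <- records |>
    dplyr::filter(is.finite(.data[[col]])) |>
    dplyr::arrange(.data$qa_date, .data$.row) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by)))

  empty <- grouped |>
    dplyr::summarise(n = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n < 2)
  if (nrow(empty) > 0) {
    cli::cli_warn(
      "{nrow(empty)} strat{?um/a} with fewer than 2 usable values omitted."
    )
  }

  out <- grouped |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(
      channel = channel_label(col),
      n = dplyr::n(),
      mean = mean(.data[[col]]),
      sd = sd(.data[[col]]),
      TL = tolerance_limit(.data[[col]], side = "lower"),
      TL_upper = tolerance_limit(.data[[col]], side = "upper"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      delta_A = delta_a(mean = .data$mean, sd = .data$sd,
                        target = .env$target, beta = .env$beta),
      AL = action_limit(.data$delta_A,
                        channel = if (is_gamma) "gamma" else "dose"),
      AL_upper = if (is_gamma) NA_real_ else .data$delta_A / 2,
      flags = paste0(
        ifelse(.data$n < .env$min_n, "provisional", ""),
        ifelse(.data$n < .env$min_n & .data$TL < .data$AL, ";", ""),
        ifelse(.data$TL < .data$AL, "TL_below_AL", "")
      )
    )
  if (is_gamma) {
    out$TL_upper <- NULL
    out$AL_upper <- NULL
    out <- dplyr::relocate(out, "TL", .after = "AL")
  } else {
    out <- dplyr::relocate(out, "AL", "AL_upper", "TL", "TL_upper",
                           .after = "delta_A")
  }
  structure(
    out,
    class = c("tg218_limits", class(out)),
    beta = beta, channel = channel_label(col), column = col,
    target = target, min_n = min_n, group_by = group_by
  )
}

#' @export
print.tg218_limits <- function(x, ...) {
  cat(sprintf(
    "<TG-218 limits> channel %s, beta = %g, target = %g, grouped by %s\n",
    attr(x, "channel"), attr(x, "beta"), attr(x, "target"),
    paste(attr(x, "group_by"), collapse = " x ")
  ))
  NextMethod()
}
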