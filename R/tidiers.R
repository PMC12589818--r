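#' Tidy an individuals control chart
#'
#' @param x An [spc_chart()] object.
#' @param ... Unused.
#' @return One row per charted point: `index`, `date` (if supplied),
#'   `value`, `in_baseline`, `beyond_limits`.
#' @export
tidy.spc_chart <- function(x, ...) {
  n <- length(x$values)
  out <- tibble::tibble(
    index = seq_len(n),
    value = x$values,
    in_baseline = seq_len(n) <= (x$baseline_n %||% n),
    beyond_limits = x$beyond_limits
  )
  if (!is.null(x$dates)) {
    out <- tibble::add_column(out, date = x$dates, .after = "index")
  }
  out
}

#' Glance at an individuals control chart
#'
#' @inheritParams tidy.spc_chart
#' @return One-row tibble: `n`, `centerline`, `mr_bar`, `ucl`, `lcl`,
#'   `n_beyond_limits`.
#' @export
glance.spc_chart <- function(x, ...) {
  tibble::tibble(
    n = length(x$values),
    centerline = x$centerline,
    mr_bar = x$mr_bar,
    ucl = x$ucl,
    lcl = x$lcl,
    n_beyond_limits = sum(x$beyond_limits)
  )
}

#' Tidy an IQR outlier report
#'
#' @param x A [iqr_outliers()] object.
#' @param ... Unused.
#' @return The flagged points, one row each: `index`, `value`.
#' @export
tidy.psqa_outliers <- function(x, ...) {
  x$flagged
}

#' Glance at an IQR outlier report
#'
#' @inheritParams tidy.psqa_outliers
#' @return One-row tibble with quartiles, fences and flagged count.
#' @export
glance.psqa_outliers <- function(x, ...) {
  tibble::tibble(
    n = x$n, q1 = x$q1, q3 = x$q3, iqr = x$iqr,
    lower_fence = x$lower_fence, upper_fence = x$upper_fence,
    k = x$k, n_flagged = nrow(x$flagged)
  )
}

#' Tidy a validation report
#'
#' @param x A `psqa_validation` object from [validate_psqa()].
#' @param ... Unused.
#' @return The issues tibble: `row`, `field`, `rule`, `severity`.
#' @export
tidy.psqa_validation <- function(x, ...) {
  x$issues
}

#' Glance at a validation report
#'
#' @inheritParams tidy.psqa_validation
#' @return One-row tibble: `accepted`, `rejected`, `n_errors`,
#'   `n_warnings`.
#' @export
glance.psqa_validation <- function(x, ...) {
  tibble::tibble(
    accepted = x$accepted,
    rejected = x$rejected,
    n_errors = sum(x$issues$severity == "error"),
    n_warnings = sum(x$issues$severity == "warning")
  )
}

#' Tidy a cohort analysis report
#'
#' @param x A [run_analysis()] report.
#' @param ... Unused.
#' @return The per-stratum limit table.
#' @export
tidy.psqa_report <- function(x, ...) {
  tibble::as_tibble(x$limits_stratum)
}

#' Glance at a cohort analysis report
#'
#' @inheritParams tidy.psqa_report
#' @return One-row tibble: total records, per-channel pooled moments
#'   (wide), alert count.
#' @export
glance.psqa_report <- function(x, ...) {
  out <- tibble::tibble(n_records = x$total, n_alerts = nrow(x$alerts))
  if (nrow(x$pooled) > 0) {
    wide <- x$pooled |>
      tidyr::pivot_wider(
        names_from = "channel", values_from = c("mean", "sd"),
        id_cols = character()
      )
    out <- dplyr::bind_cols(out, wide)
  }
  out
}
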