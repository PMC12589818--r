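#' Interquartile-range outlier flagging
#'
#' Flags values outside the Tukey fences `[Q1 - k*IQR, Q3 + k*IQR]`.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7). Comparison is strict: a value exactly on
#' a fence is not an outlier.
#'
#' @param values Numeric series, at least 4 values.
#' @param k Fence multiplier; default 1.5 (Tukey's convention). Larger `k`
#'   widens the fences and can only reduce the flagged count.
#' @return An object of class `psqa_outliers`: `q1`, `q3`, `iqr`,
#'   `lower_fence`, `upper_fence`, `k`, `n`, and `flagged`, a tibble of
#'   (`index`, `value`) outside the fences.
#' @examples
#' iqr_outliers(c(1:7, 100))$flagged
#' @export
iqr_outliers <- function(values, k = 1.5) {
  values <- as.numeric(values)
  if (sum(is.finite(values)) < 4L) {
    cli::cli_abort(
      "At least 4 finite values are required; got {sum(is.finite(values))}."
    )
  }
  if (!is.numeric(k) || length(k) != 1L || k < 0) {
    cli::cli_abort("{.arg k} must be a single nonnegative number.")
  }
  q <- unname(quantile(values, probs = c(0.25, 0.75), na.rm = TRUE, type = 7))
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  hit <- which(is.finite(values) & (values < lower | values > upper))
  structure(
    list(
      q1 = q[1], q3 = q[2], iqr = iqr,
      lower_fence = lower, upper_fence = upper, k = k,
      n = sum(is.finite(values)),
      flagged = tibble::tibble(index = hit, value = values[hit])
    ),
    class = "psqa_outliers"
  )
}

#' @export
print.psqa_outliers <- function(x, ...) {
  cat(sprintf(
    "<IQR outliers> n = %d, fences [%.4g, %.4g] (k = %g), %d flagged\n",
    x$n, x$lower_fence, x$upper_fence, x$k, nrow(x$flagged)
  ))
  invisible(x)
}

#' Evaluate limit-breach and outlier alerts over a cohort
#'
#' Batch equivalent of the on-entry alerting of a QA database: every
#' record is compared against its stratum's action and tolerance limits,
#' and within-stratum IQR outliers are flagged. Breach comparisons are
#' strict (`<` the lower limit, `>` the upper limit for the two-sided
#' dose channel); a value exactly on a limit does not alert. A value
#' beyond both limits yields a single `AL_breach` alert (the more severe
#' level) with `tl_also = TRUE`.
#'
#' @param records Tibble of PSQA records.
#' @param limits A [tg218_limits()] table covering every stratum present
#'   in `records` (on the limits' grouping columns); a stratum without a
#'   limit set is an error.
#' @param k IQR fence multiplier, default 1.5.
#'
#' @return A tibble of alerts sorted by `qa_date`: `row` (index into
#'   `records`), `patient_key`, `facility`, `site`, `qa_date`, `channel`,
#'   `level` (`"AL_breach"`, `"TL_breach"` or `"outlier"`), `threshold`
#'   (the limit or fence crossed), `value`, `tl_also`.
#' @examples
#' cohort <- generate_cohort(seed = 3)
#' lim <- tg218_limits(cohort$records, group_by = "site")
#' alerts <- evaluate_alerts(cohort$records, lim)
#' @export
evaluate_alerts <- function(records, limits, k = 1.5) {
  stopifnot(is.data.frame(records), inherits(limits, "tg218_limits"))
  col <- attr(limits, "column")
  group_by <- attr(limits, "group_by")
  is_gamma <- channel_is_gamma(col)

  records <- dplyr::mutate(records, .row = dplyr::row_number())
  usable <- dplyr::filter(records, is.finite(.data[[col]]))
  if (nrow(usable) == 0) {
    return(empty_alerts())
  }

  strata_present <- dplyr::distinct(usable, dplyr::across(dplyr::all_of(group_by)))
  missing <- dplyr::anti_join(strata_present, limits, by = group_by)
  if (nrow(missing) > 0) {
    labs <- apply(missing, 1, paste, collapse = "/")
    cli::cli_abort("No limit set for strat{?um/a}: {.val {labs}}.")
  }

  joined <- dplyr::inner_join(
    usable, tibble::as_tibble(limits)[, c(group_by, "AL", "TL",
                                          intersect(c("AL_upper", "TL_upper"),
                                                    names(limits)))],
    by = group_by
  )

  v <- joined[[col]]
  if (is_gamma) {
    al_hit <- v < joined$AL
    tl_hit <- v < joined$TL
    al_threshold <- joined$AL
    tl_threshold <- joined$TL
  } else {
    al_hit <- v < joined$AL | v > joined$AL_upper
    tl_hit <- v < joined$TL | v > joined$TL_upper
    al_threshold <- ifelse(v < joined$AL, joined$AL, joined$AL_upper)
    tl_threshold <- ifelse(v < joined$TL, joined$TL, joined$TL_upper)
  }

  mk <- function(rows, level, threshold, tl_also = FALSE) {
    tibble::tibble(
      row = joined$.row[rows],
      patient_key = joined$patient_key[rows],
      facility = joined$facility[rows],
      site = joined$site[rows],
      qa_date = joined$qa_date[rows],
      channel = channel_label(col),
      level = level,
      threshold = threshold,
      value = v[rows],
      tl_also = tl_also
    )
  }
  alerts <- list(
    mk(which(al_hit), "AL_breach", al_threshold[al_hit], tl_also = tl_hit[al_hit]),
    mk(which(tl_hit & !al_hit), "TL_breach", tl_threshold[tl_hit & !al_hit])
  )

  # within-stratum IQR outliers (>= 4 values needed per stratum)
  outlier_rows <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_by))) |>
    dplyr::group_map(function(g, key) {
      # group_map drops the grouping columns from g; restore them from key
      g <- dplyr::bind_cols(g, key[rep(1L, nrow(g)), , drop = FALSE])
      if (sum(is.finite(g[[col]])) < 4L) {
        return(NULL)
      }
      rep_ <- iqr_outliers(g[[col]], k = k)
      if (nrow(rep_$flagged) == 0) {
        return(NULL)
      }
      fence <- ifelse(rep_$flagged$value < rep_$lower_fence,
                      rep_$lower_fence, rep_$upper_fence)
      tibble::tibble(
        row = g$.row[rep_$flagged$index],
        patient_key = g$patient_key[rep_$flagged$index],
        facility = g$facility[rep_$flagged$index],
        site = g$site[rep_$flagged$index],
        qa_date = g$qa_date[rep_$flagged$index],
        channel = channel_label(col),
        level = "outlier",
        threshold = fence,
        value = rep_$flagged$value,
        tl_also = FALSE
      )
    }) |>
    dplyr::bind_rows()

  out <- dplyr::bind_rows(c(alerts, list(outlier_rows)))
  if (nrow(out) == 0) {
    return(empty_alerts())
  }
  dplyr::arrange(out, .data$qa_date, .data$row, .data$level)
}

empty_alerts <- function() {
  tibble::tibble(
    row = integer(), patient_key = character(), facility = character(),
    site = character(), qa_date = as.Date(character()), channel = character(),
    level = character(), threshold = double(), value = double(),
    tl_also = logical()
  )
}
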