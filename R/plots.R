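#' Plot an individuals control chart
#'
#' Draws the charted series with its centerline (solid), control limits
#' (dashed) and rule-1 violations highlighted. For passing-rate data the
#' upper limit can exceed 100; `clamp_100` clips the displayed limits at
#' 100 without altering the chart object.
#'
#' @param object An [spc_chart()] object.
#' @param clamp_100 Clip displayed limits to 100 (display only).
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(spc_chart(rnorm(50, 99, 1)))
#' @export
autoplot.spc_chart <- function(object, clamp_100 = FALSE, ...) {
  df <- tidy(object)
  df$x <- if ("date" %in% names(df)) df$date else df$index
  ucl <- if (clamp_100) min(object$ucl, 100) else object$ucl
  lcl <- if (clamp_100) min(object$lcl, 100) else object$lcl
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_hline(yintercept = object$centerline, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(lcl, ucl), linetype = "dashed",
                        linewidth = 0.4) +
    ggplot2::geom_line(colour = "grey55", linewidth = 0.3) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$beyond_limits),
                        show.legend = FALSE, size = 1.4) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey25",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = if ("date" %in% names(df)) "QA date" else "observation",
      y = "value",
      title = "Individuals control chart",
      subtitle = sprintf("centerline %.2f, limits [%.2f, %.2f]",
                         object$centerline, lcl, ucl)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-stratum action and tolerance limits
#'
#' One panel of AL/TL markers per stratum, with the per-stratum mean shown
#' for context — the cross-facility / cross-site benchmarking view.
#'
#' @param object A [tg218_limits()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' cohort <- generate_cohort(seed = 5)
#' autoplot(tg218_limits(cohort$records, group_by = "site"))
#' @export
autoplot.tg218_limits <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$stratum <- do.call(paste, c(df[attr(object, "group_by")], sep = " / "))
  long <- df |>
    dplyr::select("stratum", "mean", "AL", "TL") |>
    tidyr::pivot_longer(c("mean", "AL", "TL"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$stratum,
                                     shape = .data$quantity,
                                     colour = .data$quantity)) +
    ggplot2::geom_point(size = 2.2) +
    ggplot2::labs(
      x = sprintf("%s (%%)", attr(object, "channel")),
      y = NULL, colour = NULL, shape = NULL,
      title = "Action and tolerance limits by stratum",
      subtitle = sprintf("beta = %g, target = %g",
                         attr(object, "beta"), attr(object, "target"))
    ) +
    ggplot2::theme_minimal()
}

#' Plot pooled channel distributions of a cohort
#'
#' Histograms of each analysed channel across the cohort, the
#' at-a-glance view of pooled QA performance.
#'
#' @param records Tibble of PSQA records.
#' @param channels Channels to show (default: all present).
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_channel_distributions <- function(records,
                                       channels = c("3%/3mm", "2%/2mm", "dose"),
                                       bins = 40) {
  cols <- intersect(vapply(channels, channel_column, character(1)),
                    names(records))
  long <- records |>
    dplyr::select(dplyr::all_of(cols)) |>
    tidyr::pivot_longer(dplyr::everything(),
                        names_to = "channel", values_to = "value") |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::mutate(channel = vapply(.data$channel, channel_label, character(1)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    ggplot2::facet_wrap(~channel, scales = "free") +
    ggplot2::labs(x = "value (%)", y = "records",
                  title = "Pooled channel distributions") +
    ggplot2::theme_minimal()
}
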