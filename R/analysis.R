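#' Analysis configuration
#'
#' Bundles the knobs of the reporting pipeline: which channels to analyse,
#' how to stratify, the tolerance-width constant, the IQR fence multiplier
#' and the minimum stratum size. `read_config()` loads the same settings
#' from a YAML file whose keys match the argument names.
#'
#' @param channels Channels to analyse (see [channel_column()]). Channels
#'   whose column is absent from the data are skipped.
#' @param group_by Stratification for limits, charts and alerts:
#'   `"site"`, `"facility"` or `c("facility", "site")`.
#' @param beta Tolerance-width constant (default 6).
#' @param k IQR fence multiplier (default 1.5).
#' @param min_n Minimum records per stratum before limits stop being
#'   flagged provisional (default 20).
#' @return A list of class `psqa_config`.
#' @examples
#' psqa_config(group_by = "site")
#' @export
psqa_config <- function(channels = c("3%/3mm", "2%/2mm", "dose"),
                        group_by = c("facility", "site"),
                        beta = 6, k = 1.5, min_n = 20) {
  group_by <- match.arg(group_by, c("site", "facility"), several.ok = TRUE)
  structure(
    list(
      channels = vapply(channels, channel_column, character(1),
                        USE.NAMES = FALSE),
      group_by = group_by,
      beta = beta, k = k, min_n = min_n
    ),
    class = "psqa_config"
  )
}

#' @rdname psqa_config
#' @param path Path to a YAML file with any of the keys `channels`,
#'   `group_by`, `beta`, `k`, `min_n`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) {
    cli::cli_abort("Config file {.path {path}} does not exist.")
  }
  raw <- yaml::read_yaml(path)
  known <- c("channels", "group_by", "beta", "k", "min_n")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    cli::cli_abort("Unknown config key{?s}: {.field {unknown}}.")
  }
  do.call(psqa_config, raw)
}

#' @export
print.psqa_config <- function(x, ...) {
  cat("<psqa config>\n")
  cat("  channels:", paste(vapply(x$channels, channel_label, character(1)),
                           collapse = ", "), "\n")
  cat("  group_by:", paste(x$group_by, collapse = " x "),
      sprintf("| beta = %g, k = %g, min_n = %d\n", x$beta, x$k, x$min_n))
  invisible(x)
}

#' Run the full PSQA analysis pipeline
#'
#' Composes the pipeline stages over a validated cohort: per-site counts,
#' pooled per-channel moments, per-site and per-stratum limit sets,
#' per-stratum control-chart summaries, and limit-breach/outlier alerts.
#' The report is deterministic: identical records and configuration yield
#' an identical report (provenance embeds a content digest of the input
#' so audits can tie limits to the data that produced them).
#'
#' Alerts and charts are evaluated on the configured stratification;
#' records in strata too small for limits (< 2 usable values) are excluded
#' from alerting for the affected channel and counted in
#' `provenance$n_unalerted`.
#'
#' @param records Tibble of validated PSQA records.
#' @param config A [psqa_config()].
#' @param seed Optional seed recorded in provenance when the cohort is
#'   synthetic.
#'
#' @return An object of class `psqa_report`: list with `counts`, `total`,
#'   `pooled`, `limits_site`, `limits_stratum`, `charts`, `alerts`,
#'   `config`, `provenance`.
#' @examples
#' cohort <- generate_cohort(seed = 11)
#' report <- run_analysis(cohort$records, psqa_config(group_by = "site"))
#' report$counts
#' @export
run_analysis <- function(records, config = psqa_config(), seed = NULL) {
  stopifnot(is.data.frame(records), inherits(config, "psqa_config"))
  records <- tibble::as_tibble(records)
  attr(records, "validation") <- NULL

  channels <- intersect(config$channels, names(records))
  counts <- records |>
    dplyr::count(.data$site, name = "n") |>
    dplyr::arrange(match(.data$site, psqa_sites()))
  total <- nrow(records)

  pooled <- purrr::map_dfr(channels, function(col) {
    v <- records[[col]][is.finite(records[[col]])]
    tibble::tibble(
      channel = channel_label(col), n = length(v),
      mean = if (length(v) > 0) mean(v) else NA_real_,
      sd = if (length(v) > 1) sd(v) else NA_real_
    )
  })

  limits_for <- function(group_by) {
    purrr::map(channels, function(col) {
      usable <- records[is.finite(records[[col]]), ]
      enough <- usable |>
        dplyr::count(dplyr::across(dplyr::all_of(group_by))) |>
        dplyr::filter(.data$n >= 2)
      if (nrow(enough) == 0) {
        return(NULL)
      }
      suppressWarnings(tg218_limits(
        records, group_by = group_by, channel = col,
        beta = config$beta, min_n = config$min_n
      ))
    }) |> setNames(channels)
  }
  limits_site_by_channel <- if (total > 0) limits_for("site") else list()
  limits_stratum_by_channel <- if (total > 0) limits_for(config$group_by) else list()
  flatten_limits <- function(lst) {
    lst <- purrr::compact(lst)
    if (length(lst) == 0) {
      return(tibble::tibble())
    }
    out <- dplyr::bind_rows(purrr::map(lst, tibble::as_tibble))
    for (a in c("beta", "channel", "column", "target", "min_n", "group_by")) {
      attr(out, a) <- NULL
    }
    out
  }
  limits_site <- flatten_limits(limits_site_by_channel)
  limits_stratum <- flatten_limits(limits_stratum_by_channel)

  records_idx <- dplyr::mutate(records, .row = dplyr::row_number())
  charts <- purrr::map_dfr(channels, function(col) {
    usable <- records_idx |>
      dplyr::filter(is.finite(.data[[col]])) |>
      dplyr::arrange(.data$qa_date, .data$.row)
    if (nrow(usable) == 0) {
      return(NULL)
    }
    usable |>
      dplyr::group_by(dplyr::across(dplyr::all_of(config$group_by))) |>
      dplyr::filter(dplyr::n() >= 2) |>
      dplyr::group_modify(function(g, key) {
        ch <- spc_chart(g[[col]], dates = g$qa_date)
        tibble::tibble(
          channel = channel_label(col), n = length(ch$values),
          centerline = ch$centerline, mr_bar = ch$mr_bar,
          ucl = ch$ucl, lcl = ch$lcl,
          n_beyond_limits = sum(ch$beyond_limits)
        )
      }) |>
      dplyr::ungroup()
  })

  n_unalerted <- 0L
  alerts <- purrr::map_dfr(channels, function(col) {
    lim <- limits_stratum_by_channel[[col]]
    if (is.null(lim)) {
      n_unalerted <<- n_unalerted + sum(is.finite(records[[col]]))
      return(empty_alerts())
    }
    covered <- dplyr::semi_join(
      records_idx[is.finite(records_idx[[col]]), ],
      lim, by = config$group_by
    )
    n_unalerted <<- n_unalerted +
      (sum(is.finite(records[[col]])) - nrow(covered))
    a <- evaluate_alerts(covered, lim, k = config$k)
    a$row <- covered$.row[a$row]  # map back to original record rows
    a
  })
  if (nrow(alerts) > 0) {
    alerts <- dplyr::arrange(alerts, .data$qa_date, .data$row, .data$channel)
  }

  provenance <- list(
    input_digest = digest::digest(dplyr::select(records, -dplyr::any_of(".row"))),
    n_records = total,
    n_unalerted = n_unalerted,
    seed = seed,
    package_version = as.character(utils::packageVersion("psqa"))
  )

  structure(
    list(
      counts = counts, total = total, pooled = pooled,
      limits_site = limits_site, limits_stratum = limits_stratum,
      charts = if (is.null(charts)) tibble::tibble() else charts,
      alerts = alerts,
      config = unclass(config), provenance = provenance
    ),
    class = "psqa_report"
  )
}

#' @export
print.psqa_report <- function(x, ...) {
  cat(sprintf("<psqa report> %d records across %d site(s)\n",
              x$total, nrow(x$counts)))
  if (nrow(x$pooled) > 0) {
    for (i in seq_len(nrow(x$pooled))) {
      cat(sprintf("  %-8s n = %4d, mean = %6.2f, sd = %5.2f\n",
                  x$pooled$channel[i], x$pooled$n[i],
                  x$pooled$mean[i], x$pooled$sd[i]))
    }
  }
  cat(sprintf("  %d limit set(s), %d alert(s)\n",
              nrow(x$limits_stratum), nrow(x$alerts)))
  invisible(x)
}

#' Compare facilities on one site and channel
#'
#' Extracts the per-facility limit sets for a single disease site and
#' channel from a report whose stratification includes the facility —
#' the cross-facility benchmarking view (one row per facility).
#'
#' @param report A [run_analysis()] report stratified by
#'   `c("facility", "site")`.
#' @param site Canonical disease-site label.
#' @param channel Channel label (see [channel_column()]).
#' @return A tibble with one row per facility, sorted by facility label:
#'   `facility`, `n`, `mean`, `sd`, `delta_A`, `AL`, `TL`, `flags`.
#' @examples
#' cohort <- generate_cohort(seed = 11)
#' report <- run_analysis(cohort$records)
#' facility_comparison(report, site = "Pelvis", channel = "3%/3mm")
#' @export
facility_comparison <- function(report, site, channel = "3%/3mm") {
  stopifnot(inherits(report, "psqa_report"))
  if (!all(c("facility", "site") %in% report$config$group_by)) {
    cli::cli_abort(
      "The report must be stratified by facility and site (got {.val {report$config$group_by}})."
    )
  }
  lab <- channel_label(channel_column(channel))
  lim <- report$limits_stratum
  if (nrow(lim) == 0 || !lab %in% lim$channel || !site %in% lim$site) {
    cli::cli_abort("No limit sets for site {.val {site}}, channel {.val {lab}}.")
  }
  lim |>
    dplyr::filter(.data$site == .env$site, .data$channel == .env$lab) |>
    dplyr::arrange(.data$facility) |>
    dplyr::select("facility", "n", "mean", "sd", "delta_A", "AL", "TL", "flags")
}

report_date_cols <- c("qa_date", "approval_date", "date_start", "date_end")

#' Write and re-read an analysis report
#'
#' `write_report()` serializes a [run_analysis()] report as a single JSON
#' document (lossless round trip via `read_report()`), as a CSV bundle
#' (one file per table plus a provenance JSON), or as a plain-text
#' summary. `read_report()` reconstructs a `psqa_report` from the JSON
#' form.
#'
#' @param report A `psqa_report`.
#' @param path Output path: a `.json` file for `"json"`, a directory for
#'   `"csv"`, a `.txt` file for `"text"`.
#' @param format One of `"json"`, `"csv"`, `"text"`.
#' @return The path(s) written, invisibly.
#' @examples
#' cohort <- generate_cohort(seed = 11)
#' report <- run_analysis(cohort$records)
#' path <- tempfile(fileext = ".json")
#' write_report(report, path)
#' identical(read_report(path)$counts, report$counts)
#' @export
write_report <- function(report, path, format = c("json", "csv", "text")) {
  stopifnot(inherits(report, "psqa_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(
      report_to_list(report), path,
      auto_unbox = TRUE, digits = NA, null = "null", na = "null",
      dataframe = "columns"
    )
    return(invisible(path))
  }
  if (format == "csv") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    files <- character()
    for (nm in c("counts", "pooled", "limits_site", "limits_stratum",
                 "charts", "alerts")) {
      f <- file.path(path, paste0(nm, ".csv"))
      readr::write_csv(as.data.frame(report[[nm]]), f, na = "")
      files <- c(files, f)
    }
    f <- file.path(path, "provenance.json")
    jsonlite::write_json(c(report$provenance, list(config = report$config)),
                         f, auto_unbox = TRUE, null = "null", na = "null")
    return(invisible(c(files, f)))
  }
  # text
  lines <- c(
    "PSQA cohort analysis report",
    sprintf("records: %d", report$total),
    "",
    "per-site counts:",
    if (nrow(report$counts) > 0) {
      sprintf("  %-10s %5d", report$counts$site, report$counts$n)
    } else "  (none)",
    "",
    "pooled moments:",
    if (nrow(report$pooled) > 0) {
      sprintf("  %-8s n = %5d  mean = %8.3f  sd = %7.3f",
              report$pooled$channel, report$pooled$n,
              report$pooled$mean, report$pooled$sd)
    } else "  (none)",
    "",
    sprintf("limit sets (site): %d; limit sets (stratum): %d",
            nrow(report$limits_site), nrow(report$limits_stratum)),
    sprintf("alerts: %d", nrow(report$alerts))
  )
  if (nrow(report$limits_site) > 0) {
    lines <- c(lines, "", "site limits:")
    ls <- report$limits_site
    lines <- c(lines, sprintf(
      "  %-10s %-8s n = %4d  AL = %7.3f  TL = %7.3f  %s",
      ls$site, ls$channel, ls$n, ls$AL, ls$TL, ls$flags
    ))
  }
  writeLines(lines, path)
  invisible(path)
}

# Plain-list form with ISO dates, suitable for JSON.
report_to_list <- function(report) {
  out <- unclass(report)
  fix <- function(df) {
    df <- as.data.frame(df)
    for (col in intersect(report_date_cols, names(df))) {
      df[[col]] <- format(df[[col]], "%Y-%m-%d")
    }
    df
  }
  for (nm in c("counts", "pooled", "limits_site", "limits_stratum",
               "charts", "alerts")) {
    out[[nm]] <- fix(out[[nm]])
  }
  out
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_tbl <- function(x) {
    if (is.null(x) || length(x) == 0) {
      return(tibble::tibble())
    }
    df <- tibble::as_tibble(x)
    for (col in intersect(report_date_cols, names(df))) {
      df[[col]] <- as.Date(df[[col]])
    }
    df
  }
  structure(
    list(
      counts = as_tbl(raw$counts), total = raw$total,
      pooled = as_tbl(raw$pooled),
      limits_site = as_tbl(raw$limits_site),
      limits_stratum = as_tbl(raw$limits_stratum),
      charts = as_tbl(raw$charts), alerts = as_tbl(raw$alerts),
      config = raw$config, provenance = raw$provenance
    ),
    class = "psqa_report"
  )
}
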