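#' @noRd
mandatory_columns <- function() {
  c("patient_key", "facility", "site", "qa_date", "gamma_3_3")
}

optional_columns <- function() {
  c("machine", "qa_device", "approval_date", "gamma_2_2", "dose_diff_pct")
}

record_columns <- function() {
  c("patient_key", "facility", "machine", "qa_device", "site",
    "qa_date", "approval_date", "gamma_3_3", "gamma_2_2", "dose_diff_pct")
}

parse_iso_date <- function(x) {
  if (inherits(x, "Date")) {
    return(x)
  }
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  out
}

parse_number_quiet <- function(x) {
  if (is.numeric(x)) {
    return(as.double(x))
  }
  suppressWarnings(as.double(ifelse(trimws(as.character(x)) == "", NA, x)))
}

#' Validate PSQA records
#'
#' Applies the entry-form validation rules to a table of PSQA measurements:
#' range checks for numerical fields, controlled vocabularies for
#' categorical fields, mandatory-field checks, and disease-site
#' normalization. Every input row is classified as accepted or rejected;
#' rejected rows carry at least one error-severity issue and are reported,
#' never silently dropped.
#'
#' Severity policy: a missing mandatory field, a gamma passing rate outside
#' \[0, 100\], a dose difference outside `dose_window`, an unparseable QA
#' date and an unmapped disease site are **errors** (row rejected); an
#' unknown machine, QA-device or facility label is a **warning** (row
#' accepted, issue recorded).
#'
#' @param data A data frame with one row per QA measurement. Recognized
#'   columns: `patient_key`, `facility`, `machine`, `qa_device`, `site`,
#'   `qa_date`, `approval_date` (ISO-8601 dates), one column per gamma
#'   criterion named `gamma_<dose>_<dta>` (percent), and `dose_diff_pct`.
#' @param vocab Controlled vocabularies, see [psqa_vocab()].
#' @param dose_window Plausibility window (inclusive) for `dose_diff_pct`,
#'   in percent; default `c(-10, 10)`.
#' @param synonyms Site synonym table for [normalize_site()].
#'
#' @return A list with `records` (tibble of accepted rows, sites
#'   canonicalized, dates as `Date`) and `report`, a `psqa_validation`
#'   object with fields `accepted`, `rejected` and an `issues` tibble
#'   (`row`, `field`, `rule`, `severity`).
#' @seealso [read_psqa()] which applies this on ingestion.
#' @export
validate_psqa <- function(data, vocab = psqa_vocab(),
                          dose_window = c(-10, 10),
                          synonyms = site_synonyms()) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(mandatory_columns(), names(data))
  if (length(missing_cols) > 0) {
    cli::cli_abort("Missing mandatory column{?s}: {.field {missing_cols}}.")
  }

  n <- nrow(data)
  data <- tibble::as_tibble(data)
  for (col in setdiff(optional_columns(), names(data))) {
    data[[col]] <- if (col == "approval_date") as.Date(NA) else NA
  }

  issues <- list()
  add_issue <- function(rows, field, rule, severity) {
    if (length(rows) > 0) {
      issues[[length(issues) + 1L]] <<- tibble::tibble(
        row = as.integer(rows), field = field, rule = rule, severity = severity
      )
    }
  }
  blank <- function(x) is.na(x) | !nzchar(trimws(as.character(x)))

  add_issue(which(blank(data$patient_key)), "patient_key", "missing_mandatory", "error")
  add_issue(which(blank(data$facility)), "facility", "missing_mandatory", "error")
  add_issue(
    which(!blank(data$facility) & !(data$facility %in% vocab$facilities)),
    "facility", "unknown_vocabulary", "warning"
  )
  add_issue(
    which(!blank(data$machine) & !(data$machine %in% vocab$machines)),
    "machine", "unknown_vocabulary", "warning"
  )
  add_issue(
    which(!blank(data$qa_device) & !(data$qa_device %in% vocab$qa_devices)),
    "qa_device", "unknown_vocabulary", "warning"
  )

  add_issue(which(blank(data$site)), "site", "missing_mandatory", "error")
  site_norm <- normalize_site(data$site, synonyms = synonyms)
  add_issue(
    which(!blank(data$site) & site_norm == "Unmapped"),
    "site", "unmapped_site", "error"
  )
  data$site <- site_norm

  qa_date <- parse_iso_date(data$qa_date)
  add_issue(
    which(blank(data$qa_date) | (!blank(data$qa_date) & is.na(qa_date))),
    "qa_date", "unparseable_date", "error"
  )
  data$qa_date <- qa_date
  approval <- parse_iso_date(data$approval_date)
  add_issue(
    which(!blank(data$approval_date) & is.na(approval)),
    "approval_date", "unparseable_date", "warning"
  )
  data$approval_date <- approval

  gamma_cols <- grep("^gamma_", names(data), value = TRUE)
  g33_blank <- blank(data$gamma_3_3)
  for (col in gamma_cols) {
    raw <- data[[col]]
    val <- parse_number_quiet(raw)
    add_issue(which(!blank(raw) & is.na(val)), col, "unparseable_number", "error")
    add_issue(
      which(!is.na(val) & (val < 0 | val > 100)),
      col, "out_of_range", "error"
    )
    data[[col]] <- val
  }
  add_issue(which(g33_blank), "gamma_3_3", "missing_mandatory", "error")

  raw_dose <- data$dose_diff_pct
  dose <- parse_number_quiet(raw_dose)
  add_issue(which(!blank(raw_dose) & is.na(dose)),
            "dose_diff_pct", "unparseable_number", "error")
  add_issue(
    which(!is.na(dose) & (dose < dose_window[1] | dose > dose_window[2])),
    "dose_diff_pct", "out_of_range", "error"
  )
  data$dose_diff_pct <- dose

  issues <- if (length(issues) > 0) {
    dplyr::arrange(dplyr::bind_rows(issues), .data$row, .data$field)
  } else {
    tibble::tibble(row = integer(), field = character(),
                   rule = character(), severity = character())
  }

  bad_rows <- sort(unique(issues$row[issues$severity == "error"]))
  keep <- setdiff(seq_len(n), bad_rows)
  ordered_cols <- c(
    intersect(record_columns(), names(data)),
    setdiff(names(data), record_columns())
  )
  records <- data[keep, ordered_cols]

  report <- structure(
    list(accepted = length(keep), rejected = length(bad_rows), issues = issues),
    class = "psqa_validation"
  )
  list(records = records, report = report)
}

#' @export
print.psqa_validation <- function(x, ...) {
  cat(sprintf(
    "<psqa validation> %d accepted, %d rejected, %d issue(s)\n",
    x$accepted, x$rejected, nrow(x$issues)
  ))
  if (nrow(x$issues) > 0) {
    print(x$issues, n = min(nrow(x$issues), 10))
  }
  invisible(x)
}

#' Read PSQA records from a CSV file
#'
#' Reads a delimited file of PSQA measurements (RFC-4180 CSV, UTF-8, one
#' row per verification, ISO-8601 dates, one `gamma_<d>_<d>` column per
#' criterion) and applies the full validation pass of [validate_psqa()].
#' Rows failing an error-severity rule are excluded from the returned
#' records but retained in the validation report.
#'
#' @param path Path to a CSV file whose header names at least the
#'   mandatory columns `patient_key`, `facility`, `site`, `qa_date`,
#'   `gamma_3_3`.
#' @inheritParams validate_psqa
#'
#' @return A tibble of accepted records; the `psqa_validation` report is
#'   attached as attribute `"validation"` (retrieve with
#'   [validation_report()]).
#' @examples
#' path <- tempfile(fileext = ".csv")
#' cohort <- generate_cohort(seed = 1)
#' write_psqa(cohort$records, path)
#' rec <- read_psqa(path)
#' validation_report(rec)
#' @export
read_psqa <- function(path, vocab = psqa_vocab(), dose_window = c(-10, 10),
                      synonyms = site_synonyms()) {
  if (!file.exists(path)) {
    cli::cli_abort("File {.path {path}} does not exist.")
  }
  raw <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    error = function(e) cli::cli_abort("Cannot parse {.path {path}}: {conditionMessage(e)}")
  )
  res <- validate_psqa(raw, vocab = vocab, dose_window = dose_window,
                       synonyms = synonyms)
  structure(res$records, validation = res$report)
}

#' @rdname read_psqa
#' @param records A tibble returned by [read_psqa()].
#' @export
validation_report <- function(records) {
  attr(records, "validation")
}

#' Write PSQA records to CSV
#'
#' Inverse of [read_psqa()]: writes records with ISO-8601 dates and empty
#' strings for missing optional fields, so that a write/read round trip
#' reproduces the records field-for-field.
#'
#' @param records Tibble of PSQA records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_psqa <- function(records, path) {
  stopifnot(is.data.frame(records))
  out <- tibble::as_tibble(records)
  attr(out, "validation") <- NULL
  tryCatch(
    readr::write_csv(out, path, na = ""),
    error = function(e) cli::cli_abort("Cannot write {.path {path}}: {conditionMessage(e)}")
  )
  invisible(path)
}

#' Filter PSQA records by stratum and date window
#'
#' Subsets records by disease site, facility and/or an inclusive QA-date
#' window, preserving input order. Query values are checked against the
#' controlled vocabularies; an unknown value is an error rather than an
#' empty result, so typos cannot masquerade as absent data.
#'
#' @param records Tibble of PSQA records.
#' @param site,facility Optional character vectors of canonical site /
#'   facility labels to keep.
#' @param from,to Optional inclusive date-window bounds (`Date` or
#'   ISO-8601 strings).
#' @param vocab Controlled vocabularies used to check the query.
#' @return The matching rows, input order preserved.
#' @examples
#' cohort <- generate_cohort(seed = 1)
#' nrow(filter_psqa(cohort$records, site = "Pelvis"))
#' @export
filter_psqa <- function(records, site = NULL, facility = NULL,
                        from = NULL, to = NULL, vocab = psqa_vocab()) {
  stopifnot(is.data.frame(records))
  if (!is.null(site)) {
    bad <- setdiff(site, vocab$sites)
    if (length(bad) > 0) {
      cli::cli_abort("Unknown site{?s} in query: {.val {bad}}.")
    }
  }
  if (!is.null(facility)) {
    bad <- setdiff(facility, vocab$facilities)
    if (length(bad) > 0) {
      cli::cli_abort("Unknown facilit{?y/ies} in query: {.val {bad}}.")
    }
  }
  keep <- rep(TRUE, nrow(records))
  if (!is.null(site)) keep <- keep & records$site %in% site
  if (!is.null(facility)) keep <- keep & records$facility %in% facility
  if (!is.null(from)) keep <- keep & records$qa_date >= as.Date(from)
  if (!is.null(to)) keep <- keep & records$qa_date <= as.Date(to)
  records[which(keep), ]
}
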