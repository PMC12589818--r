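#' Stratum specifications for the shipped multi-facility preset
#'
#' `showa2016_strata()` returns the default synthetic-cohort calibration: a
#' 4-facility x 5-site network of 835 PSQA records split 147/256/89/258/85
#' across disease sites (CNS, HeadNeck, Chest, Pelvis, Other), with pooled
#' gamma passing rates near 99.4 +/- 1.3 (3%/3mm channel), a wider-spread
#' 2%/2mm channel near 94.3 +/- 7.7, and a dose-difference channel at
#' 0.46 +/- 0.98.
#'
#' Per-stratum means and SDs are a calibration choice, not measured values:
#' site baselines are set so the analytic action limit
#' `100 - (beta/2) * sqrt(sd^2 + (mean - 100)^2)` at `beta = 6` lands near
#' the published per-site limits, and facility effects (a multiplier on the
#' mean's gap to 100 and a scale on the SD) order the facilities from
#' tightest (NorthernYokohama) to widest (Fujigaoka) process spread.
#' Facility shares of each site's caseload are 0.35/0.25/0.20/0.20,
#' apportioned by largest remainder.
#'
#' @param date_start,date_end QA-date range over which records are spread.
#' @return A tibble with one row per (facility, site) stratum: `facility`,
#'   `site`, `machine`, `qa_device`, `n`, per-channel `mean_3_3`/`sd_3_3`,
#'   `mean_2_2`/`sd_2_2`, `mean_dose`/`sd_dose`, `date_start`, `date_end`.
#' @examples
#' strata <- showa2016_strata()
#' sum(strata$n)
#' @export
showa2016_strata <- function(date_start = as.Date("2016-01-04"),
                             date_end = as.Date("2024-12-27")) {
  sites <- tibble::tibble(
    site = psqa_sites(),
    n_site = c(147L, 256L, 89L, 258L, 85L),
    mean_3_3 = c(99.80, 99.35, 99.60, 98.90, 99.40),
    sd_3_3 = c(0.30, 1.00, 0.60, 1.84, 1.20),
    mean_2_2 = c(98.5, 93.5, 96.0, 92.5, 94.0),
    sd_2_2 = c(2.0, 7.0, 4.0, 10.0, 8.0)
  )
  facilities <- tibble::tibble(
    facility = c("UniversityHospital", "KotoToyosu", "NorthernYokohama",
                 "Fujigaoka"),
    machine = c("Clinac iX", "Infinity", "TrueBeam STx", "TrueBeam"),
    qa_device = c("ArcCHECK", "ArcCHECK", "Delta4", "ArcCHECK"),
    share = c(0.35, 0.25, 0.20, 0.20),
    gap_mult = c(1.000, 0.545, 0.118, 2.273),
    sd_mult = c(1.000, 0.300, 0.055, 1.530)
  )
  strata <- tidyr::crossing(facilities, sites)
  strata <- strata |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(n = largest_remainder(.data$n_site[1], .data$share)) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      mean_3_3 = 100 - (100 - .data$mean_3_3) * .data$gap_mult,
      sd_3_3 = .data$sd_3_3 * .data$sd_mult,
      mean_2_2 = 100 - (100 - .data$mean_2_2) * .data$gap_mult,
      sd_2_2 = .data$sd_2_2 * .data$sd_mult,
      mean_dose = 0.46,
      sd_dose = 0.98,
      date_start = date_start,
      date_end = date_end
    )
  # preset ordering: facility blocks, sites in canonical order within each
  strata$facility <- factor(strata$facility, levels = facilities$facility)
  strata$site <- factor(strata$site, levels = sites$site)
  strata <- dplyr::arrange(strata, .data$facility, .data$site)
  strata$facility <- as.character(strata$facility)
  strata$site <- as.character(strata$site)
  dplyr::select(
    strata, "facility", "site", "machine", "qa_device", "n",
    "mean_3_3", "sd_3_3", "mean_2_2", "sd_2_2", "mean_dose", "sd_dose",
    "date_start", "date_end"
  )
}

# Apportion n by weights, floors first, leftovers to largest remainders
# (ties broken by position).
largest_remainder <- function(n, weights) {
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

validate_strata <- function(strata) {
  needed <- c("facility", "site", "n", "mean_3_3", "sd_3_3")
  missing <- setdiff(needed, names(strata))
  if (length(missing) > 0) {
    cli::cli_abort("Stratum spec lacks column{?s} {.field {missing}}.")
  }
  if (any(strata$n < 0)) {
    cli::cli_abort("Stratum record counts must be >= 0.")
  }
  sd_cols <- intersect(c("sd_3_3", "sd_2_2", "sd_dose"), names(strata))
  for (col in sd_cols) {
    if (any(strata[[col]] < 0, na.rm = TRUE)) {
      cli::cli_abort("Stratum SDs must be >= 0 ({.field {col}}).")
    }
  }
  for (col in intersect(c("mean_3_3", "mean_2_2"), names(strata))) {
    if (any(strata[[col]] > 100, na.rm = TRUE)) {
      cli::cli_abort("Gamma channel means cannot exceed 100 ({.field {col}}).")
    }
  }
  invisible(strata)
}

#' Generate a synthetic multi-facility PSQA cohort
#'
#' Draws per-stratum Gaussian gamma passing rates and dose differences from
#' a stratum specification table (default: the [showa2016_strata()]
#' preset), emulating a pooled multi-institution QA database. Gamma
#' channels are clipped to \[0, 100\] (passing rates are percentages);
#' per-stratum clipping rates are reported in the manifest so their bias on
#' sample moments can be bounded. QA dates are spread evenly over each
#' stratum's date range in chronological order, and plan-approval dates
#' precede QA by one week.
#'
#' The generator is deterministic: a single RNG stream seeded once is
#' consumed in stratum order, so identical `(strata, seed)` reproduce a
#' byte-identical cohort, and the returned manifest suffices to regenerate
#' it.
#'
#' @param strata Stratum specification tibble, see [showa2016_strata()].
#' @param seed Integer RNG seed (required).
#' @param clip Clip gamma channels to \[0, 100\] (default `TRUE`). Set
#'   `FALSE` for method-validation draws where the untruncated Gaussian is
#'   the reference process.
#'
#' @return A list with `records` (tibble of PSQA records) and `manifest`
#'   (class `psqa_manifest`: `seed`, `strata`, `clip`, `n_total`,
#'   `clip_rates` tibble).
#' @examples
#' cohort <- generate_cohort(seed = 20160104)
#' nrow(cohort$records)
#' cohort$manifest$clip_rates
#' @export
generate_cohort <- function(strata = showa2016_strata(), seed, clip = TRUE) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    cli::cli_abort("{.arg seed} must be a single integer.")
  }
  validate_strata(strata)
  strata <- tibble::as_tibble(strata)
  if (!"machine" %in% names(strata)) strata$machine <- NA_character_
  if (!"qa_device" %in% names(strata)) strata$qa_device <- NA_character_
  if (!"date_start" %in% names(strata)) strata$date_start <- as.Date("2016-01-01")
  if (!"date_end" %in% names(strata)) strata$date_end <- as.Date("2024-12-31")

  set.seed(as.integer(seed))
  key_offset <- 0L
  pieces <- vector("list", nrow(strata))
  clip_rates <- vector("list", nrow(strata))
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    n <- s$n
    if (n == 0) {
      pieces[[i]] <- NULL
      next
    }
    qa_date <- as.Date(round(seq(as.numeric(as.Date(s$date_start)),
                                 as.numeric(as.Date(s$date_end)),
                                 length.out = n)), origin = "1970-01-01")
    draw <- function(mean_col, sd_col) {
      if (!mean_col %in% names(s) || is.na(s[[mean_col]])) {
        return(rep(NA_real_, n))
      }
      rnorm(n, mean = s[[mean_col]], sd = s[[sd_col]])
    }
    g33 <- draw("mean_3_3", "sd_3_3")
    g22 <- draw("mean_2_2", "sd_2_2")
    dd <- draw("mean_dose", "sd_dose")
    n_clip33 <- n_clip22 <- 0L
    if (clip) {
      n_clip33 <- sum(g33 < 0 | g33 > 100, na.rm = TRUE)
      n_clip22 <- sum(g22 < 0 | g22 > 100, na.rm = TRUE)
      g33 <- pmin(pmax(g33, 0), 100)
      g22 <- pmin(pmax(g22, 0), 100)
    }
    pieces[[i]] <- tibble::tibble(
      patient_key = sprintf("PT%05d", key_offset + seq_len(n)),
      facility = s$facility,
      machine = s$machine,
      qa_device = s$qa_device,
      site = s$site,
      qa_date = qa_date,
      approval_date = qa_date - 7L,
      gamma_3_3 = g33,
      gamma_2_2 = g22,
      dose_diff_pct = dd
    )
    clip_rates[[i]] <- tibble::tibble(
      facility = s$facility, site = s$site,
      channel = c("3%/3mm", "2%/2mm"),
      n_clipped = c(n_clip33, n_clip22),
      rate = c(n_clip33, n_clip22) / n
    )
    key_offset <- key_offset + n
  }
  records <- dplyr::bind_rows(pieces)
  if (nrow(records) == 0) {
    records <- tibble::tibble(
      patient_key = character(), facility = character(),
      machine = character(), qa_device = character(), site = character(),
      qa_date = as.Date(character()), approval_date = as.Date(character()),
      gamma_3_3 = double(), gamma_2_2 = double(), dose_diff_pct = double()
    )
  }
  manifest <- structure(
    list(
      seed = as.integer(seed), strata = strata, clip = clip,
      n_total = nrow(records),
      clip_rates = dplyr::bind_rows(clip_rates)
    ),
    class = "psqa_manifest"
  )
  list(records = records, manifest = manifest)
}

#' @export
print.psqa_manifest <- function(x, ...) {
  cat(sprintf(
    "<psqa cohort manifest> %d records, %d strata, seed %d, clip %s\n",
    x$n_total, nrow(x$strata), x$seed, x$clip
  ))
  invisible(x)
}

#' Inject known anomalies into a PSQA cohort
#'
#' Adds point outliers, step shifts or linear drifts at known positions so
#' that downstream detection (control-chart flags, IQR outlier alerts) can
#' be scored against ground truth. Indices refer to rows of `records` in
#' their current (chronological) order. Gamma channels are re-clipped to
#' \[0, 100\] after injection; rows not named by any anomaly are returned
#' bit-identical.
#'
#' Anomaly kinds (all additive on the chosen channel):
#' * `point_outlier` — adds `magnitude` at each index in `at`.
#' * `step_shift` — adds `magnitude` to every row at index >= `at`.
#' * `linear_drift` — adds a ramp growing linearly from 0 at index `at`
#'   to `magnitude` at the last row.
#'
#' @param records Tibble of PSQA records, chronologically ordered.
#' @param anomalies Tibble with columns `kind` (one of the three above),
#'   `channel` (anything [channel_column()] accepts), `magnitude`
#'   (additive, in the channel's units) and `at` (row index; for
#'   `point_outlier` may be a list-column of index vectors).
#'
#' @return A list with `records` (modified tibble) and `truth`, a tibble
#'   of ground-truth per-row perturbations (`kind`, `channel`, `row`,
#'   `delta`).
#' @examples
#' cohort <- generate_cohort(seed = 7)
#' spec <- tibble::tibble(kind = "point_outlier", channel = "3%/3mm",
#'                        magnitude = -15, at = list(c(5L, 40L)))
#' out <- inject_anomalies(cohort$records, spec)
#' out$truth
#' @export
inject_anomalies <- function(records, anomalies) {
  stopifnot(is.data.frame(records))
  if (is.null(anomalies) || nrow(anomalies) == 0) {
    return(list(records = records, truth = tibble::tibble(
      kind = character(), channel = character(), row = integer(),
      delta = double()
    )))
  }
  n <- nrow(records)
  truth <- list()
  for (i in seq_len(nrow(anomalies))) {
    a <- anomalies[i, ]
    col <- channel_column(a$channel[[1]])
    if (!col %in% names(records)) {
      cli::cli_abort("Channel column {.field {col}} not present in records.")
    }
    at <- a$at[[1]]
    at <- as.integer(at)
    if (any(at < 1 | at > n)) {
      cli::cli_abort("Anomaly index out of range (1..{n}).")
    }
    kind <- a$kind[[1]]
    delta <- switch(
      kind,
      point_outlier = {
        rows <- at
        rep(a$magnitude[[1]], length(rows))
      },
      step_shift = {
        rows <- seq.int(at[1], n)
        rep(a$magnitude[[1]], length(rows))
      },
      linear_drift = {
        rows <- seq.int(at[1], n)
        if (length(rows) == 1L) {
          a$magnitude[[1]]
        } else {
          a$magnitude[[1]] * (rows - at[1]) / (n - at[1])
        }
      },
      cli::cli_abort("Unknown anomaly kind {.val {kind}}.")
    )
    records[[col]][rows] <- records[[col]][rows] + delta
    truth[[length(truth) + 1L]] <- tibble::tibble(
      kind = kind, channel = col, row = rows, delta = delta
    )
  }
  for (col in grep("^gamma_", names(records), value = TRUE)) {
    records[[col]] <- pmin(pmax(records[[col]], 0), 100)
  }
  list(records = records, truth = dplyr::bind_rows(truth))
}
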