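one_stratum <- function(n, mean = 99.4, sd = 1.3,
                        facility = "UniversityHospital", site = "Pelvis") {
  tibble::tibble(
    facility = facility, site = site, n = as.integer(n),
    mean_3_3 = mean, sd_3_3 = sd,
    mean_2_2 = 94.3, sd_2_2 = 7.7,
    mean_dose = 0.46, sd_dose = 0.98,
    date_start = as.Date("2016-01-01"), date_end = as.Date("2020-12-31")
  )
}

test_that("the showa2016 preset reproduces the published cohort structure", {
  strata <- showa2016_strata()
  expect_equal(nrow(strata), 20)  # 4 facilities x 5 sites
  by_site <- tapply(strata$n, strata$site, sum)
  expect_equal(by_site[["CNS"]], 147)
  expect_equal(by_site[["HeadNeck"]], 256)
  expect_equal(by_site[["Chest"]], 89)
  expect_equal(by_site[["Pelvis"]], 258)
  expect_equal(by_site[["Other"]], 85)
  expect_equal(sum(strata$n), 835)
  expect_true(all(strata$sd_3_3 >= 0 & strata$mean_3_3 <= 100))
})

test_that("generation is deterministic and clipped to the percentage scale", {
  a <- generate_cohort(seed = 123)
  b <- generate_cohort(seed = 123)
  expect_identical(a$records, b$records)
  # byte-identical files
  fa <- tempfile(fileext = ".csv")
  fb <- tempfile(fileext = ".csv")
  write_psqa(a$records, fa)
  write_psqa(b$records, fb)
  expect_identical(readBin(fa, "raw", file.size(fa)),
                   readBin(fb, "raw", file.size(fb)))
  # different seed, different cohort
  c_ <- generate_cohort(seed = 124)
  expect_false(identical(a$records$gamma_3_3, c_$records$gamma_3_3))
  # clipping invariant
  expect_true(all(a$records$gamma_3_3 >= 0 & a$records$gamma_3_3 <= 100))
  expect_true(all(a$records$gamma_2_2 >= 0 & a$records$gamma_2_2 <= 100))
  # regeneration from the manifest is bit-identical
  again <- generate_cohort(a$manifest$strata, seed = a$manifest$seed,
                           clip = a$manifest$clip)
  expect_identical(a$records, again$records)
})

test_that("qa dates are chronological within stratum and approval precedes QA", {
  co <- generate_cohort(seed = 9)
  by_stratum <- split(co$records, paste(co$records$facility, co$records$site))
  for (g in by_stratum) {
    expect_true(all(diff(as.numeric(g$qa_date)) >= 0))
  }
  expect_true(all(co$records$approval_date < co$records$qa_date))
})

test_that("degenerate specs are handled: n = 0 empty, invalid spec errors", {
  empty <- generate_cohort(one_stratum(0), seed = 1)
  expect_equal(nrow(empty$records), 0)
  expect_error(generate_cohort(one_stratum(-1), seed = 1), "0")
  bad_sd <- one_stratum(5)
  bad_sd$sd_3_3 <- -1
  expect_error(generate_cohort(bad_sd, seed = 1), "SD")
  bad_mean <- one_stratum(5)
  bad_mean$mean_3_3 <- 101
  expect_error(generate_cohort(bad_mean, seed = 1), "100")
  expect_error(generate_cohort(one_stratum(5)), "seed")
})

test_that("sample moments converge to the specification (4 SE tolerance)", {
  n <- 10000
  co <- generate_cohort(one_stratum(n, mean = 99.4, sd = 1.3),
                        seed = 2016, clip = FALSE)
  g <- co$records$gamma_3_3
  expect_lt(abs(mean(g) - 99.4), 4 * 1.3 / sqrt(n))
  expect_lt(abs(sd(g) - 1.3), 4 * 1.3 / sqrt(2 * n))
  d <- co$records$dose_diff_pct
  expect_lt(abs(mean(d) - 0.46), 4 * 0.98 / sqrt(n))
  # spec example: mean within 3 sigma / sqrt(n) of target before clipping
  expect_lt(abs(mean(g) - 99.4), 3 * 1.3 / sqrt(n))
})

test_that("reported clipping rates agree with the normal upper-tail mass", {
  co <- generate_cohort(seed = 77)
  cr <- co$manifest$clip_rates
  expect_true(all(cr$rate >= 0 & cr$rate <= 1))
  # each stratum's clip rate is a binomial draw with success probability
  # P(X > 100) under its generating Gaussian (lower clips are negligible)
  strata <- co$manifest$strata
  for (i in seq_len(nrow(strata))) {
    s <- strata[i, ]
    for (ch in c("3%/3mm", "2%/2mm")) {
      mu <- if (ch == "3%/3mm") s$mean_3_3 else s$mean_2_2
      sig <- if (ch == "3%/3mm") s$sd_3_3 else s$sd_2_2
      p <- stats::pnorm(100, mu, sig, lower.tail = FALSE)
      got <- cr$rate[cr$facility == s$facility & cr$site == s$site &
                       cr$channel == ch]
      expect_lt(abs(got - p), 4 * sqrt(p * (1 - p) / s$n) + 1e-9)
    }
  }
})

test_that("anomaly injection is additive, indexed, and ground-truthed", {
  rec <- make_fixture_records(5)
  # empty spec list is the identity
  none <- inject_anomalies(rec, NULL)
  expect_identical(none$records, rec)
  expect_equal(nrow(none$truth), 0)

  const <- make_fixture_records(10)
  const$gamma_3_3 <- 99
  out <- inject_anomalies(const, tibble::tibble(
    kind = "point_outlier", channel = "3%/3mm", magnitude = -15,
    at = list(7L)
  ))
  expect_equal(out$records$gamma_3_3[7], 84)
  expect_equal(out$records$gamma_3_3[-7], rep(99, 9))
  expect_equal(out$truth$row, 7L)
  expect_equal(out$truth$delta, -15)
  # untouched columns and rows bit-identical
  expect_identical(out$records$gamma_2_2, const$gamma_2_2)

  n <- 100
  series <- make_fixture_records(5)[rep(1, n), ]
  series$gamma_3_3 <- 99
  shifted <- inject_anomalies(series, tibble::tibble(
    kind = "step_shift", channel = "3%/3mm", magnitude = -3, at = list(50L)
  ))
  expect_equal(shifted$records$gamma_3_3, c(rep(99, 49), rep(96, 51)))
  expect_equal(range(shifted$truth$row), c(50, 100))

  drift <- inject_anomalies(series, tibble::tibble(
    kind = "linear_drift", channel = "3%/3mm", magnitude = -4, at = list(51L)
  ))
  v <- drift$records$gamma_3_3
  expect_equal(v[51], 99)          # ramp starts at zero
  expect_equal(v[100], 95)         # and reaches the full magnitude
  expect_true(all(diff(v[51:100]) < 0))

  expect_error(
    inject_anomalies(series, tibble::tibble(
      kind = "point_outlier", channel = "3%/3mm", magnitude = -5,
      at = list(500L)
    )),
    "range"
  )
})
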