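test_that("process summaries use the sample (n-1) standard deviation", {
  s <- process_summary(c(99, 99, 99), target = 100)
  expect_equal(s$n, 3)
  expect_equal(s$mean, 99)
  expect_equal(s$sd, 0)
  s2 <- process_summary(c(98, 100), target = 100)
  expect_equal(s2$mean, 99)
  expect_equal(s2$sd, sqrt(2))
  expect_error(process_summary(99), "2")
  expect_error(process_summary(c(1, NA, Inf)), "2")
})

test_that("the tolerance width matches its closed form on reference inputs", {
  # perfect process: zero width for any beta
  expect_equal(delta_a(mean = 100, sd = 0, target = 100, beta = 6), 0)
  expect_equal(delta_a(mean = 100, sd = 0, target = 100, beta = 2), 0)
  # pooled 3%/3mm moments
  expect_equal(delta_a(mean = 99.4, sd = 1.3, target = 100, beta = 6),
               6 * sqrt(1.69 + 0.36))
  expect_equal(delta_a(mean = 99.4, sd = 1.3), 8.5907, tolerance = 1e-4)
  # dose-difference channel about target zero
  expect_equal(delta_a(mean = 0.46, sd = 0.98, target = 0, beta = 6),
               6 * sqrt(0.9604 + 0.2116))
  expect_equal(delta_a(mean = 0.46, sd = 0.98, target = 0), 6.4953,
               tolerance = 1e-4)
  # summary-first calling convention
  expect_equal(delta_a(process_summary(c(98, 100), target = 100)),
               6 * sqrt(2 + 1))
  expect_error(delta_a(mean = 99, sd = 1, beta = -1), "positive")
})

test_that("tolerance width is monotone in spread and offset, linear in beta (property)", {
  set.seed(7)
  for (i in 1:200) {
    m <- runif(1, 90, 100)
    s <- runif(1, 0, 5)
    b <- runif(1, 0.5, 10)
    base <- delta_a(mean = m, sd = s, target = 100, beta = b)
    expect_gte(delta_a(mean = m, sd = s + runif(1, 0, 2), target = 100, beta = b), base)
    expect_gte(delta_a(mean = m - runif(1, 0, 2), sd = s, target = 100, beta = b), base)
    lam <- runif(1, 0.1, 3)
    expect_equal(delta_a(mean = m, sd = s, target = 100, beta = lam * b),
                 lam * base)
  }
})

test_that("action limits follow AL = 100 - delta_A/2 and cap at 100", {
  expect_equal(action_limit(0), 100)
  expect_equal(action_limit(8.5907), 95.70465)
  expect_equal(action_limit(12.8), 93.6)  # the published Pelvis value inverts to width 12.8
  expect_equal(action_limit(6.4953, channel = "dose"), -3.24765)
  expect_error(action_limit(-1), ">= 0")
  # AL <= 100 always, equality only for a perfect process
  set.seed(8)
  d <- delta_a(mean = runif(50, 90, 100), sd = runif(50, 0, 4))
  expect_true(all(action_limit(d) <= 100))
})

test_that("tolerance limits derive from the individuals chart and are order-sensitive", {
  expect_equal(tolerance_limit(c(99, 99, 99)), 99)
  v <- c(98, 100, 99, 97)
  expect_equal(tolerance_limit(v), 98.5 - 2.660 * 5 / 3)
  expect_equal(tolerance_limit(v), 94.0667, tolerance = 1e-4)
  expect_equal(tolerance_limit(v, side = "upper"), 98.5 + 2.660 * 5 / 3)
  # permuting the series generally changes mR-bar, hence the limit
  expect_false(isTRUE(all.equal(tolerance_limit(v),
                                tolerance_limit(sort(v)))))
  expect_error(tolerance_limit(99), "2")
})

test_that("per-stratum limits agree with direct calls and symmetric strata match", {
  rec <- make_fixture_records(5)
  rec$site <- "Pelvis"
  rec$facility <- "UniversityHospital"
  lim <- suppressWarnings(tg218_limits(rec, group_by = "site", min_n = 3))
  expect_equal(nrow(lim), 1)
  ord <- order(rec$qa_date)
  expect_equal(lim$delta_A, delta_a(process_summary(rec$gamma_3_3, 100)))
  expect_equal(lim$AL, action_limit(delta_a(process_summary(rec$gamma_3_3, 100))))
  expect_equal(lim$TL, tolerance_limit(rec$gamma_3_3[ord]))

  # two identical strata yield identical limit sets
  rec2 <- rec
  rec2$facility <- "Fujigaoka"
  both <- suppressWarnings(
    tg218_limits(dplyr::bind_rows(rec, rec2), group_by = "facility", min_n = 3)
  )
  expect_equal(nrow(both), 2)
  expect_equal(both$AL[1], both$AL[2])
  expect_equal(both$TL[1], both$TL[2])
})

test_that("small strata are flagged provisional; TL below AL is flagged, not forbidden", {
  co <- generate_cohort(seed = 31)
  lim <- tg218_limits(co$records, group_by = c("facility", "site"), min_n = 60)
  small <- lim$n < 60
  expect_true(any(small))
  expect_true(all(grepl("provisional", lim$flags[small])))
  expect_true(all(!grepl("provisional", lim$flags[!small])))
  tl_low <- lim$TL < lim$AL
  expect_identical(grepl("TL_below_AL", lim$flags), tl_low)
})

test_that("dose-difference limits are two-sided about zero", {
  co <- generate_cohort(seed = 5)
  lim <- tg218_limits(co$records, group_by = "site", channel = "dose")
  expect_true(all(c("AL", "AL_upper", "TL", "TL_upper") %in% names(lim)))
  expect_equal(lim$AL, -lim$AL_upper)
  expect_true(all(lim$TL < lim$TL_upper))
})

test_that("estimated limits recover the analytic value on a clean Gaussian stratum", {
  strata <- tibble::tibble(
    facility = "UniversityHospital", site = "Pelvis", n = 10000L,
    mean_3_3 = 99.4, sd_3_3 = 1.3
  )
  co <- generate_cohort(strata, seed = 314, clip = FALSE)
  est_al <- action_limit(delta_a(process_summary(co$records$gamma_3_3, 100)))
  analytic <- 100 - (6 / 2) * sqrt(1.3^2 + (99.4 - 100)^2)
  expect_equal(analytic, 95.70465, tolerance = 1e-6)
  expect_lt(abs(est_al - analytic), 0.1)
})
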