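# Brute-force oracles, written independently of the package internals:
# explicit loops and first-principles formulas only.

oracle_mean <- function(x) {
  s <- 0
  for (v in x) s <- s + v
  s / length(x)
}

oracle_sd <- function(x) {
  m <- oracle_mean(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  sqrt(s / (length(x) - 1))
}

oracle_delta_a <- function(x, target, beta) {
  beta * sqrt(oracle_sd(x)^2 + (oracle_mean(x) - target)^2)
}

oracle_moving_ranges <- function(x) {
  out <- numeric(length(x) - 1)
  for (i in 2:length(x)) out[i - 1] <- abs(x[i] - x[i - 1])
  out
}

oracle_chart <- function(x) {
  cl <- oracle_mean(x)
  mr <- oracle_mean(oracle_moving_ranges(x))
  list(
    centerline = cl,
    mr_bar = mr,
    ucl = cl + 2.660 * mr,
    lcl = cl - 2.660 * mr
  )
}

oracle_tolerance_limit <- function(x) {
  oracle_chart(x)$lcl
}

# Quartile by linear interpolation between order statistics
# (h = (n - 1) p + 1), computed from scratch.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

oracle_iqr_fences <- function(x, k) {
  q1 <- oracle_quantile(x, 0.25)
  q3 <- oracle_quantile(x, 0.75)
  c(lower = q1 - k * (q3 - q1), upper = q3 + k * (q3 - q1))
}

oracle_iqr_flagged <- function(x, k) {
  f <- oracle_iqr_fences(x, k)
  hits <- integer(0)
  for (i in seq_along(x)) {
    if (x[i] < f[["lower"]] || x[i] > f[["upper"]]) hits <- c(hits, i)
  }
  hits
}

# A small, fully valid record table built in code.
make_fixture_records <- function(n = 5) {
  tibble::tibble(
    patient_key = sprintf("PT%03d", seq_len(n)),
    facility = rep(c("UniversityHospital", "Fujigaoka"), length.out = n),
    machine = rep("TrueBeam", n),
    qa_device = rep("ArcCHECK", n),
    site = rep(c("Pelvis", "CNS", "Pelvis", "Chest", "HeadNeck"),
               length.out = n),
    qa_date = as.Date("2020-01-01") + seq_len(n),
    approval_date = as.Date("2019-12-20") + seq_len(n),
    gamma_3_3 = round(seq(97, 100, length.out = n), 2),
    gamma_2_2 = round(seq(90, 99, length.out = n), 2),
    dose_diff_pct = round(seq(-1, 1, length.out = n), 2)
  )
}

write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path, na = "")
  path
}
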