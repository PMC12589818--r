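test_that("an empty cohort yields an empty but well-formed report", {
  rec <- make_fixture_records(2)[0, ]
  report <- run_analysis(rec)
  expect_equal(report$total, 0)
  expect_equal(nrow(report$counts), 0)
  expect_equal(nrow(report$limits_stratum), 0)
  expect_equal(nrow(report$alerts), 0)
  # the text rendering of an empty cohort must not crash
  path <- tempfile(fileext = ".txt")
  write_report(report, path, format = "text")
  expect_true(any(grepl("records: 0", readLines(path))))
})

test_that("the preset cohort report reproduces the stratified counts", {
  co <- generate_cohort(seed = 2016)
  report <- run_analysis(co$records, seed = 2016)
  counts <- setNames(report$counts$n, report$counts$site)
  expect_equal(counts[["CNS"]], 147)
  expect_equal(counts[["HeadNeck"]], 256)
  expect_equal(counts[["Chest"]], 89)
  expect_equal(counts[["Pelvis"]], 258)
  expect_equal(counts[["Other"]], 85)
  expect_equal(sum(report$counts$n), report$total)
  expect_equal(report$total, 835)
  # every counted site appears among the site limit sets
  expect_setequal(unique(report$limits_site$site), report$counts$site)
})

test_that("the pipeline is deterministic: identical inputs, identical report bytes", {
  co <- generate_cohort(seed = 55)
  r1 <- run_analysis(co$records, seed = 55)
  r2 <- run_analysis(co$records, seed = 55)
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_report(r1, f1)
  write_report(r2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("report JSON round-trips losslessly", {
  co <- generate_cohort(seed = 8)
  report <- run_analysis(co$records, seed = 8)
  path <- tempfile(fileext = ".json")
  write_report(report, path)
  back <- read_report(path)
  expect_equal(back$counts, report$counts)
  expect_equal(back$pooled, report$pooled)
  expect_equal(back$limits_stratum, tibble::as_tibble(report$limits_stratum))
  expect_equal(back$alerts, report$alerts)
  expect_equal(back$provenance$input_digest, report$provenance$input_digest)
  # serialization is idempotent: write(read(write(x))) == write(x)
  path2 <- tempfile(fileext = ".json")
  write_report(back, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("facility comparison mirrors the four-facility benchmarking table", {
  co <- generate_cohort(seed = 12)
  report <- run_analysis(co$records)
  cmp <- facility_comparison(report, site = "Pelvis", channel = "3%/3mm")
  expect_equal(nrow(cmp), 4)
  expect_equal(cmp$facility, sort(cmp$facility))
  expect_true(all(c("AL", "TL", "n", "flags") %in% names(cmp)))

  # single-facility cohort: the comparison row equals the pooled site limits
  solo <- co$records[co$records$facility == "Fujigaoka", ]
  rep_solo <- run_analysis(solo)
  cmp_solo <- facility_comparison(rep_solo, site = "Pelvis")
  expect_equal(nrow(cmp_solo), 1)
  pooled <- tg218_limits(solo, group_by = "site")
  expect_equal(cmp_solo$AL, pooled$AL[pooled$site == "Pelvis"])
  expect_equal(cmp_solo$TL, pooled$TL[pooled$site == "Pelvis"])

  # a facility below the minimum-n policy is present and flagged provisional
  small <- run_analysis(co$records, psqa_config(min_n = 100))
  cmp_small <- facility_comparison(small, site = "Chest")
  expect_equal(nrow(cmp_small), 4)
  expect_true(all(grepl("provisional", cmp_small$flags[cmp_small$n < 100])))

  expect_error(facility_comparison(
    run_analysis(co$records, psqa_config(group_by = "site")), site = "Pelvis"
  ), "stratified")
})

test_that("the CSV bundle writes one file per result table", {
  co <- generate_cohort(seed = 4)
  report <- run_analysis(co$records)
  dir <- tempfile()
  files <- write_report(report, dir, format = "csv")
  expect_setequal(
    basename(list.files(dir)),
    c("counts.csv", "pooled.csv", "limits_site.csv", "limits_stratum.csv",
      "charts.csv", "alerts.csv", "provenance.json")
  )
  back <- readr::read_csv(file.path(dir, "counts.csv"),
                          show_col_types = FALSE)
  expect_equal(sum(back$n), 835)
})

test_that("configuration can be loaded from YAML and rejects unknown keys", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c(
    "channels:", "  - 3%/3mm", "group_by: site", "beta: 4", "min_n: 10"
  ), path)
  cfg <- read_config(path)
  expect_s3_class(cfg, "psqa_config")
  expect_equal(cfg$channels, "gamma_3_3")
  expect_equal(cfg$beta, 4)
  expect_equal(cfg$group_by, "site")

  bad <- tempfile(fileext = ".yaml")
  writeLines("betta: 6", bad)
  expect_error(read_config(bad), "betta")
})

test_that("tidiers and plots expose the fitted objects", {
  co <- generate_cohort(seed = 6)
  report <- run_analysis(co$records)
  g <- glance(report)
  expect_equal(g$n_records, 835)
  expect_true("mean_3%/3mm" %in% names(g) || "mean_3%/3mm" %in% names(g) ||
                any(grepl("mean", names(g))))
  expect_s3_class(tidy(report), "tbl_df")

  ch <- spc_chart(co$records$gamma_3_3[1:50], dates = co$records$qa_date[1:50])
  expect_equal(nrow(tidy(ch)), 50)
  expect_equal(glance(ch)$n, 50)
  expect_s3_class(autoplot(ch), "ggplot")
  lim <- tg218_limits(co$records, group_by = "site")
  expect_s3_class(autoplot(lim), "ggplot")
  expect_s3_class(plot_channel_distributions(co$records), "ggplot")

  out <- iqr_outliers(co$records$gamma_2_2)
  expect_s3_class(tidy(out), "tbl_df")
  expect_equal(glance(out)$n, 835)

  v <- validate_psqa(make_fixture_records(3))
  expect_equal(glance(v$report)$accepted, 3)
  expect_s3_class(tidy(v$report), "tbl_df")
})
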