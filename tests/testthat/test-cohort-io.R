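test_that("event streams are sorted and creatinine is converted on read", {
  dir <- withr::local_tempdir()
  readr::write_csv(tibble::tibble(
    encounter_id = "e1",
    timestamp = c("2024-01-01T10:00:00", "2024-01-01T08:00:00",
                  "2024-01-01T09:00:00", "2024-01-01T12:00:00"),
    kind = c("urine_output", "urine_output", "urine_output", "creatinine"),
    value = c(50, 40, 60, 88.42)
  ), file.path(dir, "events.csv"))
  readr::write_csv(tibble::tibble(
    encounter_id = "e1", admission_time = "2024-01-01T07:00:00",
    discharge_time = "2024-01-03T07:00:00", age = 60, sex = "male",
    race_black = FALSE, unit = "GICU"
  ), file.path(dir, "encounters.csv"))

  cohort <- read_chart_events(file.path(dir, "events.csv"),
                              file.path(dir, "encounters.csv"),
                              creatinine_unit = "umol_l")
  uo <- cohort$events[cohort$events$kind == "urine_output", ]
  expect_false(is.unsorted(uo$timestamp))
  expect_equal(uo$value, c(40, 60, 50))
  expect_equal(cohort$events$value[cohort$events$kind == "creatinine"], 1.0,
               tolerance = 1e-12)
})

test_that("malformed inputs are hard errors naming the offending row", {
  dir <- withr::local_tempdir()
  enc_path <- file.path(dir, "encounters.csv")
  readr::write_csv(tibble::tibble(
    encounter_id = "e1", admission_time = "2024-01-01T00:00:00",
    discharge_time = "2024-01-03T00:00:00", age = 60, sex = "male",
    race_black = FALSE, unit = "GICU"), enc_path)
  write_events <- function(df) {
    p <- file.path(dir, "events.csv")
    readr::write_csv(df, p)
    p
  }
  base <- tibble::tibble(encounter_id = "e1",
                         timestamp = "2024-01-01T01:00:00",
                         kind = "urine_output", value = 10)
  expect_error(read_chart_events(
    write_events(dplyr::mutate(base, timestamp = "not-a-time")), enc_path),
    "unparseable timestamp.*row 1")
  expect_error(read_chart_events(
    write_events(dplyr::mutate(base, kind = "potassium")), enc_path),
    "unknown event kind")
  expect_error(read_chart_events(
    write_events(dplyr::mutate(base, value = -5)), enc_path),
    "negative value")
})

test_that("creatinine unit conversion round trips to 1e-9 relative tolerance", {
  x <- c(0.4, 1, 1.3, 4, 12.7)
  back <- convert_creatinine(convert_creatinine(x, "mg_dl", "umol_l"),
                             "umol_l", "mg_dl")
  expect_equal(back, x, tolerance = 1e-9)
})

test_that("synthetic cohort written to CSV and re-read is identical", {
  syn <- generate_cohort(cohort_config(n_encounters = 10, seed = 31))
  dir <- withr::local_tempdir()
  write_cohort(syn$cohort, dir)
  back <- read_chart_events(file.path(dir, "events.csv"),
                            file.path(dir, "encounters.csv"))
  expect_equal(back$events$value, syn$cohort$events$value)
  expect_equal(back$events$kind, syn$cohort$events$kind)
  expect_equal(as.numeric(back$events$timestamp),
               as.numeric(syn$cohort$events$timestamp))
  expect_equal(back$encounters$age, syn$cohort$encounters$age)
})

test_that("exclusion cascade counts each encounter under its first criterion", {
  enc_ok <- function(id, age = 60, events = TRUE) {
    list(id = id, age = age, events = events)
  }
  t0 <- T0
  encounters <- tibble::tibble(
    encounter_id = c("short", "nodem", "old", "oligo", "rrt", "nodata", "ok",
                     "old_and_rrt"),
    admission_time = t0,
    discharge_time = c(t0 + 20 * 3600, rep(t0 + 72 * 3600, 7)),
    age = c(60, NA, 95, 60, 60, 60, 60, 95),
    sex = "male", race_black = FALSE, unit = "GICU",
    admission_type = NA_character_, baseline_creatinine = NA_real_)
  normal_ev <- function(id) {
    dplyr::bind_rows(
      tibble::tibble(encounter_id = id, timestamp = t0, kind = "weight",
                     value = 80),
      tibble::tibble(encounter_id = id, timestamp = t0 + (1:48) * 3600,
                     kind = "urine_output", value = 80),
      tibble::tibble(encounter_id = id, timestamp = t0 + 6 * 3600,
                     kind = "creatinine", value = 0.9))
  }
  events <- dplyr::bind_rows(
    normal_ev("short"), normal_ev("nodem"), normal_ev("old"), normal_ev("ok"),
    normal_ev("old_and_rrt"),
    # oligoanuric first 6 h: 0.3 mL/kg/h at 80 kg
    tibble::tibble(encounter_id = "oligo", timestamp = t0, kind = "weight",
                   value = 80),
    tibble::tibble(encounter_id = "oligo", timestamp = t0 + (1:48) * 3600,
                   kind = "urine_output", value = c(rep(24, 8), rep(80, 40))),
    normal_ev("rrt"),
    tibble::tibble(encounter_id = c("rrt", "old_and_rrt"),
                   timestamp = t0 + 10 * 3600, kind = "rrt_start", value = 0)
  )
  res <- apply_exclusions(make_cohort(encounters, events))
  expect_equal(unname(res$report$excluded["short_stay"]), 1L)
  expect_equal(unname(res$report$excluded["missing_demographics"]), 1L)
  # both over-age encounters fall under age, incl. the one also on RRT
  expect_equal(unname(res$report$excluded["age_over_90"]), 2L)
  expect_equal(unname(res$report$excluded["admission_oligoanuria"]), 1L)
  expect_equal(unname(res$report$excluded["rrt"]), 1L)
  expect_equal(unname(res$report$excluded["insufficient_data"]), 1L)
  expect_equal(res$report$retained, 1L)
  expect_equal(res$retained$encounters$encounter_id, "ok")
  # conservation
  expect_equal(res$report$initial,
               res$report$retained + sum(res$report$excluded))
  # idempotence
  res2 <- apply_exclusions(res$retained)
  expect_equal(sum(res2$report$excluded), 0L)
  expect_equal(res2$report$retained, res$report$retained)
  # empty input
  res0 <- apply_exclusions(make_cohort(encounters[0, ], events[0, ]))
  expect_equal(res0$report$initial, 0L)
  expect_equal(sum(res0$report$excluded), 0L)
})

test_that("conservation holds on generated cohorts", {
  for (seed in c(5, 6)) {
    syn <- generate_cohort(cohort_config(n_encounters = 60, seed = seed))
    res <- apply_exclusions(syn$cohort)
    expect_equal(res$report$initial,
                 res$report$retained + sum(res$report$excluded))
  }
})

test_that("outcomes table writes deterministically and round trips", {
  syn <- generate_cohort(cohort_config(n_encounters = 8, seed = 12))
  out <- cohort_outcomes(apply_exclusions(syn$cohort)$retained)
  path <- withr::local_tempfile(fileext = ".csv")
  write_outcomes_table(out, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(out))
  expect_equal(back$max_stage, out$max_stage)
  expect_equal(names(back)[1], "encounter_id")
  # header-only CSV for an empty cohort
  path0 <- withr::local_tempfile(fileext = ".csv")
  write_outcomes_table(out[0, ], path0)
  expect_equal(nrow(readr::read_csv(path0, show_col_types = FALSE)), 0)
})

test_that("cohort_summary reports charted-baseline and RRT proportions", {
  t0 <- T0
  enc <- tibble::tibble(
    encounter_id = sprintf("e%02d", 1:20), admission_time = t0,
    discharge_time = t0 + 48 * 3600, age = 60,
    sex = rep(c("female", "male"), 10), race_black = FALSE,
    unit = rep(c("GICU", "CICU"), each = 10),
    admission_type = NA_character_,
    baseline_creatinine = c(rep(0.9, 6), rep(NA, 14)))
  evs <- tibble::tibble(encounter_id = c("e10", "e11"),
                        timestamp = t0 + 3600, kind = "rrt_start", value = 0)
  s <- cohort_summary(make_cohort(enc, evs))
  expect_equal(s$n_encounters, 20)
  expect_equal(s$pct_baseline_charted, 30)
  expect_equal(s$pct_rrt, 10)
  expect_equal(s$pct_female, 50)
  expect_equal(s$pct_gicu, 50)
})
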