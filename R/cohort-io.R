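#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Recognised chart-event kinds
#'
#' Long-format chart events carry one `kind` per row. Values are in
#' kind-specific units: urine output in mL accumulated since the previous
#' urine charting, creatinine in mg/dL internally (µmol/L accepted on read),
#' weight in kg, eGFR in mL/min/1.73 m², enoxaparin doses in mg. RRT
#' start/stop events delimit renal replacement therapy intervals.
#'
#' @export
chart_event_kinds <- c(
  "urine_output", "creatinine", "weight", "egfr",
  "enoxaparin_dose", "rrt_start", "rrt_stop", "baseline_creatinine"
)

#' µmol/L per mg/dL for creatinine
#' @export
UMOL_PER_MGDL <- 88.42

#' Convert a creatinine concentration between unit systems
#'
#' @param value numeric concentration(s).
#' @param from,to `"mg_dl"` or `"umol_l"`.
#' @return concentration in the `to` unit.
#' @export
convert_creatinine <- function(value, from = "umol_l", to = "mg_dl") {
  from <- match.arg(from, c("umol_l", "mg_dl"))
  to <- match.arg(to, c("umol_l", "mg_dl"))
  if (from == to) return(value)
  if (from == "umol_l") value / UMOL_PER_MGDL else value * UMOL_PER_MGDL
}

new_cohort <- function(encounters, events) {
  structure(list(encounters = encounters, events = events),
            class = "aki_cohort")
}

#' @export
print.aki_cohort <- function(x, ...) {
  cat(sprintf("<aki_cohort> %d encounters, %d chart events\n",
              nrow(x$encounters), nrow(x$events)))
  invisible(x)
}

#' Read long-format chart events and assemble an ICU cohort
#'
#' Reads the two study tables: `encounters.csv` (one row per ICU admission
#' with demographics and admission/discharge times) and `events.csv`
#' (long-format timestamped chart events). Event streams are sorted by
#' timestamp within encounter and creatinine values (including charted
#' baselines) are converted to the canonical internal unit, mg/dL.
#'
#' @param events_path path to the events CSV with columns `encounter_id`,
#'   `timestamp` (ISO-8601), `kind` (see [chart_event_kinds]), `value`.
#' @param encounters_path path to the encounters CSV with columns
#'   `encounter_id`, `admission_time`, `discharge_time`, `age`, `sex`,
#'   `race_black`, `unit`, and optionally `admission_type`,
#'   `baseline_creatinine`.
#' @param creatinine_unit unit system of creatinine values in the file
#'   (declared once per file, never mixed): `"mg_dl"` or `"umol_l"`.
#' @return an `aki_cohort`: a list with tibbles `encounters` and `events`.
#' @export
read_chart_events <- function(events_path, encounters_path,
                              creatinine_unit = c("mg_dl", "umol_l")) {
  creatinine_unit <- match.arg(creatinine_unit)
  events <- readr::read_csv(events_path, show_col_types = FALSE,
                            col_types = readr::cols(
                              encounter_id = readr::col_character(),
                              timestamp = readr::col_character(),
                              kind = readr::col_character(),
                              value = readr::col_double()
                            ))
  ts <- as.POSIXct(events$timestamp, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                                  "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                  "%Y-%m-%d"),
                   optional = TRUE)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stopf("unparseable timestamp '%s' in events row %d",
          events$timestamp[bad], bad)
  }
  events$timestamp <- ts
  unknown <- !events$kind %in% chart_event_kinds
  if (any(unknown)) {
    bad <- which(unknown)[1]
    stopf("unknown event kind '%s' in events row %d", events$kind[bad], bad)
  }
  if (any(events$value < 0, na.rm = TRUE)) {
    bad <- which(events$value < 0)[1]
    stopf("negative value %g in events row %d", events$value[bad], bad)
  }
  cr <- events$kind %in% c("creatinine", "baseline_creatinine")
  events$value[cr] <- convert_creatinine(events$value[cr],
                                         from = creatinine_unit, to = "mg_dl")
  events <- dplyr::arrange(events, .data$encounter_id, .data$timestamp)

  encounters <- readr::read_csv(encounters_path, show_col_types = FALSE)
  for (col in c("admission_time", "discharge_time")) {
    if (!inherits(encounters[[col]], "POSIXct")) {
      parsed <- as.POSIXct(as.character(encounters[[col]]), tz = "UTC",
                           tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                          "%Y-%m-%d %H:%M:%OS",
                                          "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"),
                           optional = TRUE)
      if (anyNA(parsed) && !all(is.na(encounters[[col]]))) {
        bad <- which(is.na(parsed) & !is.na(encounters[[col]]))[1]
        stopf("unparseable %s in encounters row %d", col, bad)
      }
      encounters[[col]] <- parsed
    }
  }
  encounters$encounter_id <- as.character(encounters$encounter_id)
  if (!"admission_type" %in% names(encounters)) {
    encounters$admission_type <- NA_character_
  }
  if (!"baseline_creatinine" %in% names(encounters)) {
    encounters$baseline_creatinine <- NA_real_
  } else {
    encounters$baseline_creatinine <-
      convert_creatinine(encounters$baseline_creatinine,
                         from = creatinine_unit, to = "mg_dl")
  }
  new_cohort(as_tibble(encounters), as_tibble(events))
}

#' Split a cohort into per-encounter objects
#'
#' @param cohort an `aki_cohort`.
#' @return a named list of `aki_encounter` objects, each carrying the
#'   demographics, the time-ordered event stream, the charted baseline
#'   creatinine (from the encounters table or the earliest
#'   `baseline_creatinine` event) and the RRT intervals paired from
#'   `rrt_start`/`rrt_stop` events (an unmatched start runs to discharge).
#' @export
as_encounters <- function(cohort) {
  stopifnot(inherits(cohort, "aki_cohort"))
  ev_split <- split(cohort$events, cohort$events$encounter_id)
  out <- purrr::pmap(cohort$encounters, function(...) {
    row <- list(...)
    ev <- ev_split[[row$encounter_id]] %||%
      cohort$events[0, , drop = FALSE]
    baseline <- row$baseline_creatinine
    if (is.null(baseline) || is.na(baseline)) {
      bl_ev <- ev[ev$kind == "baseline_creatinine", ]
      baseline <- if (nrow(bl_ev)) bl_ev$value[1] else NA_real_
    }
    starts <- ev$timestamp[ev$kind == "rrt_start"]
    stops <- ev$timestamp[ev$kind == "rrt_stop"]
    rrt <- if (length(starts)) {
      tibble(start = starts,
             stop = c(stops, rep(row$discharge_time,
                                 max(0, length(starts) - length(stops))))[
                                   seq_along(starts)])
    } else {
      tibble(start = as.POSIXct(character(), tz = "UTC"),
             stop = as.POSIXct(character(), tz = "UTC"))
    }
    structure(list(
      encounter_id = row$encounter_id,
      age = row$age, sex = row$sex, race_black = row$race_black,
      unit = row$unit, admission_type = row$admission_type %||% NA_character_,
      admission_time = row$admission_time,
      discharge_time = row$discharge_time,
      baseline_creatinine = baseline,
      events = ev, rrt_intervals = rrt
    ), class = "aki_encounter")
  })
  stats::setNames(out, cohort$encounters$encounter_id)
}

#' @export
print.aki_encounter <- function(x, ...) {
  cat(sprintf("<aki_encounter %s> %s, %d events, LOS %.1f h\n",
              x$encounter_id, x$unit, nrow(x$events),
              hours_between(x$discharge_time, x$admission_time)))
  invisible(x)
}

#' Exclusion-cascade configuration
#'
#' Criteria are applied in the fixed study order; every excluded encounter is
#' counted under the first criterion it fails.
#'
#' @param min_los_hours minimum length of stay (strict: LOS must exceed this).
#' @param max_age oldest age retained (strict: age > `max_age` is excluded).
#' @param oligoanuria_threshold mean weight-normalised urine output
#'   (mL/kg/h) below which the first hours of the stay count as admission
#'   oligoanuria.
#' @param oligoanuria_window_h length of the admission window examined (h);
#'   all of its hours must have urine charting coverage for the criterion to
#'   apply.
#' @return a list of class `exclusion_config`.
#' @export
exclusion_config <- function(min_los_hours = 24, max_age = 90,
                             oligoanuria_threshold = 0.5,
                             oligoanuria_window_h = 6) {
  structure(list(min_los_hours = min_los_hours, max_age = max_age,
                 oligoanuria_threshold = oligoanuria_threshold,
                 oligoanuria_window_h = oligoanuria_window_h),
            class = "exclusion_config")
}

exclusion_criteria <- c("short_stay", "missing_demographics", "age_over_90",
                        "admission_oligoanuria", "rrt", "insufficient_data")

#' Apply the study exclusion cascade
#'
#' Applies, in order: length of stay not exceeding 24 h; missing age, sex or
#' race; age above 90 years; acute kidney injury on admission (oligoanuria —
#' mean weight-normalised urine output below 0.5 mL/kg/h over the first 6 h,
#' requiring full urine charting coverage of that window); renal replacement
#' therapy during the stay; and insufficient data to compute at least one
#' stage stream (no creatinine, and no urine output with a weight). Each
#' excluded encounter is counted once, under the first criterion it fails.
#'
#' @param cohort an `aki_cohort`.
#' @param config an [exclusion_config()].
#' @return a list with `retained` (an `aki_cohort` of the surviving
#'   encounters) and `report` (an `exclusion_report`: initial and retained
#'   counts plus per-criterion exclusion counts, conserving the total).
#' @export
apply_exclusions <- function(cohort, config = exclusion_config()) {
  stopifnot(inherits(cohort, "aki_cohort"))
  encs <- as_encounters(cohort)
  reason <- vapply(encs, exclusion_reason, character(1), config = config)
  counts <- vapply(exclusion_criteria,
                   function(cr) sum(reason == cr, na.rm = TRUE), integer(1))
  keep <- reason == ""
  retained <- new_cohort(
    cohort$encounters[cohort$encounters$encounter_id %in% names(encs)[keep], ],
    cohort$events[cohort$events$encounter_id %in% names(encs)[keep], ]
  )
  report <- structure(list(initial = length(encs), retained = sum(keep),
                           excluded = counts, criteria = exclusion_criteria),
                      class = "exclusion_report")
  list(retained = retained, report = report)
}

exclusion_reason <- function(enc, config) {
  los_h <- hours_between(enc$discharge_time, enc$admission_time)
  if (!(los_h > config$min_los_hours)) return("short_stay")
  if (is.na(enc$age) || is.na(enc$sex) || is.na(enc$race_black)) {
    return("missing_demographics")
  }
  if (enc$age > config$max_age) return("age_over_90")
  if (admission_oligoanuria(enc, config)) return("admission_oligoanuria")
  if (nrow(enc$rrt_intervals) > 0) return("rrt")
  has_scr <- any(enc$events$kind == "creatinine")
  has_uo <- any(enc$events$kind == "urine_output")
  has_wt <- any(enc$events$kind == "weight")
  if (!has_scr && !(has_uo && has_wt)) return("insufficient_data")
  ""
}

# AKI on admission: mean weight-normalised urine output below threshold over
# the first hours of the stay. Encounters without full urine charting coverage
# of the window (or without any weight) are not excluded here.
admission_oligoanuria <- function(enc, config) {
  w <- config$oligoanuria_window_h
  rates <- hourly_uo_rate(enc)
  if (is.null(rates) || nrow(rates) < w) return(FALSE)
  first <- rates$rate_ml_kg_h[seq_len(w)]
  if (anyNA(first)) return(FALSE)
  mean(first) < config$oligoanuria_threshold
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat(sprintf("<exclusion_report> %d -> %d retained\n", x$initial, x$retained))
  for (cr in x$criteria) cat(sprintf("  %-22s %d\n", cr, x$excluded[[cr]]))
  invisible(x)
}

#' Write an exclusion report as JSON
#' @param report an `exclusion_report`.
#' @param path output path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(
    list(initial = report$initial, retained = report$retained,
         excluded = as.list(report$excluded)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write a cohort back to the two study CSVs
#'
#' Inverse of [read_chart_events()] (values written in mg/dL): emits
#' `encounters.csv` and `events.csv` under `dir`.
#'
#' @param cohort an `aki_cohort`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "aki_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  enc <- cohort$encounters
  enc$admission_time <- format(enc$admission_time, "%Y-%m-%dT%H:%M:%S")
  enc$discharge_time <- format(enc$discharge_time, "%Y-%m-%dT%H:%M:%S")
  ev <- cohort$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%S")
  readr::write_csv(enc, file.path(dir, "encounters.csv"))
  readr::write_csv(ev, file.path(dir, "events.csv"))
  invisible(dir)
}

#' Write the per-encounter outcomes table
#'
#' One row per encounter, deterministic column order; a header-only CSV for an
#' empty cohort.
#'
#' @param outcomes tibble from [cohort_outcomes()].
#' @param path output CSV path.
#' @export
write_outcomes_table <- function(outcomes, path) {
  cols <- c("encounter_id", "unit", "admission_stage", "discharge_stage",
            "max_stage", paste0("day", 1:5, "_max_stage"),
            "aki_at_admission", "progressed_from_1", "progressed_2_to_3",
            "first_aki_day", "los_days")
  cols <- c(intersect(cols, names(outcomes)), setdiff(names(outcomes), cols))
  readr::write_csv(outcomes[, cols], path)
  invisible(path)
}

#' Cohort-level demographic and data-availability summary
#'
#' Counts and proportions of the kind reported in cohort-overview tables:
#' encounters, sex, unit mix, age, charted baseline creatinine, RRT use, and
#' availability of creatinine/urine-output/weight charting.
#'
#' @param cohort an `aki_cohort`.
#' @return a one-row tibble of counts and percentages.
#' @export
cohort_summary <- function(cohort) {
  stopifnot(inherits(cohort, "aki_cohort"))
  enc <- cohort$encounters
  n <- nrow(enc)
  has_kind <- function(kind) {
    ids <- unique(cohort$events$encounter_id[cohort$events$kind == kind])
    sum(enc$encounter_id %in% ids)
  }
  n_rrt <- has_kind("rrt_start")
  n_baseline <- sum(!is.na(enc$baseline_creatinine)) +
    sum(is.na(enc$baseline_creatinine) &
          enc$encounter_id %in%
            unique(cohort$events$encounter_id[
              cohort$events$kind == "baseline_creatinine"]))
  pct <- function(x) if (n > 0) 100 * x / n else NA_real_
  tibble(
    n_encounters = n,
    n_female = sum(enc$sex == "female", na.rm = TRUE),
    pct_female = pct(sum(enc$sex == "female", na.rm = TRUE)),
    n_gicu = sum(enc$unit == "GICU", na.rm = TRUE),
    pct_gicu = pct(sum(enc$unit == "GICU", na.rm = TRUE)),
    mean_age = mean(enc$age, na.rm = TRUE),
    sd_age = stats::sd(enc$age, na.rm = TRUE),
    n_baseline_charted = n_baseline,
    pct_baseline_charted = pct(n_baseline),
    n_rrt = n_rrt,
    pct_rrt = pct(n_rrt),
    pct_with_scr = pct(has_kind("creatinine")),
    pct_with_uo = pct(has_kind("urine_output")),
    pct_with_weight = pct(has_kind("weight"))
  )
}
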