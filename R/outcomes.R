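#' AKI stage at admission
#'
#' The first combined stage evaluated within the admission window (default
#' 6 h). Encounters whose first evaluation comes later have an unknown
#' admission stage; they are counted as not admitted with AKI in cohort
#' tallies and flagged in the per-encounter output.
#'
#' @param combined combined stage series tibble.
#' @param admission_time admission timestamp.
#' @param window_h admission window, h.
#' @return integer stage 0-3, or `NA` when no evaluation falls in the window.
#' @export
admission_stage <- function(combined, admission_time, window_h = 6) {
  if (nrow(combined) == 0) return(NA_integer_)
  inwin <- combined$timestamp <= admission_time + window_h * 3600
  if (!any(inwin)) return(NA_integer_)
  as.integer(combined$stage[which(inwin)[1]])
}

#' AKI stage at discharge
#'
#' The combined stage as of the last measured urine output or serum
#' creatinine event.
#'
#' @param combined combined stage series tibble.
#' @param events the encounter's event tibble.
#' @return integer stage, or `NA` when the series is empty.
#' @export
discharge_stage <- function(combined, events) {
  if (nrow(combined) == 0) return(NA_integer_)
  obs <- events$timestamp[events$kind %in% c("urine_output", "creatinine")]
  t_last <- if (length(obs)) max(obs) else max(combined$timestamp)
  as.integer(locf_at(combined$timestamp, combined$stage, t_last,
                     default = NA_integer_))
}

#' Maximum combined stage per ICU day
#'
#' Day `k` covers hours `[24(k-1), 24k)` after admission. The combined stage
#' is a state, so the last value is carried forward into windows with no
#' updates (configurable off). Days starting at or after discharge are absent
#' (`NA`).
#'
#' @param combined combined stage series tibble.
#' @param admission_time,discharge_time encounter timestamps.
#' @param n_days number of days reported (default 5).
#' @param carry_forward carry the last stage into update-free windows.
#' @return integer vector of length `n_days`.
#' @export
max_stage_per_day <- function(combined, admission_time, discharge_time,
                              n_days = 5, carry_forward = TRUE) {
  out <- rep(NA_integer_, n_days)
  los_h <- hours_between(discharge_time, admission_time)
  for (k in seq_len(n_days)) {
    w0 <- admission_time + (k - 1) * 86400
    if ((k - 1) * 24 >= los_h) break
    w1 <- admission_time + k * 86400
    inwin <- combined$timestamp >= w0 & combined$timestamp < w1
    vals <- combined$stage[inwin]
    if (carry_forward) {
      entering <- locf_at(combined$timestamp, combined$stage, w0,
                          default = NA_integer_)
      if (!is.na(entering)) vals <- c(vals, entering)
    }
    out[k] <- if (length(vals)) as.integer(max(vals)) else NA_integer_
  }
  out
}

#' Stage-progression flags
#'
#' Scans consecutive evaluations of the combined series: `progressed_from_1`
#' is true when any evaluation moves from stage 1 to a higher stage (1 to 3
#' counts); `progressed_2_to_3` when any moves from 2 to 3. Per-encounter
#' flags — repeated episodes count once.
#'
#' @param combined combined stage series tibble.
#' @return a list with logicals `progressed_from_1` and `progressed_2_to_3`.
#' @export
progression_flags <- function(combined) {
  v <- combined$stage
  if (length(v) < 2) {
    return(list(progressed_from_1 = FALSE, progressed_2_to_3 = FALSE))
  }
  a <- v[-length(v)]
  b <- v[-1]
  list(progressed_from_1 = any(a == 1 & b > 1),
       progressed_2_to_3 = any(a == 2 & b == 3))
}

#' ICU day of first AKI
#'
#' Ceiling of the time from admission to the first nonzero combined stage, in
#' days (an event in the first 24 h is day 1).
#'
#' @param combined combined stage series tibble.
#' @param admission_time admission timestamp.
#' @return integer day, or `NA` when no AKI is observed (censored).
#' @export
first_aki_day <- function(combined, admission_time) {
  hit <- combined$timestamp[combined$stage > 0]
  if (length(hit) == 0) return(NA_integer_)
  max(1L, as.integer(ceiling(hours_between(hit[1], admission_time) / 24)))
}

#' Per-encounter outcome row
#'
#' @param encounter an `aki_encounter`.
#' @param series its `stage_series` from [stage_encounter()].
#' @param n_days days reported in the per-day maxima.
#' @return a one-row tibble of the encounter's outcomes.
#' @export
encounter_outcomes <- function(encounter, series, n_days = 5) {
  comb <- series$combined
  adm <- admission_stage(comb, encounter$admission_time)
  daily <- max_stage_per_day(comb, encounter$admission_time,
                             encounter$discharge_time, n_days = n_days)
  prog <- progression_flags(comb)
  mx <- if (nrow(comb)) as.integer(max(comb$stage)) else NA_integer_
  out <- tibble(
    encounter_id = encounter$encounter_id,
    unit = encounter$unit,
    admission_stage = adm,
    discharge_stage = discharge_stage(comb, encounter$events),
    max_stage = mx,
    aki_at_admission = !is.na(adm) & adm >= 1,
    progressed_from_1 = prog$progressed_from_1,
    progressed_2_to_3 = prog$progressed_2_to_3,
    ever_stage_1 = any(comb$stage == 1),
    ever_stage_2 = any(comb$stage == 2),
    first_aki_day = first_aki_day(comb, encounter$admission_time),
    los_days = hours_between(encounter$discharge_time,
                             encounter$admission_time) / 24
  )
  for (k in seq_len(n_days)) out[[paste0("day", k, "_max_stage")]] <- daily[k]
  out
}

#' Outcomes for every encounter of a staged cohort
#'
#' @param cohort an `aki_cohort` (exclusions applied).
#' @param series_list staged series from [stage_cohort()]; computed when
#'   omitted.
#' @param rules staging rules used when staging is needed.
#' @return a tibble with one row per encounter (see [encounter_outcomes()]).
#' @export
cohort_outcomes <- function(cohort, series_list = NULL,
                            rules = staging_rules()) {
  if (is.null(series_list)) series_list <- stage_cohort(cohort, rules)
  encs <- as_encounters(cohort)
  purrr::map_dfr(names(encs), function(id) {
    encounter_outcomes(encs[[id]], series_list[[id]])
  })
}

#' Discrete-time Kaplan-Meier curve of remaining AKI-free
#'
#' Daily product-limit estimate of the proportion of encounters still free of
#' AKI: encounters leave the at-risk set on the day they first develop AKI
#' (event) or are discharged without AKI (censored). Computed with
#' [survival::survfit()] on (day, event) pairs.
#'
#' @param outcomes per-encounter outcome tibble from [cohort_outcomes()].
#' @param max_day last ICU day reported (default 10).
#' @param include_admission_aki count encounters with AKI at admission as
#'   day-1 events instead of excluding them.
#' @return a tibble `day`, `n_at_risk`, `n_events`, `survival`.
#' @export
km_no_aki <- function(outcomes, max_day = 10,
                      include_admission_aki = FALSE) {
  df <- outcomes
  if (!include_admission_aki) df <- df[!df$aki_at_admission, ]
  if (nrow(df) == 0) {
    return(tibble(day = integer(), n_at_risk = integer(),
                  n_events = integer(), survival = numeric()))
  }
  event <- !is.na(df$first_aki_day)
  disc_day <- pmax(1, ceiling(df$los_days))
  time <- ifelse(event, df$first_aki_day, disc_day)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  sm <- summary(fit, times = seq_len(max_day), extend = TRUE)
  tibble(day = as.integer(sm$time),
         n_at_risk = as.integer(sm$n.risk),
         n_events = as.integer(sm$n.event),
         survival = sm$surv)
}

#' Cohort-level AKI outcome table
#'
#' Counts and proportions of the standard cohort metrics: admitted with AKI,
#' developed AKI in ICU (not admitted with AKI and maximum stage at least 1),
#' discharged with AKI, maximum stage 1/2/3, no AKI, any AKI, and the two
#' progression rates. Every proportion is reported with its denominator:
#' admission/development/discharge metrics over all encounters; maximum-stage,
#' no-AKI and any-AKI prevalence over encounters not admitted with AKI;
#' progression rates over encounters that reached the originating stage.
#'
#' @param outcomes per-encounter outcome tibble from [cohort_outcomes()].
#' @return a tibble `metric`, `n`, `denominator`, `proportion`, `pct`.
#' @export
cohort_outcome_table <- function(outcomes) {
  n <- nrow(outcomes)
  admitted <- sum(outcomes$aki_at_admission, na.rm = TRUE)
  not_admitted <- n - admitted
  mx <- outcomes$max_stage
  developed <- sum(!outcomes$aki_at_admission & !is.na(mx) & mx >= 1,
                   na.rm = TRUE)
  discharged <- sum(!is.na(outcomes$discharge_stage) &
                      outcomes$discharge_stage >= 1)
  n_stage <- function(k) sum(!is.na(mx) & mx == k)
  # progression denominators: encounters whose combined series ever showed
  # stage 1 / stage 2
  reached1 <- if ("ever_stage_1" %in% names(outcomes)) {
    sum(outcomes$ever_stage_1, na.rm = TRUE)
  } else {
    sum(!is.na(mx) & mx >= 1)
  }
  reached2 <- if ("ever_stage_2" %in% names(outcomes)) {
    sum(outcomes$ever_stage_2, na.rm = TRUE)
  } else {
    sum(!is.na(mx) & mx >= 2)
  }
  prog1 <- sum(outcomes$progressed_from_1, na.rm = TRUE)
  prog23 <- sum(outcomes$progressed_2_to_3, na.rm = TRUE)
  rows <- tibble(
    metric = c("admitted_with_aki", "developed_aki_in_icu",
               "discharged_with_aki", "max_stage_1", "max_stage_2",
               "max_stage_3", "no_aki", "any_aki",
               "progressed_from_stage_1", "progressed_stage_2_to_3"),
    count = c(admitted, developed, discharged, n_stage(1), n_stage(2),
              n_stage(3),
              not_admitted - (n_stage(1) + n_stage(2) + n_stage(3)),
              n_stage(1) + n_stage(2) + n_stage(3),
              prog1, prog23),
    denominator = c(n, n, n, not_admitted, not_admitted, not_admitted,
                    not_admitted, not_admitted, reached1, reached2)
  )
  names(rows)[names(rows) == "count"] <- "n"
  rows$proportion <- ifelse(rows$denominator > 0,
                            rows$n / rows$denominator, NA_real_)
  rows$pct <- 100 * rows$proportion
  rows
}
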