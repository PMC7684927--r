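# builders for small hand-made encounters and cohorts

T0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

ev <- function(h, kind, value) {
  data.frame(h = h, kind = kind, value = value)
}

make_cohort <- function(encounters, events) {
  akiflow:::new_cohort(tibble::as_tibble(encounters),
                       tibble::as_tibble(events))
}

# one encounter from event rows given as hours since admission
make_encounter <- function(events = NULL, age = 60, sex = "male",
                           race_black = FALSE, unit = "GICU", los_h = 72,
                           baseline = NA_real_, id = "e1", t0 = T0) {
  enc <- tibble::tibble(
    encounter_id = id, admission_time = t0,
    discharge_time = t0 + los_h * 3600,
    age = age, sex = sex, race_black = race_black, unit = unit,
    admission_type = NA_character_, baseline_creatinine = baseline)
  evs <- if (is.null(events) || nrow(events) == 0) {
    tibble::tibble(encounter_id = character(),
                   timestamp = as.POSIXct(character(), tz = "UTC"),
                   kind = character(), value = numeric())
  } else {
    dplyr::arrange(
      tibble::tibble(encounter_id = id, timestamp = t0 + events$h * 3600,
                     kind = events$kind, value = events$value),
      timestamp)
  }
  as_encounters(make_cohort(enc, evs))[[1]]
}

# hourly urine charting at a given mL/kg/h rate profile
uo_events <- function(rates, weight = 80) {
  ev(seq_along(rates), "urine_output", rates * weight)
}

# an hourly rate grid in the shape hourly_uo_rate() returns
rate_grid <- function(rate_ml_kg_h, weight = 80, t0 = T0) {
  n <- length(rate_ml_kg_h)
  tibble::tibble(
    hour = seq_len(n), time_end = t0 + seq_len(n) * 3600,
    ml_per_h = rate_ml_kg_h * weight, weight_kg = weight,
    rate_ml_kg_h = rate_ml_kg_h,
    missing = is.na(rate_ml_kg_h))
}

# random 72-h rate grid with low/anuric episodes and missing hours
random_rate_grid <- function(n_hours = 72, weight = 80) {
  rate <- round(stats::runif(n_hours, 0, 1.2), 2)
  if (stats::runif(1) < 0.6) {
    s <- sample(n_hours - 14, 1)
    len <- sample(6:14, 1)
    rate[s:(s + len)] <- round(stats::runif(1, 0, 0.45), 2)
  }
  if (stats::runif(1) < 0.25) {
    s <- sample(n_hours - 13, 1)
    rate[s:(s + 12)] <- 0
  }
  rate[stats::runif(n_hours) < 0.12] <- NA
  rate_grid(rate, weight)
}

# stage of a series at given times, last observation carried forward
stage_at <- function(series, at, default = NA_integer_) {
  vapply(at, function(t) {
    idx <- which(series$timestamp <= t)
    if (length(idx) == 0) default else series$stage[max(idx)]
  }, integer(1))
}
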