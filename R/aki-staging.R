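#' AKIN staging rules
#'
#' Thresholds and window lengths for urine-output (UO) and creatinine (Cr)
#' staging, following the AKIN criteria.
#'
#' UO staging evaluates trailing windows of weight-normalised hourly output:
#' stage 1 when the trailing 6-h mean falls below 0.5 mL/kg/h, stage 2 when
#' the trailing 12-h mean falls below 0.5, stage 3 when the trailing 24-h mean
#' falls below 0.3 or every hour of the trailing 12 h is anuric. Cr staging
#' compares each measurement with the baseline: stage 1 at an absolute rise of
#' at least 0.3 mg/dL or a ratio of at least 1.5x; stage 2 above 2x; stage 3
#' above 3x, or creatinine at or above 4.0 mg/dL with an acute rise of at
#' least 0.5 mg/dL.
#'
#' @param uo_stage1_rate,uo_stage2_rate,uo_stage3_rate rate thresholds,
#'   mL/kg/h.
#' @param uo_stage1_window,uo_stage2_window,uo_stage3_window trailing window
#'   lengths, h (strictly increasing across stages).
#' @param anuria_window anuria window length, h.
#' @param anuria_ml_per_h an hour with less than this absolute output (mL/h)
#'   counts as anuric; slightly above zero to tolerate charting noise.
#' @param uo_window_mode `"mean"` (trailing-window mean below threshold,
#'   default) or `"all_hours"` (every hour in the window below threshold).
#' @param uo_max_pool_h maximum accumulation period assumed for one charted
#'   urine volume, h; hours of a longer charting gap beyond this cap have no
#'   coverage and are missing.
#' @param cr_stage1_rise,cr_stage1_ratio,cr_stage2_ratio,cr_stage3_ratio,cr_stage3_abs,cr_stage3_acute_rise
#'   creatinine thresholds, mg/dL or ratios to baseline.
#' @return a list of class `staging_rules`.
#' @export
staging_rules <- function(uo_stage1_rate = 0.5, uo_stage1_window = 6,
                          uo_stage2_rate = 0.5, uo_stage2_window = 12,
                          uo_stage3_rate = 0.3, uo_stage3_window = 24,
                          anuria_window = 12, anuria_ml_per_h = 1,
                          uo_window_mode = c("mean", "all_hours"),
                          uo_max_pool_h = 6,
                          cr_stage1_rise = 0.3, cr_stage1_ratio = 1.5,
                          cr_stage2_ratio = 2, cr_stage3_ratio = 3,
                          cr_stage3_abs = 4.0, cr_stage3_acute_rise = 0.5) {
  uo_window_mode <- match.arg(uo_window_mode)
  stopifnot(uo_stage1_window < uo_stage2_window,
            uo_stage2_window < uo_stage3_window,
            uo_stage1_rate > 0, uo_stage3_rate > 0)
  structure(as.list(environment()), class = "staging_rules")
}

#' Hourly weight-normalised urine-output rate grid
#'
#' Builds an hourly grid from admission to the last urine event. Each charted
#' urine volume is spread uniformly over the interval since the previous
#' urine charting (or admission, for the first), up to the pooling cap
#' `uo_max_pool_h`; hours of a longer gap beyond the cap have no charting
#' coverage and are marked missing, never zero. Each hour's rate is divided by
#' the most recent weight as of the end of that hour.
#'
#' @param encounter an `aki_encounter`.
#' @param rules a [staging_rules()].
#' @return a tibble with one row per hour since admission: `hour` (1-based,
#'   hour `h` covers `[admission + h - 1, admission + h)` hours), `time_end`,
#'   `ml_per_h`, `weight_kg`, `rate_ml_kg_h` (NA when missing), `missing`; or
#'   `NULL` when no weight is available (UO staging uncomputable).
#' @export
hourly_uo_rate <- function(encounter, rules = staging_rules()) {
  stopifnot(inherits(encounter, "aki_encounter"))
  ev <- encounter$events
  uo <- ev[ev$kind == "urine_output", ]
  wt <- ev[ev$kind == "weight", ]
  if (nrow(wt) == 0) return(NULL)
  if (nrow(uo) == 0) {
    return(tibble(hour = integer(), time_end = as.POSIXct(character(),
                                                          tz = "UTC"),
                  ml_per_h = numeric(), weight_kg = numeric(),
                  rate_ml_kg_h = numeric(), missing = logical()))
  }
  t0 <- encounter$admission_time
  uo_h <- hours_between(uo$timestamp, t0)
  wt_h <- hours_between(wt$timestamp, t0)
  n_hours <- floor(max(uo_h) + 1e-9)
  vol <- numeric(n_hours)
  covered <- numeric(n_hours)
  prev <- 0
  for (j in seq_len(nrow(uo))) {
    end <- uo_h[j]
    start <- max(prev, end - rules$uo_max_pool_h, 0)
    len <- end - start
    prev <- end
    if (len <= 1e-9 || n_hours == 0) next
    r <- uo$value[j] / len
    h1 <- max(1L, floor(start + 1e-9) + 1L)
    h2 <- min(n_hours, ceiling(end - 1e-9))
    if (h1 > h2) next
    hs <- h1:h2
    ov <- pmin(hs, end) - pmax(hs - 1, start)
    ov[ov < 0] <- 0
    vol[hs] <- vol[hs] + r * ov
    covered[hs] <- covered[hs] + ov
  }
  hour_end <- seq_len(n_hours)
  widx <- findInterval(hour_end + 1e-9, wt_h)
  weight <- ifelse(widx > 0, wt$value[pmax(widx, 1)], NA_real_)
  missing <- covered < 1 - 1e-6 | is.na(weight)
  rate <- ifelse(missing, NA_real_, vol / weight)
  tibble(hour = hour_end,
         time_end = t0 + hour_end * 3600,
         ml_per_h = ifelse(covered < 1 - 1e-6, NA_real_, vol),
         weight_kg = weight,
         rate_ml_kg_h = rate,
         missing = missing)
}

#' Urine-output AKI stage series
#'
#' Evaluates the AKIN urine-output criteria on an hourly rate grid. At each
#' hour the trailing 6/12/24-h windows ending there are examined; a window is
#' eligible only if every hour in it is non-missing, and the emitted stage is
#' the maximum satisfied stage. A stage point is emitted at the first eligible
#' hour and whenever the value changes.
#'
#' @param rates hourly grid from [hourly_uo_rate()] (or `NULL`).
#' @param rules a [staging_rules()].
#' @return a tibble `timestamp`, `stage` (source `uo`); empty when the grid is
#'   `NULL`, empty, or never has an eligible window.
#' @export
stage_uo <- function(rates, rules = staging_rules()) {
  empty <- tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                  stage = integer())
  if (is.null(rates) || nrow(rates) == 0) return(empty)
  x <- rates$rate_ml_kg_h
  anuric <- ifelse(rates$missing, NA, rates$ml_per_h < rules$anuria_ml_per_h)
  # threshold comparisons carry a 1e-9 guard: a window mean exactly at the
  # threshold is not below it, regardless of accumulation order
  if (rules$uo_window_mode == "mean") {
    m1 <- roll_mean_strict(x, rules$uo_stage1_window)
    m2 <- roll_mean_strict(x, rules$uo_stage2_window)
    m3 <- roll_mean_strict(x, rules$uo_stage3_window)
    s1 <- !is.na(m1) & m1 < rules$uo_stage1_rate - 1e-9
    s2 <- !is.na(m2) & m2 < rules$uo_stage2_rate - 1e-9
    s3m <- !is.na(m3) & m3 < rules$uo_stage3_rate - 1e-9
  } else {
    below <- function(thr) ifelse(rates$missing, NA, x < thr)
    a1 <- roll_mean_strict(below(rules$uo_stage1_rate), rules$uo_stage1_window)
    a2 <- roll_mean_strict(below(rules$uo_stage2_rate), rules$uo_stage2_window)
    a3 <- roll_mean_strict(below(rules$uo_stage3_rate), rules$uo_stage3_window)
    s1 <- !is.na(a1) & a1 == 1
    s2 <- !is.na(a2) & a2 == 1
    s3m <- !is.na(a3) & a3 == 1
    m1 <- a1
  }
  an <- roll_mean_strict(anuric, rules$anuria_window)
  s3 <- s3m | (!is.na(an) & an == 1)
  known <- !is.na(roll_mean_strict(x, rules$uo_stage1_window)) | s3
  stage <- ifelse(s3, 3L, ifelse(s2, 2L, ifelse(s1, 1L, 0L)))
  keep <- which(known)
  if (length(keep) == 0) return(empty)
  st <- stage[keep]
  emit <- c(TRUE, st[-1] != st[-length(st)])
  tibble(timestamp = rates$time_end[keep[emit]], stage = as.integer(st[emit]))
}

#' Creatinine AKI stage series
#'
#' One stage point per creatinine measurement, from the ratio to and rise
#' above baseline. Stages are not ratcheted: the stage falls when creatinine
#' falls.
#'
#' @param cr_events tibble of creatinine events (`timestamp`, `value` in
#'   mg/dL), time-ordered.
#' @param baseline baseline resolution from [resolve_baseline()], or a single
#'   positive number (mg/dL).
#' @param rules a [staging_rules()].
#' @return a tibble `timestamp`, `stage` (source `cr`).
#' @export
stage_cr <- function(cr_events, baseline, rules = staging_rules()) {
  b <- if (is.list(baseline)) baseline$value else baseline
  if (is.na(b) || b <= 0) stopf("baseline creatinine must be positive")
  if (is.null(cr_events) || nrow(cr_events) == 0) {
    return(tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                  stage = integer()))
  }
  scr <- cr_events$value
  r <- scr / b
  d <- scr - b
  stage <- ifelse(
    r > rules$cr_stage3_ratio |
      (scr >= rules$cr_stage3_abs & d >= rules$cr_stage3_acute_rise), 3L,
    ifelse(r > rules$cr_stage2_ratio, 2L,
           ifelse(r >= rules$cr_stage1_ratio | d >= rules$cr_stage1_rise,
                  1L, 0L)))
  tibble(timestamp = cr_events$timestamp, stage = as.integer(stage))
}

#' Combined AKI stage series
#'
#' The combined stage is the maximum of the most recent values of the UO and
#' Cr streams, evaluated at every timestamp where either component updates; a
#' component with no value yet contributes 0.
#'
#' @param uo,cr stage series tibbles (`timestamp`, `stage`).
#' @return a tibble `timestamp`, `stage` with one evaluation per update time.
#' @export
combined_stage <- function(uo, cr) {
  ts <- sort(unique(c(uo$timestamp, cr$timestamp)))
  if (length(ts) == 0) {
    return(tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                  stage = integer()))
  }
  u <- locf_at(uo$timestamp, uo$stage, ts, default = 0L)
  c_ <- locf_at(cr$timestamp, cr$stage, ts, default = 0L)
  tibble(timestamp = ts, stage = as.integer(pmax(u, c_)))
}

#' Stage one encounter
#'
#' Runs the full event-driven staging engine for an encounter: hourly UO rate
#' grid, UO stage series, Cr stage series against the resolved baseline, and
#' the combined series.
#'
#' @param encounter an `aki_encounter`.
#' @param rules a [staging_rules()].
#' @param baseline optional baseline resolution; resolved with
#'   [resolve_baseline()] when omitted.
#' @return a list of class `stage_series` with elements `encounter_id`, `uo`,
#'   `cr`, `combined` (stage tibbles), `rates` (hourly grid or `NULL`) and
#'   `baseline`.
#' @export
stage_encounter <- function(encounter, rules = staging_rules(),
                            baseline = NULL) {
  stopifnot(inherits(encounter, "aki_encounter"))
  baseline <- baseline %||% resolve_baseline(encounter)
  rates <- hourly_uo_rate(encounter, rules)
  uo <- stage_uo(rates, rules)
  cr_events <- encounter$events[encounter$events$kind == "creatinine", ]
  cr <- if (nrow(cr_events) > 0) {
    stage_cr(cr_events, baseline, rules)
  } else {
    tibble(timestamp = as.POSIXct(character(), tz = "UTC"), stage = integer())
  }
  structure(list(encounter_id = encounter$encounter_id, uo = uo, cr = cr,
                 combined = combined_stage(uo, cr), rates = rates,
                 baseline = baseline),
            class = "stage_series")
}

#' @export
print.stage_series <- function(x, ...) {
  cat(sprintf("<stage_series %s> uo: %d pts, cr: %d pts, combined: %d pts\n",
              x$encounter_id, nrow(x$uo), nrow(x$cr), nrow(x$combined)))
  invisible(x)
}

#' Stage every encounter of a cohort
#'
#' @param cohort an `aki_cohort` (exclusions already applied).
#' @param rules a [staging_rules()].
#' @param ... passed to [resolve_baseline()].
#' @return a named list of `stage_series`, one per encounter.
#' @export
stage_cohort <- function(cohort, rules = staging_rules(), ...) {
  encs <- as_encounters(cohort)
  lapply(encs, function(e) {
    stage_encounter(e, rules, baseline = resolve_baseline(e, ...))
  })
}

#' Flatten staged series to a long table
#'
#' @param series_list list of `stage_series` from [stage_cohort()].
#' @return a tibble `encounter_id`, `timestamp`, `source`, `stage`.
#' @export
stages_table <- function(series_list) {
  purrr::map_dfr(series_list, function(s) {
    dplyr::bind_rows(
      dplyr::mutate(s$uo, source = "uo"),
      dplyr::mutate(s$cr, source = "cr"),
      dplyr::mutate(s$combined, source = "combined")
    ) |>
      dplyr::mutate(encounter_id = s$encounter_id) |>
      dplyr::select("encounter_id", "timestamp", "source", "stage")
  })
}
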