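#' Synthetic ICU cohort configuration
#'
#' Parameters of the synthetic cohort generator. The defaults emulate the
#' control-phase study conditions: unit mix ~42% general ICU, ICU length of
#' stay log-normal targeting mean 5.8 and SD 6.7 days (rounded up to whole
#' days so every latent stage day is fully charted), age 63.6 (14.5) years
#' clamped to 18-90, 32% female, 1.3% Black, admission weight log-normal with
#' mean 81 and SD 20 kg, 1.6% charted baseline creatinine, 6.5% RRT, stage-1
#' progression probability 0.42 and stage-2-to-3 probability 0.213, and a
#' 1.72% per-dose enoxaparin error rate.
#'
#' AKI onset follows a per-day hazard with a unit-specific shape: front-loaded
#' in the cardiac ICU (postoperative insult in the first day or two) and
#' spread across the stay in the general ICU. Latent stages evolve on a daily
#' clock and are non-decreasing within the stay; emissions are hourly and, in
#' noise-free mode, satisfy exactly the AKIN criterion of the latent stage.
#'
#' @param n_encounters cohort size.
#' @param seed RNG seed (mandatory; generation is deterministic given the
#'   config).
#' @param unit_gicu_fraction fraction of encounters in the general ICU.
#' @param los_mean_days,los_sd_days target mean/SD of the log-normal length
#'   of stay before day-rounding.
#' @param los_min_days minimum stay, days.
#' @param age_mean,age_sd,age_min,age_max age distribution (normal, clamped).
#' @param female_fraction,black_fraction demographic mix.
#' @param weight_mean,weight_sd admission weight distribution (log-normal by
#'   moments), kg.
#' @param baseline_scr_meanlog,baseline_scr_sdlog true baseline creatinine
#'   distribution (log-normal), mg/dL.
#' @param fraction_charted_baseline fraction of encounters with a charted
#'   baseline creatinine.
#' @param onset_mode `"hazard"` (default), `"all_day1"` (every encounter
#'   starts a stage-1 episode on day 1; used for parameter-recovery designs)
#'   or `"none"`.
#' @param onset_hazard named list of per-day hazard vectors by unit (last
#'   element recycled for later days).
#' @param p_progress_1 probability that a stage-1 episode progresses to a
#'   higher stage.
#' @param p_2_to_3 probability that a progressed (stage-2) episode progresses
#'   on to stage 3.
#' @param stage1_duration_days,stage2_duration_days days spent in stage 1/2
#'   before a drawn progression occurs.
#' @param cr_channel_fraction fraction of AKI episodes expressed through
#'   creatinine (the rest through urine output).
#' @param uo_rates named list of emission rates, mL/kg/h: `healthy`,
#'   `stage1_high`/`stage1_low` (alternating 6-h blocks on stage-1 days),
#'   `stage2`, `stage3`.
#' @param cr_ratios creatinine-to-baseline ratios emitted for stages 0-3.
#' @param uo_noise_sd,scr_noise_sd truncated-normal jitter SDs (0 = noise-free
#'   mode, the default).
#' @param scr_hour,egfr_hour,dose_hour daily charting hours for creatinine,
#'   eGFR and enoxaparin.
#' @param dose_error_rate per-dose probability of an injected dosing error
#'   (a dose exceeding the recommendation for the preceding eGFR).
#' @param rrt_probability fraction of encounters receiving RRT.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_encounters = 100, seed,
                          unit_gicu_fraction = 0.42,
                          los_mean_days = 5.8, los_sd_days = 6.7,
                          los_min_days = 2,
                          age_mean = 63.6, age_sd = 14.5,
                          age_min = 18, age_max = 90,
                          female_fraction = 0.32, black_fraction = 0.013,
                          weight_mean = 81, weight_sd = 20,
                          baseline_scr_meanlog = log(0.85),
                          baseline_scr_sdlog = 0.18,
                          fraction_charted_baseline = 0.016,
                          onset_mode = c("hazard", "all_day1", "none"),
                          onset_hazard = list(GICU = 0.09,
                                              CICU = c(0.25, 0.20, 0.01)),
                          p_progress_1 = 0.42, p_2_to_3 = 0.213,
                          stage1_duration_days = 1, stage2_duration_days = 1,
                          cr_channel_fraction = 0.3,
                          uo_rates = list(healthy = 1.0, stage1_high = 0.7,
                                          stage1_low = 0.4, stage2 = 0.4,
                                          stage3 = 0.25),
                          cr_ratios = c(1.0, 1.6, 2.5, 3.5),
                          uo_noise_sd = 0, scr_noise_sd = 0,
                          scr_hour = 6, egfr_hour = 6.5, dose_hour = 8,
                          dose_error_rate = 0.0172,
                          rrt_probability = 0.065) {
  onset_mode <- match.arg(onset_mode)
  if (missing(seed)) stopf("a seed is mandatory")
  probs <- c(unit_gicu_fraction, female_fraction, black_fraction,
             fraction_charted_baseline, p_progress_1, p_2_to_3,
             cr_channel_fraction, dose_error_rate, rrt_probability,
             unlist(onset_hazard))
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  stopifnot(n_encounters >= 0, los_mean_days > 0, los_sd_days > 0,
            length(cr_ratios) == 4, stage1_duration_days >= 1,
            stage2_duration_days >= 1)
  cfg <- as.list(environment())
  cfg$probs <- NULL
  structure(cfg, class = "cohort_config")
}

# log-normal parameters from target mean/sd
lnorm_params <- function(mean, sd) {
  sdlog <- sqrt(log(1 + (sd / mean)^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

# daily hazard for a unit, recycling the last element
hazard_for <- function(config, unit, day) {
  h <- config$onset_hazard[[unit]]
  h[pmin(day, length(h))]
}

# latent daily stage path: 0 until onset, then 1, progressing to 2 (and 3)
# after the configured dwell times when the progression flags are drawn;
# non-decreasing within the stay
latent_path <- function(n_days, onset_day, progress1, progress23, config) {
  path <- rep(0L, n_days)
  if (is.na(onset_day) || onset_day > n_days) return(path)
  path[onset_day:n_days] <- 1L
  if (progress1) {
    d2 <- onset_day + config$stage1_duration_days
    if (d2 <= n_days) {
      path[d2:n_days] <- 2L
      if (progress23) {
        d3 <- d2 + config$stage2_duration_days
        if (d3 <= n_days) path[d3:n_days] <- 3L
      }
    }
  }
  path
}

# hourly urine rates (mL/kg/h) for one latent day
uo_day_rates <- function(stage, r) {
  switch(stage + 1L,
         rep(r$healthy, 24),
         rep(c(r$stage1_high, r$stage1_low), each = 6, times = 2),
         rep(r$stage2, 24),
         rep(r$stage3, 24))
}

#' Generate a synthetic ICU cohort with known latent truth
#'
#' Draws demographics, latent daily AKI stage paths and charting streams per
#' [cohort_config()], and emits an `aki_cohort` in the long chart-event
#' format together with the latent truth. In noise-free mode the emissions
#' satisfy exactly the AKIN criterion of each latent stage day, so the
#' staging engine recovers the latent trajectories.
#'
#' @param config a [cohort_config()].
#' @return a list of class `synthetic_cohort` with `cohort` (an
#'   `aki_cohort`), `truth` (one row per encounter: unit, emission channel,
#'   onset day, drawn and realised progression flags, realised maximum stage
#'   and first AKI day, stage path list-column, dose bookkeeping) and
#'   `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n_encounters
  empty <- list(
    cohort = new_cohort(
      tibble(encounter_id = character(),
             admission_time = as.POSIXct(character(), tz = "UTC"),
             discharge_time = as.POSIXct(character(), tz = "UTC"),
             age = numeric(), sex = character(), race_black = logical(),
             unit = character(), admission_type = character(),
             baseline_creatinine = numeric()),
      tibble(encounter_id = character(),
             timestamp = as.POSIXct(character(), tz = "UTC"),
             kind = character(), value = numeric())),
    truth = tibble(encounter_id = character()), config = config)
  if (n == 0) return(structure(empty, class = "synthetic_cohort"))

  ids <- sprintf("enc%05d", seq_len(n))
  unit <- ifelse(stats::runif(n) < config$unit_gicu_fraction, "GICU", "CICU")
  lp <- lnorm_params(config$los_mean_days, config$los_sd_days)
  n_days <- pmax(config$los_min_days,
                 ceiling(stats::rlnorm(n, lp$meanlog, lp$sdlog)))
  age <- pmin(config$age_max,
              pmax(config$age_min,
                   round(stats::rnorm(n, config$age_mean, config$age_sd))))
  female <- stats::runif(n) < config$female_fraction
  black <- stats::runif(n) < config$black_fraction
  wp <- lnorm_params(config$weight_mean, config$weight_sd)
  weight <- round(stats::rlnorm(n, wp$meanlog, wp$sdlog), 1)
  true_baseline <- round(stats::rlnorm(n, config$baseline_scr_meanlog,
                                       config$baseline_scr_sdlog), 2)
  charted <- stats::runif(n) < config$fraction_charted_baseline
  rrt <- stats::runif(n) < config$rrt_probability
  channel <- ifelse(stats::runif(n) < config$cr_channel_fraction, "cr", "uo")
  progress1 <- stats::runif(n) < config$p_progress_1
  progress23 <- stats::runif(n) < config$p_2_to_3

  onset_day <- rep(NA_integer_, n)
  if (config$onset_mode == "all_day1") {
    onset_day[] <- 1L
  } else if (config$onset_mode == "hazard") {
    for (i in seq_len(n)) {
      for (d in seq_len(n_days[i])) {
        if (stats::runif(1) < hazard_for(config, unit[i], d)) {
          onset_day[i] <- d
          break
        }
      }
    }
  }

  # baseline the staging engine will resolve: the charted value when present,
  # otherwise the MDRD back-calculation; emissions are relative to it so that
  # emitted creatinine satisfies exactly the intended stage criterion
  resolved_baseline <- ifelse(
    charted, true_baseline,
    estimate_baseline_scr(age, female, black))

  admission <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
    (seq_len(n) - 1) * 86400

  # assemble events as plain vectors per encounter (timestamps as seconds
  # since admission) and build a single tibble at the end
  per_enc <- purrr::map(seq_len(n), function(i) {
    D <- n_days[i]
    path <- latent_path(D, onset_day[i], progress1[i], progress23[i], config)
    r <- config$uo_rates

    if (channel[i] == "uo") {
      rates <- unlist(lapply(path, uo_day_rates, r = r))
      scr_mult <- rep(1, D)
    } else {
      rates <- rep(r$healthy, 24 * D)
      scr_mult <- config$cr_ratios[path + 1L]
    }
    if (config$uo_noise_sd > 0) {
      rates <- pmax(0, rates + stats::rnorm(length(rates), 0,
                                            config$uo_noise_sd))
    }
    scr_vals <- resolved_baseline[i] * scr_mult
    if (config$scr_noise_sd > 0) {
      scr_vals <- pmax(0.05, scr_vals + stats::rnorm(D, 0,
                                                     config$scr_noise_sd))
    }
    egfr_vals <- round(mdrd_egfr(scr_vals, age[i], female[i], black[i]), 1)
    rec <- recommended_dose(egfr_vals)
    err <- stats::runif(D) < config$dose_error_rate
    dose_val <- ifelse(err, ifelse(rec < 40, 40, 60), rec)
    keep_dose <- err | rec > 0
    days0 <- (seq_len(D) - 1) * 86400

    off <- c(0,
             seq_len(24 * D) * 3600,
             days0 + config$scr_hour * 3600,
             days0 + config$egfr_hour * 3600,
             (days0 + config$dose_hour * 3600)[keep_dose])
    kind <- c("weight",
              rep("urine_output", 24 * D),
              rep("creatinine", D),
              rep("egfr", D),
              rep("enoxaparin_dose", sum(keep_dose)))
    value <- c(weight[i],
               round(rates * weight[i], 1),
               round(scr_vals, 3),
               egfr_vals,
               dose_val[keep_dose])
    if (rrt[i]) {
      off <- c(off, 12 * 3600, min(36 * 3600, D * 86400))
      kind <- c(kind, "rrt_start", "rrt_stop")
      value <- c(value, 0, 0)
    }
    ord <- order(off)
    realized_max <- max(path)
    list(off = off[ord], kind = kind[ord], value = value[ord],
         n_ev = length(off),
         progressed_from_1 = any(path == 1L) && realized_max > 1,
         progressed_2_to_3 = any(path == 2L) && realized_max == 3L,
         max_stage = as.integer(realized_max),
         first_aki_day = if (any(path > 0)) which(path > 0)[1]
                         else NA_integer_,
         n_doses_charted = sum(keep_dose),
         n_error_doses = sum(err),
         path = path)
  })

  encounters <- tibble(
    encounter_id = ids,
    admission_time = admission,
    discharge_time = admission + n_days * 86400,
    age = age,
    sex = ifelse(female, "female", "male"),
    race_black = black,
    unit = unit,
    admission_type = ifelse(unit == "CICU", "surgical-elective",
                            "medical"),
    baseline_creatinine = ifelse(charted, true_baseline, NA_real_)
  )
  n_ev <- vapply(per_enc, `[[`, integer(1), "n_ev")
  events <- tibble(
    encounter_id = rep(ids, n_ev),
    timestamp = rep(admission, n_ev) +
      unlist(purrr::map(per_enc, "off"), use.names = FALSE),
    kind = unlist(purrr::map(per_enc, "kind"), use.names = FALSE),
    value = unlist(purrr::map(per_enc, "value"), use.names = FALSE)
  )
  truth <- tibble(
    encounter_id = ids, unit = unit, channel = channel,
    n_days = n_days, onset_day = onset_day,
    progress1_drawn = progress1,
    progressed_from_1 = vapply(per_enc, `[[`, logical(1),
                               "progressed_from_1"),
    progress23_drawn = progress23,
    progressed_2_to_3 = vapply(per_enc, `[[`, logical(1),
                               "progressed_2_to_3"),
    max_stage = vapply(per_enc, `[[`, integer(1), "max_stage"),
    first_aki_day = vapply(per_enc, `[[`, integer(1), "first_aki_day"),
    rrt = rrt, weight_kg = weight,
    n_dose_slots = n_days,
    n_doses_charted = vapply(per_enc, `[[`, integer(1), "n_doses_charted"),
    n_error_doses = vapply(per_enc, `[[`, integer(1), "n_error_doses"),
    stage_path = purrr::map(per_enc, "path")
  )
  structure(list(cohort = new_cohort(encounters, events), truth = truth,
                 config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d encounters (seed %d), %d with AKI\n",
              nrow(x$cohort$encounters), x$config$seed,
              sum(x$truth$max_stage > 0)))
  invisible(x)
}

#' Generate a two-phase (control/intervention) synthetic study
#'
#' Derives independent seeds for the two phases from a master seed and tags
#' the resulting cohorts.
#'
#' @param control_config,intervention_config [cohort_config()]s for the two
#'   phases (their `seed` fields are overridden).
#' @param master_seed master RNG seed.
#' @return a list of class `two_phase_study` with elements `control` and
#'   `intervention`, each a `synthetic_cohort`.
#' @export
generate_two_phase_study <- function(control_config, intervention_config,
                                     master_seed) {
  seeds <- withr::with_seed(master_seed,
                            sample.int(.Machine$integer.max - 1, 2))
  control_config$seed <- seeds[1]
  intervention_config$seed <- seeds[2]
  structure(list(control = generate_cohort(control_config),
                 intervention = generate_cohort(intervention_config),
                 master_seed = master_seed),
            class = "two_phase_study")
}

#' Control- and intervention-like study configurations
#'
#' Convenience wrappers over [cohort_config()] with the phase-specific rates:
#' stage-1 progression 0.42 vs 0.335, stage-2-to-3 progression 0.213 vs
#' 0.118, per-dose error rate 1.72% vs 0.6%, charted baseline fraction 1.6%
#' vs 58%, RRT 6.5% vs 7.9%.
#'
#' @param n_encounters cohort size.
#' @param seed RNG seed.
#' @param ... further overrides passed to [cohort_config()].
#' @export
config_control_like <- function(n_encounters, seed, ...) {
  cohort_config(n_encounters = n_encounters, seed = seed,
                p_progress_1 = 0.42, p_2_to_3 = 0.213,
                dose_error_rate = 0.0172,
                fraction_charted_baseline = 0.016,
                rrt_probability = 0.065, ...)
}

#' @rdname config_control_like
#' @export
config_intervention_like <- function(n_encounters, seed, ...) {
  cohort_config(n_encounters = n_encounters, seed = seed,
                p_progress_1 = 0.335, p_2_to_3 = 0.118,
                dose_error_rate = 0.006,
                fraction_charted_baseline = 0.58,
                rrt_probability = 0.079, ...)
}
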