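#' Default eGFR-based enoxaparin dose table
#'
#' Half-open eGFR bands `[lower, upper)` partitioning `[0, Inf)` with the
#' recommended daily prophylactic dose: 40 mg at eGFR of 30 and above, 20 mg
#' in `[20, 30)`, and no enoxaparin (0 mg) below 20.
#'
#' @return a tibble `egfr_lower`, `egfr_upper`, `dose_mg`.
#' @export
default_dose_table <- function() {
  tibble(egfr_lower = c(0, 20, 30),
         egfr_upper = c(20, 30, Inf),
         dose_mg = c(0, 20, 40))
}

validate_dose_table <- function(table) {
  stopifnot(all(c("egfr_lower", "egfr_upper", "dose_mg") %in% names(table)))
  table <- table[order(table$egfr_lower), ]
  if (table$egfr_lower[1] != 0 || !is.infinite(table$egfr_upper[nrow(table)]) ||
      (nrow(table) > 1 &&
       any(table$egfr_upper[-nrow(table)] != table$egfr_lower[-1]))) {
    stopf("dose table bands must partition [0, Inf)")
  }
  if (any(table$dose_mg < 0) || is.unsorted(table$dose_mg)) {
    stopf("recommended doses must be non-negative and non-decreasing in eGFR")
  }
  table
}

#' Recommended daily enoxaparin dose for an eGFR
#'
#' @param egfr eGFR value(s), mL/min/1.73 m² (non-negative).
#' @param table dose table as in [default_dose_table()].
#' @return recommended dose(s), mg/day.
#' @export
recommended_dose <- function(egfr, table = default_dose_table()) {
  if (any(egfr < 0)) stopf("eGFR must be non-negative")
  table <- validate_dose_table(table)
  idx <- findInterval(egfr, table$egfr_lower)
  table$dose_mg[idx]
}

empty_assessments <- function() {
  tibble(encounter_id = character(),
         dose_time = as.POSIXct(character(), tz = "UTC"),
         dose_mg = numeric(), egfr = numeric(),
         egfr_time = as.POSIXct(character(), tz = "UTC"),
         recommended_mg = numeric(), verdict = character(),
         ineligibility_reason = character())
}

#' Classify the enoxaparin doses of an encounter
#'
#' Each administered (nonzero) dose is judged against the closest preceding
#' eGFR: correct when the dose does not exceed the recommended daily dose for
#' that eGFR, incorrect otherwise. Doses given before any eGFR is available
#' are ineligible (`no_prior_egfr`). Encounters on RRT or whose maximum
#' charted weight exceeds `weight_limit_kg` are ineligible as a whole.
#'
#' @param encounter an `aki_encounter`.
#' @param table dose table.
#' @param weight_limit_kg weight cutoff, kg (the maximum charted weight
#'   during the stay is compared against it).
#' @return a tibble with one row per dose: `encounter_id`, `dose_time`,
#'   `dose_mg`, `egfr`, `egfr_time`, `recommended_mg`, `verdict` (`correct`,
#'   `incorrect` or `ineligible`), `ineligibility_reason`.
#' @export
classify_doses <- function(encounter, table = default_dose_table(),
                           weight_limit_kg = 100) {
  stopifnot(inherits(encounter, "aki_encounter"))
  ev <- encounter$events
  doses <- ev[ev$kind == "enoxaparin_dose" & ev$value > 0, ]
  base <- tibble(
    encounter_id = encounter$encounter_id,
    dose_time = doses$timestamp, dose_mg = doses$value,
    egfr = NA_real_,
    egfr_time = as.POSIXct(rep(NA_real_, nrow(doses)), tz = "UTC"),
    recommended_mg = NA_real_,
    verdict = rep("ineligible", nrow(doses)),
    ineligibility_reason = rep(NA_character_, nrow(doses))
  )
  if (nrow(doses) == 0) return(base)
  wts <- ev$value[ev$kind == "weight"]
  if (nrow(encounter$rrt_intervals) > 0) {
    base$ineligibility_reason <- "rrt"
    return(base)
  }
  if (length(wts) && max(wts) > weight_limit_kg) {
    base$ineligibility_reason <- "weight_gt_100kg"
    return(base)
  }
  egfr_ev <- ev[ev$kind == "egfr", ]
  idx <- findInterval(as.numeric(doses$timestamp),
                      as.numeric(egfr_ev$timestamp))
  has_egfr <- idx > 0
  base$ineligibility_reason[!has_egfr] <- "no_prior_egfr"
  if (any(has_egfr)) {
    base$egfr[has_egfr] <- egfr_ev$value[idx[has_egfr]]
    base$egfr_time[has_egfr] <- egfr_ev$timestamp[idx[has_egfr]]
    base$recommended_mg[has_egfr] <- recommended_dose(base$egfr[has_egfr],
                                                      table)
    base$verdict[has_egfr] <- ifelse(
      base$dose_mg[has_egfr] <= base$recommended_mg[has_egfr],
      "correct", "incorrect")
  }
  base
}

#' Per-encounter enoxaparin compliance
#'
#' @param assessments dose assessments for one encounter from
#'   [classify_doses()].
#' @return a one-row tibble: `encounter_id`, counts `n_correct`,
#'   `n_incorrect`, `n_ineligible`, `eligible` (any assessable dose and not
#'   excluded wholesale) and `fully_compliant` (no incorrect dose and at
#'   least one correct one).
#' @export
encounter_compliance <- function(assessments) {
  n_correct <- sum(assessments$verdict == "correct")
  n_incorrect <- sum(assessments$verdict == "incorrect")
  n_ineligible <- sum(assessments$verdict == "ineligible")
  whole_excluded <- any(assessments$ineligibility_reason %in%
                          c("rrt", "weight_gt_100kg"))
  tibble(
    encounter_id = if (nrow(assessments)) assessments$encounter_id[1]
                   else NA_character_,
    n_correct = n_correct, n_incorrect = n_incorrect,
    n_ineligible = n_ineligible,
    eligible = !whole_excluded & (n_correct + n_incorrect) > 0,
    fully_compliant = !whole_excluded & n_incorrect == 0 & n_correct >= 1
  )
}

#' Cohort-level enoxaparin dose summary
#'
#' @param cohort an `aki_cohort`.
#' @param table dose table.
#' @param weight_limit_kg weight cutoff for encounter eligibility.
#' @return a list with the pooled `assessments` tibble, the per-encounter
#'   `compliance` tibble, and a one-row `summary` tibble: `total_doses` (the
#'   assessable correct + incorrect doses), `incorrect_doses`,
#'   `incorrect_fraction` (`NA` when nothing was assessable),
#'   `eligible_encounters`, `compliant_encounters`, `compliant_fraction`.
#' @export
cohort_dose_summary <- function(cohort, table = default_dose_table(),
                                weight_limit_kg = 100) {
  encs <- as_encounters(cohort)
  assessments <- purrr::map_dfr(encs, classify_doses, table = table,
                                weight_limit_kg = weight_limit_kg)
  if (nrow(assessments) == 0) assessments <- empty_assessments()
  compliance <- if (nrow(assessments) == 0) {
    encounter_compliance(assessments)[0, ]
  } else {
    purrr::map_dfr(split(assessments, assessments$encounter_id),
                   encounter_compliance)
  }
  total <- sum(compliance$n_correct) + sum(compliance$n_incorrect)
  incorrect <- sum(compliance$n_incorrect)
  eligible <- sum(compliance$eligible)
  compliant <- sum(compliance$fully_compliant)
  list(
    assessments = assessments,
    compliance = compliance,
    summary = tibble(
      total_doses = total,
      incorrect_doses = incorrect,
      incorrect_fraction = if (total > 0) incorrect / total else NA_real_,
      eligible_encounters = eligible,
      compliant_encounters = compliant,
      compliant_fraction = if (eligible > 0) compliant / eligible
                           else NA_real_
    )
  )
}

#' Breakdown of incorrect doses by eGFR band and given dose
#'
#' @param assessments pooled dose assessments.
#' @param table dose table defining the bands.
#' @return a tibble `egfr_band`, `dose_mg`, `n_incorrect`; the counts sum to
#'   the total number of incorrect doses.
#' @export
dose_error_breakdown <- function(assessments, table = default_dose_table()) {
  table <- validate_dose_table(table)
  bad <- assessments[assessments$verdict == "incorrect", ]
  if (nrow(bad) == 0) {
    return(tibble(egfr_band = character(), dose_mg = numeric(),
                  n_incorrect = integer()))
  }
  idx <- findInterval(bad$egfr, table$egfr_lower)
  bad$egfr_band <- sprintf("[%g,%g)", table$egfr_lower[idx],
                           table$egfr_upper[idx])
  bad |>
    dplyr::count(.data$egfr_band, .data$dose_mg, name = "n_incorrect") |>
    as_tibble()
}
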