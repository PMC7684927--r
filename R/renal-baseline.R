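#' MDRD estimated glomerular filtration rate
#'
#' Four-variable re-expressed MDRD study equation for IDMS-aligned creatinine:
#'
#' eGFR = 175 * SCr^-1.154 * age^-0.203 * 0.742\[if female\] * 1.212\[if Black\]
#'
#' in mL/min/1.73 m² with serum creatinine in mg/dL and age in years.
#'
#' @param scr serum creatinine, mg/dL (> 0).
#' @param age age in years (> 0).
#' @param female,black logical demographic flags.
#' @param coefficient leading coefficient; 175 for the re-expressed (IDMS)
#'   variant, 186 for the original.
#' @param use_race_coefficient apply the 1.212 factor for Black patients.
#' @return eGFR in mL/min/1.73 m²; vectorised over all arguments.
#' @export
mdrd_egfr <- function(scr, age, female, black,
                      coefficient = 175, use_race_coefficient = TRUE) {
  if (any(scr <= 0)) stopf("serum creatinine must be positive")
  if (any(age <= 0)) stopf("age must be positive")
  coefficient * scr^-1.154 * age^-0.203 *
    ifelse(female, 0.742, 1) *
    ifelse(black & use_race_coefficient, 1.212, 1)
}

#' Back-calculate baseline creatinine from an assumed-normal eGFR
#'
#' Inverts the MDRD equation: the unique serum creatinine at which a patient
#' of the given age, sex and race would have the assumed eGFR. Used to supply
#' a baseline creatinine when none is charted.
#'
#' @inheritParams mdrd_egfr
#' @param assumed_egfr assumed-normal eGFR, mL/min/1.73 m² (default 75, the
#'   convention for MDRD baseline back-calculation).
#' @return baseline serum creatinine, mg/dL; vectorised.
#' @export
estimate_baseline_scr <- function(age, female, black, assumed_egfr = 75,
                                  coefficient = 175,
                                  use_race_coefficient = TRUE) {
  if (any(age <= 0)) stopf("age must be positive")
  if (any(assumed_egfr <= 0)) stopf("assumed eGFR must be positive")
  k <- coefficient * age^-0.203 *
    ifelse(female, 0.742, 1) *
    ifelse(black & use_race_coefficient, 1.212, 1)
  (assumed_egfr / k)^(-1 / 1.154)
}

#' Resolve the baseline creatinine for an encounter
#'
#' Uses the charted baseline when one is present; otherwise back-calculates it
#' from the MDRD equation at the assumed-normal eGFR, flagging the source.
#'
#' @param encounter an `aki_encounter`.
#' @param assumed_egfr assumed-normal eGFR for the MDRD fallback.
#' @param coefficient,use_race_coefficient passed to [estimate_baseline_scr()].
#' @return a list with `value` (mg/dL), `source` (`"charted"` or
#'   `"mdrd_estimated"`) and, for estimates, `assumed_egfr`.
#' @export
resolve_baseline <- function(encounter, assumed_egfr = 75,
                             coefficient = 175, use_race_coefficient = TRUE) {
  stopifnot(inherits(encounter, "aki_encounter"))
  if (!is.null(encounter$baseline_creatinine) &&
      !is.na(encounter$baseline_creatinine)) {
    return(list(value = encounter$baseline_creatinine, source = "charted",
                assumed_egfr = NA_real_))
  }
  est <- estimate_baseline_scr(
    age = encounter$age, female = encounter$sex == "female",
    black = isTRUE(encounter$race_black), assumed_egfr = assumed_egfr,
    coefficient = coefficient, use_race_coefficient = use_race_coefficient)
  list(value = est, source = "mdrd_estimated", assumed_egfr = assumed_egfr)
}
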