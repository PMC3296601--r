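#' Monthly care cost by MMSE severity band
#'
#' Step-function lookup of the monthly direct patient-care cost (2008
#' euros). The same cost applies regardless of location of care, since the
#' band costs blend ambulatory and nursing-home care.
#'
#' @param mmse Current MMSE score(s) in [0, 30]. Vectorised.
#' @param params Model parameters.
#' @return Monthly cost(s) in euros.
#' @export
#' @examples
#' monthly_care_cost(17)  # 1275
monthly_care_cost <- function(mmse, params = default_parameters()) {
  if (any(mmse < 0 | mmse > 30))
    stop("invalid argument: mmse must lie in [0, 30]")
  bands <- params$costs$care_monthly
  out <- rep(NA_real_, length(mmse))
  for (j in seq_len(nrow(bands))) {
    top_band <- bands$mmse_max[j] >= 30
    in_band <- mmse >= bands$mmse_min[j] &
      (if (top_band) mmse <= bands$mmse_max[j] else mmse < bands$mmse_max[j])
    out[in_band] <- bands$cost[j]
  }
  out
}

#' Expected proportion of patients institutionalized at a given MMSE
#'
#' Linear model fitted through the reported institutionalization rates of
#' German AD patients (42.9% below MMSE 20, 0% at 20 or above):
#' `max(0, 0.6435 - 0.0286 * MMSE)`, optionally capped. The simulation
#' carries location of care as this severity-linked expected fraction
#' rather than as individual transitions.
#'
#' @param mmse Current MMSE score(s). Vectorised.
#' @param params Model parameters.
#' @return Proportion(s) in [0, 1].
#' @export
#' @examples
#' institutionalized_fraction(10)  # 0.3575
institutionalized_fraction <- function(mmse, params = default_parameters()) {
  if (any(mmse < 0 | mmse > 30))
    stop("invalid argument: mmse must lie in [0, 30]")
  co <- params$institutionalization
  pmin(pmax(0, co[["intercept"]] - co[["mmse_slope"]] * mmse),
       params$institutionalization_cap)
}

#' Daily caregiver time
#'
#' Linear predictor for caregiver minutes per day as a function of caregiver
#' age and sex, patient sex, current disease scores (NPI on the raw 0-144
#' scale) and psychiatric-medication use; floored at zero. If the optional
#' MMSE-band table `params$costs$caregiver_time_table` is supplied (columns
#' `mmse_min`, `minutes_per_day`, rows in decreasing `mmse_min` order
#' covering 0), it replaces the regression.
#'
#' @param mmse,npi,adl,iadl Current scores. Vectorised.
#' @param cg_age,cg_male Caregiver age (years) and sex dummy.
#' @param male Patient-sex dummy.
#' @param psy_med Psychiatric-medication dummy.
#' @param params Model parameters.
#' @return Minutes per day.
#' @export
#' @examples
#' caregiver_minutes_per_day(20, 20, 30, 40, cg_age = 70, cg_male = 0,
#'                           male = 1, psy_med = 0)  # 354.37
caregiver_minutes_per_day <- function(mmse, npi, adl, iadl, cg_age, cg_male,
                                      male, psy_med,
                                      params = default_parameters()) {
  tab <- params$costs$caregiver_time_table
  if (!is.null(tab)) {
    idx <- vapply(mmse, function(m) which(m >= tab$mmse_min)[1], integer(1))
    return(pmax(0, tab$minutes_per_day[idx]))
  }
  co <- params$caregiver_time
  pmax(0, co[["intercept"]] + co[["age_cg"]] * cg_age +
         co[["male_cg"]] * cg_male + co[["male_patient"]] * male +
         co[["mmse"]] * mmse + co[["npi"]] * npi + co[["adl"]] * adl +
         co[["iadl"]] * iadl + co[["psy_med"]] * psy_med)
}

#' Patient health utility
#'
#' EQ-5D-based utility as a linear function of current MMSE, current NPI
#' (raw scale), institutionalization and living with the caregiver. Because
#' the simulation carries institutionalization as an expected fraction, the
#' binary dummy is replaced by that fraction. The predictor is clamped to
#' at most 1 (it may fall below 0, as EQ-5D utilities can).
#'
#' @param mmse,npi Current scores.
#' @param institutionalized_frac Expected institutionalized fraction in
#'   [0, 1].
#' @param lives_with_cg 0/1: patient lives with the caregiver.
#' @param params Model parameters.
#' @return Utility value(s), at most 1.
#' @export
#' @examples
#' patient_utility(20, 10, 0, 1)  # 0.619
patient_utility <- function(mmse, npi, institutionalized_frac, lives_with_cg,
                            params = default_parameters()) {
  if (any(institutionalized_frac < 0 | institutionalized_frac > 1))
    stop("invalid argument: institutionalized_frac must lie in [0, 1]")
  co <- params$utility_patient
  pmin(1, co[["intercept"]] + co[["mmse"]] * mmse + co[["npi"]] * npi +
         co[["institutionalized"]] * institutionalized_frac +
         co[["caregiver"]] * lives_with_cg)
}

#' Caregiver health utility
#'
#' SF-36-derived utility for the caregiver as a linear function of caregiver
#' age and sex, patient age, and the patient's current scores (the MMSE
#' coefficient is zero as published). NPI enters on the raw 0-144 scale.
#'
#' @param mmse,npi,adl,iadl Patient's current scores.
#' @param cg_age,cg_male Caregiver age and sex dummy.
#' @param age Patient age at baseline.
#' @param psy_med Psychiatric-medication dummy.
#' @param params Model parameters.
#' @return Utility value(s), at most 1.
#' @export
#' @examples
#' caregiver_utility(20, 10, 30, 40, cg_age = 70, cg_male = 1, age = 75,
#'                   psy_med = 0)  # 0.739
caregiver_utility <- function(mmse, npi, adl, iadl, cg_age, cg_male, age,
                              psy_med, params = default_parameters()) {
  co <- params$utility_caregiver
  pmin(1, co[["intercept"]] + co[["age_cg"]] * cg_age +
         co[["male_cg"]] * cg_male + co[["age_patient"]] * age +
         co[["mmse"]] * mmse + co[["npi"]] * npi + co[["adl"]] * adl +
         co[["iadl"]] * iadl + co[["psy_med"]] * psy_med)
}

#' Present value of a constant unit-rate stream over a time segment
#'
#' Continuous discounting with the annual-equivalent force
#' `delta = log(1 + rate)`, so a unit rate over `[t0, t1]` years has present
#' value `(exp(-delta t0) - exp(-delta t1)) / delta`; with rate 0 this is
#' the segment length. Multiply by the stream's annual rate for arbitrary
#' piecewise-constant streams.
#'
#' @param t0,t1 Segment start and end in years, `0 <= t0 <= t1`. Vectorised.
#' @param rate Annual discount rate (default 0.03).
#' @return Present value(s) of a unit annual rate over the segment.
#' @export
#' @examples
#' discounted_integral(0, 10)  # 8.65753
discounted_integral <- function(t0, t1, rate = 0.03) {
  if (rate < 0) stop("invalid argument: rate must be >= 0")
  if (any(t1 < t0) || any(t0 < 0))
    stop("invalid argument: need 0 <= t0 <= t1")
  if (rate == 0) return(t1 - t0)
  delta <- log1p(rate)
  (exp(-delta * t0) - exp(-delta * t1)) / delta
}
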