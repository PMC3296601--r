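#' Default model parameters
#'
#' Returns the full set of model inputs used by the simulation: disease
#' progression equation coefficients, treatment-effect terms, persistence
#' (discontinuation) risk schedules, the parametric mortality stand-in,
#' German cost inputs (2008 euros), the institutionalization model,
#' caregiver-time and utility regressions, discounting, and the severity
#' thresholds used for time-above/below-threshold reporting.
#'
#' Every equation's coefficients are named so that sensitivity analyses can
#' perturb them individually.
#'
#' Scale conventions: MMSE 0-30 (higher = better cognition); NPI 0-144
#' (higher = worse behaviour; the NPI change equation operates internally on
#' a normalised 0-100 scale, raw/1.44); ADL and IADL 0-100 (0 = best
#' function). All progression rates are annual; a model year is 52 weeks.
#'
#' @return A named list of class `adesim_params`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$costs$drug_daily
default_parameters <- function() {
  p <- list(
    progression = list(
      # Annual MMSE rate of change: piecewise-linear in the previous MMSE
      # (PM1 = min(prev, 9); PM2 = max(0, min(prev - 9, 9));
      #  PM3 = max(0, min(prev - 18, 12))), previous-year rate, and age.
      mmse = c(intercept = -5.4663, pm1 = -0.4299, pm2 = -0.0042,
               pm3 = 0.1415, prev_rate = -0.0791, age = 0.0747),
      # NPI change from baseline, on the normalised 0-100 scale; the result
      # is multiplied by npi_rescale to return to the raw 0-144 range.
      npi = c(intercept = 5.74, donepezil = -0.64, weeks = 0.03,
              npi_base = -0.59, npi_base_weeks = -0.001, npi_recent = 0.24,
              white = -1.74, black = -3.82, psy_med = 2.34,
              mmse_base = 0.12, mmse_recent = -0.22),
      npi_rescale = 1.44,
      adl = c(intercept = 1.35, donepezil = -0.81, weeks = 0.06,
              adl_base = -0.79, adl_prev = 0.71, mmse_base = 0.12,
              age = 0.09, psy_med = 0.81, black = -3.05,
              mmse_recent = -0.49),
      iadl = c(intercept = 1.27, donepezil = 0.63, weeks = 0.17,
               donepezil_weeks = -0.06, iadl_base = -0.84,
               iadl_base_weeks = 0.002, iadl_prev = 0.84, male = -0.67,
               mmse_base = 0.20, mmse_recent = -0.28, adl_base = -0.16,
               adl_recent = 0.18),
      # Donepezil term in the MMSE rate equation: 6.16 points/yr during the
      # first 20 weeks on treatment, 2.47 over weeks 20-52, 0 afterwards
      # (maintenance only).
      donepezil_rate = c(early = 6.16, late = 2.47),
      donepezil_rate_breaks = c(early_weeks = 20, late_weeks = 52),
      # Benefits are lost linearly over 6 weeks after stopping treatment.
      taper_weeks = 6
    ),
    # Placebo-adjusted 6-month effects used to derive memantine's effects
    # from donepezil's (no head-to-head data): memantine coefficient =
    # donepezil coefficient x (memantine effect / donepezil effect), per
    # scale; the functional ratio is shared by ADL and IADL.
    effects_6mo = list(
      donepezil = c(mmse = 1.16, npi = -2.40, func = -4.44),
      memantine = c(mmse = 0.48, npi = -2.76, func = -2.35)
    ),
    persistence = list(
      # Cumulative discontinuation risks; the 6-12-month and after-12-month
      # entries are interval risks conditional on still being on treatment
      # at the interval start (piecewise-exponential construction).
      donepezil = c(m0_3 = 0.051, m0_6 = 0.051, m6_12 = 0.102,
                    annual_after_12 = 0.103),
      memantine = c(m0_3 = 0.031, m0_6 = 0.031, m6_12 = 0.063,
                    annual_after_12 = 0.063),
      # Hook for Cox hazard ratios on time-updated MMSE and MMSE decline
      # rate (coefficients were not published; identity by default).
      hr_coef = c(mmse = 0, mmse_rate = 0)
    ),
    mortality = list(
      # Gompertz residual-life stand-in for the life-table construction,
      # calibrated so a 60%-female cohort aged 75 has a mean 10-year
      # truncated survival of 4.89 years.
      shape = 0.09,
      rate_female = 6.1366e-05,
      rate_male = 9.8186e-05,
      dementia_multiplier = 2.0
    ),
    costs = list(
      # Monthly care costs by MMSE severity band (2008 euros); the same
      # cost applies regardless of location of care.
      care_monthly = data.frame(
        mmse_min = c(25, 20, 15, 10, 0),
        mmse_max = c(30, 25, 20, 15, 10),   # upper bound exclusive except top
        cost = c(184, 593, 1275, 1958, 2981)
      ),
      drug_daily = c(none = 0, donepezil = 4.20, memantine = 3.83),
      monitoring_quarterly = 53.47,   # GP visit/assessment, on treatment only
      caregiver_hour = 5.21,
      # Optional alternative caregiver-time source: a data.frame with
      # columns mmse_min, minutes_per_day replacing the regression.
      caregiver_time_table = NULL
    ),
    institutionalization = c(intercept = 0.6435, mmse_slope = 0.0286),
    institutionalization_cap = 1.0,
    caregiver_time = c(intercept = 76.41, age_cg = 1.8, male_cg = 93.02,
                       male_patient = 85.56, mmse = -6.47, npi = 0.58,
                       adl = 2.66, iadl = 2.61, psy_med = 20.55),
    utility_patient = c(intercept = 0.408, mmse = 0.010, npi = -0.004,
                        institutionalized = -0.159, caregiver = 0.051),
    utility_caregiver = c(intercept = 0.90, age_cg = -0.003, male_cg = 0.03,
                          age_patient = 0.001, mmse = 0.00, npi = -0.001,
                          adl = -0.001, iadl = -0.0004, psy_med = -0.01),
    discount_rate = 0.03,
    thresholds = c(mmse = 10, npi = 28, adl = 50, iadl = 50)
  )
  class(p) <- c("adesim_params", "list")
  p
}

#' Default simulation configuration
#'
#' @param horizon_years Simulation horizon (default 10 years).
#' @param update_interval_weeks Scheduled reassessment cadence (default 6
#'   weeks, matching the benefit-loss taper window).
#' @param treatment_duration_years Maximum time on treatment (default equals
#'   the horizon, i.e. no cap short of the horizon).
#' @param stopping_rule One of `"none"`, `"mmse_below_10"`,
#'   `"deterioration_any_scale_after_6mo"`.
#' @param discount_rate Annual discount rate for costs and QALYs.
#' @return A named list of class `adesim_config`.
#' @export
default_config <- function(horizon_years = 10, update_interval_weeks = 6,
                           treatment_duration_years = horizon_years,
                           stopping_rule = "none", discount_rate = 0.03) {
  stopifnot(horizon_years > 0, update_interval_weeks > 0,
            treatment_duration_years > 0)
  cfg <- list(
    horizon_years = horizon_years,
    update_interval_weeks = update_interval_weeks,
    treatment_duration_years = treatment_duration_years,
    stopping_rule = stopping_rule,
    discount_rate = discount_rate
  )
  class(cfg) <- c("adesim_config", "list")
  cfg
}

#' Memantine-to-donepezil effect ratios per scale
#'
#' Derives the per-scale scaling applied to donepezil's treatment
#' coefficients to obtain memantine's, from the placebo-adjusted 6-month
#' effect table. The functional ratio applies to both ADL and IADL.
#'
#' @param params Model parameters.
#' @return Named vector with elements `mmse`, `npi`, `adl`, `iadl`.
#' @keywords internal
memantine_ratios <- function(params) {
  tab <- memantine_effect_table(params$effects_6mo$donepezil,
                                params$effects_6mo$memantine)
  c(mmse = tab$ratio[["mmse"]], npi = tab$ratio[["npi"]],
    adl = tab$ratio[["func"]], iadl = tab$ratio[["func"]])
}

# Per-arm multiplier on the donepezil treatment coefficients.
arm_effect_scale <- function(arm, params) {
  switch(arm,
    none = c(mmse = 0, npi = 0, adl = 0, iadl = 0),
    donepezil = c(mmse = 1, npi = 1, adl = 1, iadl = 1),
    memantine = memantine_ratios(params),
    stop("unknown arm: ", arm)
  )
}

#' Validate a parameter set
#'
#' Checks structural requirements: care-cost bands partition the MMSE range
#' 0-30 without gaps, risks lie in [0,1), rates are positive, and required
#' keys are present. Errors name the offending key.
#'
#' @param params Parameter list as from [default_parameters()].
#' @return `params`, invisibly, if valid.
#' @export
validate_parameters <- function(params) {
  required <- c("progression", "effects_6mo", "persistence", "mortality",
                "costs", "institutionalization", "caregiver_time",
                "utility_patient", "utility_caregiver", "discount_rate",
                "thresholds")
  missing <- setdiff(required, names(params))
  if (length(missing))
    stop("missing parameter key(s): ", paste(missing, collapse = ", "))
  bands <- params$costs$care_monthly
  bands <- bands[order(bands$mmse_min), ]
  if (bands$mmse_min[1] != 0 || bands$mmse_max[nrow(bands)] != 30)
    stop("costs$care_monthly: bands must span MMSE 0 to 30")
  if (nrow(bands) > 1 && any(bands$mmse_max[-nrow(bands)] != bands$mmse_min[-1]))
    stop("costs$care_monthly: gap or overlap between MMSE bands at mmse = ",
         bands$mmse_max[which(bands$mmse_max[-nrow(bands)] != bands$mmse_min[-1])[1]])
  if (any(bands$cost < 0)) stop("costs$care_monthly: negative cost")
  for (arm in c("donepezil", "memantine")) {
    r <- params$persistence[[arm]]
    if (any(r < 0) || any(r >= 1))
      stop("persistence$", arm, ": risks must lie in [0, 1)")
    if (r[["m0_6"]] < r[["m0_3"]])
      stop("persistence$", arm, ": cumulative risk at 6 months below 3-month risk")
  }
  with(params$mortality, {
    if (shape <= 0 || rate_female <= 0 || rate_male <= 0 ||
        dementia_multiplier <= 0)
      stop("mortality: shape, rates and dementia_multiplier must be positive")
  })
  if (params$discount_rate < 0) stop("discount_rate: must be >= 0")
  if (params$progression$taper_weeks <= 0)
    stop("progression$taper_weeks: must be positive")
  invisible(params)
}

#' @export
print.adesim_params <- function(x, ...) {
  cat("<adesim model parameters>\n")
  cat("  progression equations : MMSE rate, NPI/ADL/IADL change-from-baseline\n")
  cat("  donepezil rate terms  :",
      paste(x$progression$donepezil_rate, collapse = " / "),
      "points/yr (weeks <20 / 20-52)\n")
  cat("  drug cost per day     : donepezil EUR",
      x$costs$drug_daily[["donepezil"]], "; memantine EUR",
      x$costs$drug_daily[["memantine"]], "\n")
  cat("  discount rate         :", x$discount_rate, "per year\n")
  invisible(x)
}

#' @export
print.adesim_config <- function(x, ...) {
  cat("<adesim simulation config>\n")
  cat("  horizon            :", x$horizon_years, "years\n")
  cat("  update interval    :", x$update_interval_weeks, "weeks\n")
  cat("  treatment duration :", x$treatment_duration_years, "years\n")
  cat("  stopping rule      :", x$stopping_rule, "\n")
  invisible(x)
}
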