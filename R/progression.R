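#' Partition a previous MMSE score into piecewise-linear segments
#'
#' The annual MMSE rate-of-change equation is piecewise linear in the
#' previous MMSE measurement, split as
#' `PM1 = min(prev, 9)`, `PM2 = max(0, min(prev - 9, 9))`,
#' `PM3 = max(0, min(prev - 18, 12))`, so that the rate of decline can differ
#' across the severe (0-9), moderate (9-18) and mild (18-30) stretches of
#' the scale. The three components always sum to the input.
#'
#' @param prev_mmse Previous MMSE score(s), in [0, 30]. Vectorised.
#' @return A matrix with columns `pm1`, `pm2`, `pm3`.
#' @export
#' @examples
#' partition_mmse(20)  # 9, 9, 2
partition_mmse <- function(prev_mmse) {
  if (any(prev_mmse < 0 | prev_mmse > 30))
    stop("invalid argument: prev_mmse must lie in [0, 30]")
  cbind(pm1 = pmin(prev_mmse, 9),
        pm2 = pmax(0, pmin(prev_mmse - 9, 9)),
        pm3 = pmax(0, pmin(prev_mmse - 18, 12)))
}

#' Annual MMSE rate of change
#'
#' Linear predictor for the annual change in MMSE (points/year, signed;
#' negative = decline), as a function of the previous MMSE (piecewise),
#' the trailing-year rate of change, patient age, the patient's random
#' intercept, and any treatment term. Rates are never clamped; clamping is
#' applied to scores.
#'
#' @param prev_mmse Previous MMSE score(s).
#' @param prev_rate Trailing-year MMSE change (points/year, signed).
#' @param age Patient age at baseline (years).
#' @param delta Per-patient random intercept (points/year).
#' @param treatment_term Treatment term (points/year), see
#'   [treatment_rate_term()].
#' @param coef Named coefficient vector (defaults to the shipped values).
#' @return Annual rate(s) of change in MMSE points/year.
#' @export
#' @examples
#' mmse_annual_rate(20, 0, 75)  # -3.4877
mmse_annual_rate <- function(prev_mmse, prev_rate, age, delta = 0,
                             treatment_term = 0,
                             coef = default_parameters()$progression$mmse) {
  stopifnot(all(is.finite(prev_mmse)), all(is.finite(prev_rate)),
            all(is.finite(age)))
  pm <- partition_mmse(prev_mmse)
  unname(coef[["intercept"]] + coef[["pm1"]] * pm[, "pm1"] +
           coef[["pm2"]] * pm[, "pm2"] + coef[["pm3"]] * pm[, "pm3"] +
           coef[["prev_rate"]] * prev_rate + coef[["age"]] * age +
           delta + treatment_term)
}

#' Treatment term in the MMSE rate equation
#'
#' Donepezil adds 6.16 points/year to the MMSE rate of change during the
#' first 20 weeks on treatment and 2.47 over weeks 20-52; beyond one year
#' continued treatment maintains previous gains only (term 0). Memantine's
#' term is the donepezil term scaled by the ratio of placebo-adjusted
#' 6-month MMSE effects.
#'
#' @param arm `"none"`, `"donepezil"` or `"memantine"`.
#' @param weeks_on_treatment Weeks since treatment start (vectorised).
#' @param params Model parameters.
#' @return Treatment term(s) in MMSE points/year.
#' @export
#' @examples
#' treatment_rate_term("donepezil", 10)  # 6.16
treatment_rate_term <- function(arm, weeks_on_treatment,
                                params = default_parameters()) {
  if (any(weeks_on_treatment < 0))
    stop("invalid argument: weeks_on_treatment must be >= 0")
  scale <- arm_effect_scale(arm, params)[["mmse"]]
  dr <- params$progression$donepezil_rate
  br <- params$progression$donepezil_rate_breaks
  base <- ifelse(weeks_on_treatment < br[["early_weeks"]], dr[["early"]],
                 ifelse(weeks_on_treatment <= br[["late_weeks"]],
                        dr[["late"]], 0))
  scale * base
}

# Mean of the piecewise treatment rate term over a window [w0, w1] of weeks
# on treatment (exact integral / width); used by the engine so that the
# 20- and 52-week breakpoints need not align with the update grid.
treatment_rate_term_mean <- function(arm, w0, w1, params) {
  scale <- arm_effect_scale(arm, params)[["mmse"]]
  dr <- params$progression$donepezil_rate
  br <- params$progression$donepezil_rate_breaks
  seg <- function(lo, hi) pmax(0, pmin(w1, hi) - pmax(w0, lo))
  num <- dr[["early"]] * seg(0, br[["early_weeks"]]) +
    dr[["late"]] * seg(br[["early_weeks"]], br[["late_weeks"]])
  ifelse(w1 > w0, scale * num / (w1 - w0), 0)
}

#' NPI change from baseline
#'
#' Evaluates the NPI change-from-baseline equation. The equation was fitted
#' on a normalised 0-100 behaviour scale, so NPI inputs are divided by the
#' rescale factor (1.44) internally and the resulting change is multiplied
#' back to the raw 0-144 range. The `NPI x Weeks` interaction uses the
#' baseline NPI. MMSE inputs are on the raw 0-30 scale.
#'
#' @param donepezil 0/1 treatment indicator (memantine arms pass a scaled
#'   indicator, see `arm_effect_scale`).
#' @param weeks Weeks of follow-up since baseline.
#' @param npi_base,npi_recent Baseline and most recent NPI, raw 0-144 scale.
#' @param white,black Race dummies (reference: all other races).
#' @param psy_med Psychiatric-medication dummy.
#' @param mmse_base,mmse_recent Baseline and most recent MMSE.
#' @param delta Random intercept (normalised-scale units).
#' @param params Model parameters.
#' @return Change from baseline NPI on the raw 0-144 scale. The caller is
#'   responsible for clamping `npi_base + change` into [0, 144].
#' @export
change_npi <- function(donepezil, weeks, npi_base, npi_recent, white, black,
                       psy_med, mmse_base, mmse_recent, delta = 0,
                       params = default_parameters()) {
  if (any(weeks < 0)) stop("invalid argument: weeks must be >= 0")
  co <- params$progression$npi
  f <- params$progression$npi_rescale
  nb <- npi_base / f
  nr <- npi_recent / f
  inner <- co[["intercept"]] + co[["donepezil"]] * donepezil +
    co[["weeks"]] * weeks + co[["npi_base"]] * nb +
    co[["npi_base_weeks"]] * nb * weeks + co[["npi_recent"]] * nr +
    co[["white"]] * white + co[["black"]] * black +
    co[["psy_med"]] * psy_med + co[["mmse_base"]] * mmse_base +
    co[["mmse_recent"]] * mmse_recent + delta
  inner * f
}

#' ADL change from baseline
#'
#' Change-from-baseline equation for basic activities of daily living
#' (standardised 0-100, 0 best). `adl_prev` is the most recently computed
#' ADL value.
#'
#' @inheritParams change_npi
#' @param adl_base,adl_prev Baseline and most recent ADL (0-100).
#' @param age Patient age at baseline (years).
#' @return Change from baseline ADL (caller clamps `adl_base + change`).
#' @export
change_adl <- function(donepezil, weeks, adl_base, adl_prev, mmse_base,
                       mmse_recent, age, psy_med, black, delta = 0,
                       params = default_parameters()) {
  if (any(weeks < 0)) stop("invalid argument: weeks must be >= 0")
  co <- params$progression$adl
  co[["intercept"]] + co[["donepezil"]] * donepezil +
    co[["weeks"]] * weeks + co[["adl_base"]] * adl_base +
    co[["adl_prev"]] * adl_prev + co[["mmse_base"]] * mmse_base +
    co[["age"]] * age + co[["psy_med"]] * psy_med + co[["black"]] * black +
    co[["mmse_recent"]] * mmse_recent + delta
}

#' IADL change from baseline
#'
#' Change-from-baseline equation for instrumental activities of daily living
#' (standardised 0-100, 0 best). Includes a treatment-by-time interaction
#' and terms in the patient's current ADL; the `IADL x Weeks` interaction
#' uses the baseline IADL.
#'
#' @inheritParams change_adl
#' @param iadl_base,iadl_prev Baseline and most recent IADL (0-100).
#' @param adl_recent Most recent (newly updated) ADL.
#' @param male Patient-sex dummy (1 = male).
#' @return Change from baseline IADL (caller clamps `iadl_base + change`).
#' @export
change_iadl <- function(donepezil, weeks, iadl_base, iadl_prev, male,
                        mmse_base, mmse_recent, adl_base, adl_recent,
                        delta = 0, params = default_parameters()) {
  if (any(weeks < 0)) stop("invalid argument: weeks must be >= 0")
  co <- params$progression$iadl
  co[["intercept"]] + co[["donepezil"]] * donepezil +
    co[["weeks"]] * weeks + co[["donepezil_weeks"]] * donepezil * weeks +
    co[["iadl_base"]] * iadl_base +
    co[["iadl_base_weeks"]] * iadl_base * weeks +
    co[["iadl_prev"]] * iadl_prev + co[["male"]] * male +
    co[["mmse_base"]] * mmse_base + co[["mmse_recent"]] * mmse_recent +
    co[["adl_base"]] * adl_base + co[["adl_recent"]] * adl_recent + delta
}

#' Linear benefit-loss taper after treatment discontinuation
#'
#' Patients who stop treatment lose all treatment-attributable score
#' differences linearly over the following `taper_weeks` (default 6): the
#' remaining offset is `offset * max(0, 1 - weeks_since_stop / taper_weeks)`,
#' exactly zero at and beyond the taper window.
#'
#' @param offset Accumulated treatment-attributable offset (score units).
#' @param weeks_since_stop Weeks since discontinuation (vectorised).
#' @param taper_weeks Taper window in weeks.
#' @return Remaining offset(s).
#' @export
#' @examples
#' apply_discontinuation_taper(2, 3)  # 1
apply_discontinuation_taper <- function(offset, weeks_since_stop,
                                        taper_weeks = 6) {
  if (taper_weeks <= 0) stop("invalid argument: taper_weeks must be positive")
  if (any(weeks_since_stop < 0))
    stop("invalid argument: weeks_since_stop must be >= 0")
  offset * pmax(0, 1 - weeks_since_stop / taper_weeks)
}

#' Differences and ratios of placebo-adjusted 6-month effects
#'
#' Compares per-outcome placebo-adjusted 6-month effects for two drugs;
#' used to derive memantine's treatment coefficients from donepezil's in the
#' absence of head-to-head data.
#'
#' @param donepezil_6mo,memantine_6mo Named numeric vectors of per-outcome
#'   effects (same names).
#' @return A list with elements `difference` (memantine - donepezil) and
#'   `ratio` (memantine / donepezil), both named.
#' @export
#' @examples
#' memantine_effect_table(c(mmse = 1.16), c(mmse = 0.48))$difference  # -0.68
memantine_effect_table <- function(donepezil_6mo, memantine_6mo) {
  stopifnot(identical(names(donepezil_6mo), names(memantine_6mo)))
  if (any(donepezil_6mo == 0))
    stop("undefined ratio: zero donepezil effect for outcome ",
         paste(names(donepezil_6mo)[donepezil_6mo == 0], collapse = ", "))
  list(difference = memantine_6mo - donepezil_6mo,
       ratio = memantine_6mo / donepezil_6mo)
}
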