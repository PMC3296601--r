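#' Convert cumulative discontinuation risks into piecewise-constant hazards
#'
#' The persistence inputs are printed as cumulative risks over months 0-3
#' and 0-6, an interval risk over months 6-12, and an annual risk after
#' month 12; interval risks are read as probabilities conditional on still
#' being on treatment at the interval start (the standard actuarial
#' reading, which makes the 0-6-month column consistent with the 0-3-month
#' one). Each interval's hazard is `-log(1 - risk) / width`, giving a
#' continuous survival function.
#'
#' @param schedule Named vector with elements `m0_3`, `m0_6`, `m6_12`,
#'   `annual_after_12` (risks in [0, 1)).
#' @return A list of class `piecewise_hazard` with `breaks` (years,
#'   `c(0, 0.25, 0.5, 1, Inf)`) and `hazard` (per year, one per interval).
#' @export
#' @examples
#' hz <- hazards_from_cumulative_risks(default_parameters()$persistence$donepezil)
#' hz$hazard[1]  # -log(1 - 0.051) / 0.25
hazards_from_cumulative_risks <- function(schedule) {
  needed <- c("m0_3", "m0_6", "m6_12", "annual_after_12")
  stopifnot(all(needed %in% names(schedule)))
  if (any(schedule < 0) || any(schedule >= 1))
    stop("invalid argument: risks must lie in [0, 1)")
  if (schedule[["m0_6"]] < schedule[["m0_3"]])
    stop("invalid argument: cumulative risk at 6 months below 3-month risk")
  # Conditional interval risks on (0,3], (3,6], (6,12] months, then annual.
  r1 <- schedule[["m0_3"]]
  r2 <- max(0, 1 - (1 - schedule[["m0_6"]]) / (1 - schedule[["m0_3"]]))
  r3 <- schedule[["m6_12"]]
  r4 <- schedule[["annual_after_12"]]
  h <- list(
    breaks = c(0, 0.25, 0.5, 1, Inf),
    hazard = c(-log(1 - r1) / 0.25,
               -log(1 - r2) / 0.25,
               -log(1 - r3) / 0.5,
               -log(1 - r4))
  )
  class(h) <- c("piecewise_hazard", "list")
  h
}

#' Cumulative hazard of a piecewise-constant hazard function
#'
#' @param hz A `piecewise_hazard`.
#' @param t Time(s) in years.
#' @param hr Constant hazard-ratio multiplier (default 1).
#' @return Cumulative hazard at `t`.
#' @export
cumulative_hazard <- function(hz, t, hr = 1) {
  k <- length(hz$hazard)
  H <- numeric(length(t))
  for (j in seq_len(k)) {
    lo <- hz$breaks[j]
    hi <- hz$breaks[j + 1]
    H <- H + hz$hazard[j] * pmax(0, pmin(t, hi) - lo)
  }
  hr * H
}

#' Sample a treatment-discontinuation time by inverse-CDF
#'
#' Inverts the survival function of the piecewise-exponential
#' discontinuation model at a uniform draw: the patient discontinues at the
#' first time the cumulative risk reaches `u`. With a hazard ratio of 1 the
#' sampled times reproduce the printed cumulative risks in distribution.
#' Draws beyond the total risk mass at any finite time return `Inf`.
#'
#' The same uniform draw is shared across the treatment arms of one patient
#' and inverted against each arm's own schedule (common random numbers).
#'
#' @param u Uniform draw(s) in (0, 1). Vectorised.
#' @param hz A `piecewise_hazard`.
#' @param hr Constant hazard-ratio multiplier (default 1, the published
#'   Cox coefficients on time-updated MMSE not being available).
#' @return Discontinuation time(s) in years (possibly `Inf`).
#' @export
#' @examples
#' hz <- hazards_from_cumulative_risks(default_parameters()$persistence$donepezil)
#' sample_discontinuation_time(0.03, hz)  # ~0.1455 years
sample_discontinuation_time <- function(u, hz, hr = 1) {
  if (any(u <= 0 | u >= 1))
    stop("invalid argument: u must lie strictly in (0, 1)")
  target <- -log(1 - u) / hr
  k <- length(hz$hazard)
  width <- diff(hz$breaks)
  seg <- hz$hazard * width            # cumulative hazard per interval
  seg[is.nan(seg)] <- 0               # 0 * Inf for zero-hazard final interval
  cumseg <- c(0, cumsum(seg))
  t <- rep(Inf, length(u))
  for (j in seq_len(k)) {
    in_j <- target > cumseg[j] & target <= cumseg[j + 1] & hz$hazard[j] > 0
    t[in_j] <- hz$breaks[j] + (target[in_j] - cumseg[j]) / hz$hazard[j]
  }
  # Draws inside an earlier interval with infinite remaining mass are
  # covered above; anything past all finite mass stays Inf.
  t
}

#' Evaluate a clinical stopping rule
#'
#' Stopping rules are checked at scheduled reassessment events while the
#' patient is on treatment:
#' * `"none"` never fires.
#' * `"mmse_below_10"` fires when the current MMSE is strictly below 10.
#' * `"deterioration_any_scale_after_6mo"` fires from 26 weeks onwards when
#'   any scale is worse than baseline (MMSE below, or NPI/ADL/IADL above,
#'   its baseline value).
#'
#' @param rule Rule name.
#' @param mmse,npi,adl,iadl Current scores (vectorised).
#' @param mmse0,npi0,adl0,iadl0 Baseline scores.
#' @param t_weeks Weeks since baseline.
#' @return Logical: stop treatment now.
#' @export
evaluate_stopping_rule <- function(rule, mmse, npi, adl, iadl,
                                   mmse0, npi0, adl0, iadl0, t_weeks) {
  switch(rule,
    none = rep(FALSE, length(mmse)),
    mmse_below_10 = mmse < 10,
    deterioration_any_scale_after_6mo =
      (t_weeks >= 26) &
        (mmse < mmse0 | npi > npi0 | adl > adl0 | iadl > iadl0),
    stop("unknown stopping rule: ", rule)
  )
}
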