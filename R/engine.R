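#' @title Discrete event simulation engine
#' @description Internal step logic and the per-arm cohort runner. Patients
#'   advance on a fixed reassessment grid (default every 6 weeks) from
#'   baseline to the horizon; death and treatment discontinuation occur in
#'   continuous time within intervals and truncate the affected accruals
#'   exactly. Updates are applied in the order MMSE, NPI, ADL, IADL, each
#'   later equation seeing the newly updated MMSE (and the IADL equation the
#'   newly updated ADL). Costs and utilities accrue over each interval at
#'   the start-of-interval state (left-endpoint rule).
#' @name engine
NULL

# Remaining-benefit multiplier at time t (weeks since baseline) for a
# patient whose treatment stops at t_stop_w: 1 while on treatment, linear
# taper to 0 over taper_weeks afterwards.
.taper_mult <- function(t, t_stop_w, taper_weeks) {
  ifelse(t <= t_stop_w, 1, pmax(0, 1 - (t - t_stop_w) / taper_weeks))
}

# One update step for vectors of patients in a single arm.
# st: list(mmse, npi, adl, iadl, prev_rate, o_mmse, t_stop_w)
# pt: cohort columns incl. race dummies; mmse_year_ago: vector for PrevRate.
.step_scores <- function(st, pt, arm, t0, t1, mmse_year_ago, params) {
  prog <- params$progression
  taper <- prog$taper_weeks
  scale <- arm_effect_scale(arm, params)
  dtw <- t1 - t0

  # --- MMSE: annual-rate equation; treatment term integrated exactly over
  # the on-treatment part of the interval; accumulated treatment offset
  # o_mmse tapers after discontinuation.
  base_rate <- mmse_annual_rate(st$mmse, st$prev_rate, pt$age,
                                pt$delta_mmse, 0, prog$mmse)
  w_hi <- pmin(t1, st$t_stop_w)
  dr <- prog$donepezil_rate
  br <- prog$donepezil_rate_breaks
  seg <- function(lo, hi) pmax(0, pmin(w_hi, hi) - pmax(t0, lo))
  i_tx <- scale[["mmse"]] *
    (dr[["early"]] * seg(0, br[["early_weeks"]]) +
       dr[["late"]] * seg(br[["early_weeks"]], br[["late_weeks"]])) / .WEEKS_PER_YEAR
  o_new <- st$o_mmse + i_tx
  d_tx <- o_new * .taper_mult(t1, st$t_stop_w, taper) -
    st$o_mmse * .taper_mult(t0, st$t_stop_w, taper)
  mmse_new <- pmin(pmax(st$mmse + base_rate * dtw / .WEEKS_PER_YEAR + d_tx, 0), 30)

  # --- NPI / ADL / IADL: change-from-baseline equations evaluated without
  # the treatment dummy; the direct treatment term (frozen at its
  # stop-time value once off treatment) is added with the taper multiplier.
  r1 <- .taper_mult(t1, st$t_stop_w, taper)
  w_eff <- pmin(t1, st$t_stop_w)   # weeks at which the direct term is frozen

  ch_npi <- change_npi(0, t1, pt$npi0, st$npi, pt$white, pt$black,
                       pt$psy_med, pt$mmse0, mmse_new, pt$delta_npi, params)
  d_npi <- scale[["npi"]] * prog$npi[["donepezil"]] * prog$npi_rescale * r1
  npi_new <- pmin(pmax(pt$npi0 + ch_npi + d_npi, 0), 144)

  ch_adl <- change_adl(0, t1, pt$adl0, st$adl, pt$mmse0, mmse_new, pt$age,
                       pt$psy_med, pt$black, pt$delta_adl, params)
  d_adl <- scale[["adl"]] * prog$adl[["donepezil"]] * r1
  adl_new <- pmin(pmax(pt$adl0 + ch_adl + d_adl, 0), 100)

  ch_iadl <- change_iadl(0, t1, pt$iadl0, st$iadl, pt$male, pt$mmse0,
                         mmse_new, pt$adl0, adl_new, pt$delta_iadl, params)
  d_iadl <- scale[["iadl"]] *
    (prog$iadl[["donepezil"]] + prog$iadl[["donepezil_weeks"]] * w_eff) * r1
  iadl_new <- pmin(pmax(pt$iadl0 + ch_iadl + d_iadl, 0), 100)

  prev_rate_new <- (mmse_new - mmse_year_ago) /
    ((t1 - pmax(0, t1 - .WEEKS_PER_YEAR)) / .WEEKS_PER_YEAR)

  list(mmse = mmse_new, npi = npi_new, adl = adl_new, iadl = iadl_new,
       prev_rate = prev_rate_new, o_mmse = o_new, t_stop_w = st$t_stop_w)
}

# Interval accrual at the start-of-interval state over [t0_w, te_w] weeks
# (te_w already truncated at death/horizon), returned as named list of
# per-patient increments.
.accrue <- function(st, pt, arm, t0_w, te_w, params, rate) {
  tau0 <- t0_w / .WEEKS_PER_YEAR
  taue <- pmax(te_w, t0_w) / .WEEKS_PER_YEAR
  du <- taue - tau0
  df <- discounted_integral(tau0, taue, rate)

  care_rate <- monthly_care_cost(st$mmse, params) * 12
  f_inst <- institutionalized_fraction(st$mmse, params)
  cg_min <- caregiver_minutes_per_day(st$mmse, st$npi, st$adl, st$iadl,
                                      pt$cg_age, pt$cg_male, pt$male,
                                      pt$psy_med, params)
  cg_rate <- cg_min * .DAYS_PER_YEAR * params$costs$caregiver_hour / 60
  u_p <- patient_utility(st$mmse, st$npi, f_inst, pt$lives_with_cg, params)
  u_c <- caregiver_utility(st$mmse, st$npi, st$adl, st$iadl, pt$cg_age,
                           pt$cg_male, pt$age, pt$psy_med, params)

  # Drug + monitoring accrue over the on-treatment part of the interval.
  tx_end <- pmin(taue, st$t_stop_w / .WEEKS_PER_YEAR)
  du_tx <- pmax(0, tx_end - tau0)
  df_tx <- discounted_integral(tau0, pmax(tau0, tx_end), rate)
  drug_rate <- params$costs$drug_daily[[arm]] * .DAYS_PER_YEAR
  mon_rate <- params$costs$monitoring_quarterly * 4

  th <- params$thresholds
  list(
    drug_undisc = drug_rate * du_tx,        drug_disc = drug_rate * df_tx,
    monitoring_undisc = mon_rate * du_tx,   monitoring_disc = mon_rate * df_tx,
    care_undisc = care_rate * du,           care_disc = care_rate * df,
    caregiver_cost_undisc = cg_rate * du,   caregiver_cost_disc = cg_rate * df,
    years_mmse_above = (st$mmse > th[["mmse"]]) * du,
    years_npi_below = (st$npi < th[["npi"]]) * du,
    years_adl_below = (st$adl < th[["adl"]]) * du,
    years_iadl_below = (st$iadl < th[["iadl"]]) * du,
    years_institution = f_inst * du,
    caregiver_time_years = cg_min / 1440 * du,
    qaly_patient_undisc = u_p * du,         qaly_patient_disc = u_p * df,
    qaly_caregiver_undisc = u_c * du,       qaly_caregiver_disc = u_c * df
  )
}

# Precompute cohort covariate list used by the stepper.
.patient_covariates <- function(cohort) {
  list(age = cohort$age, male = cohort$male,
       white = as.numeric(cohort$race == "White"),
       black = as.numeric(cohort$race == "Black"),
       psy_med = cohort$psy_med, mmse0 = cohort$mmse0, npi0 = cohort$npi0,
       adl0 = cohort$adl0, iadl0 = cohort$iadl0, cg_age = cohort$cg_age,
       cg_male = cohort$cg_male, lives_with_cg = cohort$lives_with_cg,
       delta_mmse = cohort$delta_mmse, delta_npi = cohort$delta_npi,
       delta_adl = cohort$delta_adl, delta_iadl = cohort$delta_iadl)
}

#' Simulate one treatment arm for a whole cohort
#'
#' Runs the discrete event simulation for every patient in `cohort` under a
#' single treatment arm, using the supplied per-patient uniform draws for
#' death and discontinuation. Sharing `draws` across calls with different
#' arms implements common random numbers: death times are identical across
#' arms, and each arm inverts the same discontinuation draw against its own
#' risk schedule.
#'
#' @param cohort An `adesim_cohort`.
#' @param arm `"none"`, `"donepezil"` or `"memantine"`.
#' @param params Model parameters ([default_parameters()]).
#' @param config Simulation configuration ([default_config()]).
#' @param draws List with elements `u_death` and `u_disc`, numeric vectors
#'   of length `nrow(cohort)` in (0, 1).
#' @return A data.frame of class `arm_outcomes`, one row per patient, with
#'   undiscounted and discounted cost components, QALYs, life-years and
#'   time-in-state tallies; cohort fingerprint, arm and weights attached as
#'   attributes.
#' @export
simulate_arm <- function(cohort, arm, params = default_parameters(),
                         config = default_config(), draws) {
  stopifnot(inherits(cohort, "adesim_cohort"))
  arm <- match.arg(arm, c("none", "donepezil", "memantine"))
  n <- nrow(cohort)
  stopifnot(length(draws$u_death) == n, length(draws$u_disc) == n)
  rate <- config$discount_rate
  horizon_w <- config$horizon_years * .WEEKS_PER_YEAR

  death_y <- sample_death_time(cohort$age, cohort$male, draws$u_death,
                               params$mortality)
  death_w <- death_y * .WEEKS_PER_YEAR
  life_years <- pmin(death_y, config$horizon_years)

  if (arm == "none") {
    t_stop_w <- rep(0, n)
    disc_y <- rep(Inf, n)
  } else {
    hz <- hazards_from_cumulative_risks(params$persistence[[arm]])
    hrc <- params$persistence$hr_coef
    hr <- exp(hrc[["mmse"]] * cohort$mmse0)   # baseline-covariate hook; 1 by default
    disc_y <- sample_discontinuation_time(draws$u_disc, hz, hr)
    t_stop_w <- pmin(disc_y, config$treatment_duration_years) * .WEEKS_PER_YEAR
  }

  pt <- .patient_covariates(cohort)
  st <- list(mmse = cohort$mmse0, npi = cohort$npi0, adl = cohort$adl0,
             iadl = cohort$iadl0, prev_rate = rep(0, n),
             o_mmse = rep(0, n), t_stop_w = t_stop_w)

  grid <- seq(0, horizon_w, by = config$update_interval_weeks)
  if (grid[length(grid)] < horizon_w) grid <- c(grid, horizon_w)
  hist_mmse <- matrix(0, n, length(grid))
  hist_mmse[, 1] <- st$mmse

  acc <- NULL
  for (k in 2:length(grid)) {
    t0 <- grid[k - 1]
    t1 <- grid[k]
    te <- pmin(t1, pmax(death_w, t0))
    inc <- .accrue(st, pt, arm, t0, te, params, rate)
    acc <- if (is.null(acc)) inc else Map(`+`, acc, inc)

    # PrevRate reference: MMSE one year before t1 (linear interpolation on
    # the stored grid; baseline value before the first year has elapsed).
    target <- max(0, t1 - .WEEKS_PER_YEAR)
    j <- findInterval(target, grid)
    m_ago <- if (grid[j] == target || j == length(grid)) hist_mmse[, j] else {
      w <- (target - grid[j]) / (grid[j + 1] - grid[j])
      (1 - w) * hist_mmse[, j] + w * hist_mmse[, j + 1]
    }

    st <- .step_scores(st, pt, arm, t0, t1, m_ago, params)
    hist_mmse[, k] <- st$mmse

    if (arm != "none" && config$stopping_rule != "none") {
      firing <- evaluate_stopping_rule(config$stopping_rule, st$mmse, st$npi,
                                       st$adl, st$iadl, pt$mmse0, pt$npi0,
                                       pt$adl0, pt$iadl0, t1) &
        st$t_stop_w > t1 & death_w > t1
      st$t_stop_w[firing] <- t1
    }
  }

  out <- data.frame(id = cohort$id, life_years = life_years,
                    death_years = death_y,
                    discontinuation_years = disc_y, acc)
  out$direct_cost_undisc <- out$drug_undisc + out$monitoring_undisc +
    out$care_undisc
  out$direct_cost_disc <- out$drug_disc + out$monitoring_disc + out$care_disc
  out$total_cost_undisc <- out$direct_cost_undisc + out$caregiver_cost_undisc
  out$total_cost_disc <- out$direct_cost_disc + out$caregiver_cost_disc
  structure(out,
            class = c("arm_outcomes", "data.frame"),
            arm = arm,
            weights = cohort$weight,
            cohort_hash = rlang::hash(list(as.data.frame(cohort), config)))
}

#' Run the simulation for several arms with common random numbers
#'
#' Draws one death uniform and one discontinuation uniform per patient from
#' `seed`, then simulates each requested arm on the identical cohort with
#' those shared draws.
#'
#' @param cohort An `adesim_cohort`.
#' @param arms Character vector of arms to simulate.
#' @param params,config Model parameters and configuration.
#' @param seed Integer seed for the per-patient uniform draws.
#' @return Named list of `arm_outcomes` data.frames, one per arm.
#' @export
#' @examples
#' cohort <- generate_cohort(population_spec(n = 20, random_seed = 3))
#' res <- run_simulation(cohort, c("none", "donepezil"), seed = 1)
#' aggregate_outcomes(res$donepezil)["qaly_patient_disc"]
run_simulation <- function(cohort, arms = c("none", "donepezil", "memantine"),
                           params = default_parameters(),
                           config = default_config(), seed = 1L) {
  set.seed(seed)
  n <- nrow(cohort)
  draws <- list(u_death = runif(n), u_disc = runif(n))
  setNames(lapply(arms, function(a)
    simulate_arm(cohort, a, params, config, draws)), arms)
}

#' Simulate the three arms for a single patient
#'
#' Clones one baseline patient into the no-treatment, donepezil and
#' memantine arms. The clones share the baseline attributes, random
#' intercepts, death time and discontinuation draw, so survival is identical
#' across arms by construction.
#'
#' @param baseline A one-row `adesim_cohort`.
#' @param config,params Configuration and parameters.
#' @param draws Optional list(`u_death`, `u_disc`) of single uniforms;
#'   drawn from `seed` if omitted.
#' @param seed Seed used when `draws` is missing.
#' @return Named list of one-row `arm_outcomes` for the three arms.
#' @export
run_patient_triplet <- function(baseline, config = default_config(),
                                params = default_parameters(),
                                draws = NULL, seed = 1L) {
  stopifnot(nrow(baseline) == 1)
  if (is.null(draws)) {
    set.seed(seed)
    draws <- list(u_death = runif(1), u_disc = runif(1))
  }
  setNames(lapply(c("none", "donepezil", "memantine"), function(a)
    simulate_arm(baseline, a, params, config, draws)),
    c("none", "donepezil", "memantine"))
}

#' Advance a patient state by one interval
#'
#' Single-step access to the engine's update rule, mainly for inspection and
#' testing: applies the MMSE, NPI, ADL and IADL updates in order over
#' `[t_weeks, t_weeks + dt_weeks]` and returns the new state together with
#' the interval's accrual record (computed from the start-of-interval
#' state).
#'
#' @param state List with `t_weeks`, `mmse`, `npi`, `adl`, `iadl`,
#'   `prev_rate`, `o_mmse`, `t_stop_w` (use `Inf` while on treatment with no
#'   stop scheduled, `0` for a never-treated patient), and `mmse_year_ago`
#'   (MMSE one year back, or at baseline).
#' @param baseline A one-row `adesim_cohort`.
#' @param arm Treatment arm.
#' @param dt_weeks Interval length in weeks (> 0).
#' @param params,config Parameters and configuration.
#' @return List with `state` (advanced) and `accrual` (named increments).
#' @export
#' @examples
#' b <- generate_cohort(population_spec(n = 1, random_seed = 1))
#' s <- list(t_weeks = 0, mmse = 20, npi = 20, adl = 30, iadl = 40,
#'           prev_rate = 0, o_mmse = 0, t_stop_w = 0, mmse_year_ago = 20)
#' advance_patient(s, b, "none", 52)$state$mmse
advance_patient <- function(state, baseline, arm, dt_weeks,
                            params = default_parameters(),
                            config = default_config()) {
  stopifnot(dt_weeks > 0, nrow(baseline) == 1)
  pt <- .patient_covariates(baseline)
  t0 <- state$t_weeks
  t1 <- t0 + dt_weeks
  acc <- .accrue(state, pt, arm, t0, t1, params, config$discount_rate)
  st <- .step_scores(state, pt, arm, t0, t1, state$mmse_year_ago, params)
  st$t_weeks <- t1
  list(state = st, accrual = acc)
}

#' Weighted cohort-mean outcomes
#'
#' Aggregates per-patient arm outcomes into per-patient averages using the
#' cohort sampling weights (or explicit weights). The cost identities
#' (total = direct + caregiver time; direct = drug + monitoring + care) are
#' preserved by linearity.
#'
#' @param outcomes An `arm_outcomes` data.frame.
#' @param weights Nonnegative weights; defaults to the cohort weights
#'   attached to `outcomes`.
#' @return Named numeric vector of weighted means over all outcome columns.
#' @export
aggregate_outcomes <- function(outcomes, weights = attr(outcomes, "weights")) {
  if (is.null(weights)) weights <- rep(1, nrow(outcomes))
  if (any(weights < 0) || sum(weights) == 0)
    stop("invalid argument: weights must be nonnegative and not all zero")
  cols <- setdiff(names(outcomes),
                  c("id", "death_years", "discontinuation_years"))
  v <- vapply(cols, function(cl)
    sum(outcomes[[cl]] * weights) / sum(weights), numeric(1))
  setNames(v, cols)
}

#' @export
print.arm_outcomes <- function(x, ...) {
  agg <- aggregate_outcomes(x)
  cat("<arm outcomes> arm =", attr(x, "arm"), "|", nrow(x), "patients\n")
  cat(sprintf("  life-years %.3f | QALY(patient) %.3f | direct cost EUR %.0f | total cost EUR %.0f (discounted)\n",
              agg[["life_years"]], agg[["qaly_patient_disc"]],
              agg[["direct_cost_disc"]], agg[["total_cost_disc"]]))
  invisible(x)
}
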