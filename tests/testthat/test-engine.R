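# Independent scalar reimplementation of the per-patient simulation for one
# arm, written with literal coefficients and plain loops. Used as an oracle
# for the vectorised engine.
scalar_oracle <- function(b, arm, u_death, u_disc, horizon_y = 1, dt = 6,
                          duration_y = Inf) {
  delta_d <- log1p(0.03)
  pv <- function(a0, a1) (exp(-delta_d * a0) - exp(-delta_d * a1)) / delta_d
  care <- function(m) if (m >= 25) 184 else if (m >= 20) 593 else
    if (m >= 15) 1275 else if (m >= 10) 1958 else 2981
  clamp <- function(x, lo, hi) min(max(x, lo), hi)

  p <- default_parameters()
  death_y <- sample_death_time(b$age, b$male, u_death, p$mortality)
  if (arm == "none") {
    t_stop <- 0
  } else {
    hz <- hazards_from_cumulative_risks(p$persistence[[arm]])
    t_stop <- min(sample_discontinuation_time(u_disc, hz), duration_y) * 52
  }
  sc <- switch(arm,
    none = c(mmse = 0, npi = 0, adl = 0, iadl = 0),
    donepezil = c(mmse = 1, npi = 1, adl = 1, iadl = 1),
    memantine = c(mmse = 0.48 / 1.16, npi = -2.76 / -2.40,
                  adl = -2.35 / -4.44, iadl = -2.35 / -4.44))
  tap <- function(t) if (t <= t_stop) 1 else max(0, 1 - (t - t_stop) / 6)
  drug_daily <- c(none = 0, donepezil = 4.20, memantine = 3.83)[[arm]]

  white <- as.numeric(b$race == "White")
  black <- as.numeric(b$race == "Black")
  m <- b$mmse0; npi <- b$npi0; adl <- b$adl0; iadl <- b$iadl0
  pr <- 0; o <- 0
  acc <- numeric(0)
  add <- function(acc, nm, v) { acc[nm] <- (if (nm %in% names(acc)) acc[[nm]] else 0) + v; acc }

  grid <- seq(0, horizon_y * 52, by = dt)
  if (grid[length(grid)] < horizon_y * 52) grid <- c(grid, horizon_y * 52)
  death_w <- death_y * 52
  for (k in 2:length(grid)) {
    t0 <- grid[k - 1]; t1 <- grid[k]
    te <- min(t1, max(death_w, t0))
    a0 <- t0 / 52; ae <- te / 52
    du <- ae - a0; df <- pv(a0, ae)
    f_inst <- clamp(0.6435 - 0.0286 * m, 0, 1)
    cg_min <- max(0, 76.41 + 1.8 * b$cg_age + 93.02 * b$cg_male +
                    85.56 * b$male - 6.47 * m + 0.58 * npi + 2.66 * adl +
                    2.61 * iadl + 20.55 * b$psy_med)
    u_p <- min(1, 0.408 + 0.010 * m - 0.004 * npi - 0.159 * f_inst +
                 0.051 * b$lives_with_cg)
    u_c <- min(1, 0.90 - 0.003 * b$cg_age + 0.03 * b$cg_male +
                 0.001 * b$age + 0.00 * m - 0.001 * npi - 0.001 * adl -
                 0.0004 * iadl - 0.01 * b$psy_med)
    tx_end <- min(ae, t_stop / 52)
    du_tx <- max(0, tx_end - a0); df_tx <- pv(a0, max(a0, tx_end))

    acc <- add(acc, "drug_undisc", drug_daily * 365.25 * du_tx)
    acc <- add(acc, "drug_disc", drug_daily * 365.25 * df_tx)
    acc <- add(acc, "monitoring_undisc", 53.47 * 4 * du_tx)
    acc <- add(acc, "monitoring_disc", 53.47 * 4 * df_tx)
    acc <- add(acc, "care_undisc", care(m) * 12 * du)
    acc <- add(acc, "care_disc", care(m) * 12 * df)
    cg_rate <- cg_min * 365.25 * 5.21 / 60
    acc <- add(acc, "caregiver_cost_undisc", cg_rate * du)
    acc <- add(acc, "caregiver_cost_disc", cg_rate * df)
    acc <- add(acc, "years_mmse_above", (m > 10) * du)
    acc <- add(acc, "years_npi_below", (npi < 28) * du)
    acc <- add(acc, "years_adl_below", (adl < 50) * du)
    acc <- add(acc, "years_iadl_below", (iadl < 50) * du)
    acc <- add(acc, "years_institution", f_inst * du)
    acc <- add(acc, "caregiver_time_years", cg_min / 1440 * du)
    acc <- add(acc, "qaly_patient_undisc", u_p * du)
    acc <- add(acc, "qaly_patient_disc", u_p * df)
    acc <- add(acc, "qaly_caregiver_undisc", u_c * du)
    acc <- add(acc, "qaly_caregiver_disc", u_c * df)

    # State update: MMSE first, then NPI, ADL, IADL seeing the new MMSE.
    rate <- -5.4663 - 0.4299 * min(m, 9) - 0.0042 * max(0, min(m - 9, 9)) +
      0.1415 * max(0, min(m - 18, 12)) - 0.0791 * pr + 0.0747 * b$age +
      b$delta_mmse
    w_hi <- min(t1, t_stop)
    i_tx <- sc[["mmse"]] *
      (6.16 * max(0, min(w_hi, 20) - max(t0, 0)) +
         2.47 * max(0, min(w_hi, 52) - max(t0, 20))) / 52
    o_new <- o + i_tx
    d_tx <- o_new * tap(t1) - o * tap(t0)
    m_new <- clamp(m + rate * (t1 - t0) / 52 + d_tx, 0, 30)

    ch_npi <- (5.74 + 0.03 * t1 - 0.59 * (b$npi0 / 1.44) -
                 0.001 * (b$npi0 / 1.44) * t1 + 0.24 * (npi / 1.44) -
                 1.74 * white - 3.82 * black + 2.34 * b$psy_med +
                 0.12 * b$mmse0 - 0.22 * m_new + b$delta_npi) * 1.44
    npi_new <- clamp(b$npi0 + ch_npi +
                       sc[["npi"]] * (-0.64) * 1.44 * tap(t1), 0, 144)

    ch_adl <- 1.35 + 0.06 * t1 - 0.79 * b$adl0 + 0.71 * adl +
      0.12 * b$mmse0 + 0.09 * b$age + 0.81 * b$psy_med - 3.05 * black -
      0.49 * m_new + b$delta_adl
    adl_new <- clamp(b$adl0 + ch_adl + sc[["adl"]] * (-0.81) * tap(t1),
                     0, 100)

    w_eff <- min(t1, t_stop)
    ch_iadl <- 1.27 + 0.17 * t1 - 0.84 * b$iadl0 + 0.002 * b$iadl0 * t1 +
      0.84 * iadl - 0.67 * b$male + 0.20 * b$mmse0 - 0.28 * m_new -
      0.16 * b$adl0 + 0.18 * adl_new + b$delta_iadl
    iadl_new <- clamp(b$iadl0 + ch_iadl +
                        sc[["iadl"]] * (0.63 - 0.06 * w_eff) * tap(t1),
                      0, 100)

    pr <- (m_new - b$mmse0) / ((t1 - max(0, t1 - 52)) / 52)
    m <- m_new; npi <- npi_new; adl <- adl_new; iadl <- iadl_new
    o <- o_new
  }
  acc["life_years"] <- min(death_y, horizon_y)
  acc
}

test_that("a one-year untreated step reproduces the hand-traced MMSE", {
  b <- make_patient()
  s <- list(t_weeks = 0, mmse = 20, npi = 20, adl = 30, iadl = 40,
            prev_rate = 0, o_mmse = 0, t_stop_w = 0, mmse_year_ago = 20)
  out <- advance_patient(s, b, "none", 52)
  expect_equal(out$state$mmse, 20 - 3.4877, tolerance = 1e-9)
  expect_equal(out$state$prev_rate, -3.4877, tolerance = 1e-9)
  # The interval accrues at the start state: 52 weeks in the 20-24 band.
  expect_equal(out$accrual$care_undisc, 593 * 12, tolerance = 1e-9)
})

test_that("the vectorised engine matches the scalar reimplementation", {
  cfg <- default_config(horizon_years = 1)
  b1 <- make_patient(male = 0, race = "Black", psy_med = 1,
                     lives_with_cg = 0, mmse0 = 22, npi0 = 30, adl0 = 25,
                     iadl0 = 35, delta_mmse = 0.5, delta_npi = -1,
                     delta_adl = 0.3, delta_iadl = -0.2)
  b2 <- make_patient()
  cases <- expand.grid(arm = c("none", "donepezil", "memantine"),
                       u_death = c(0.01, 0.98), pat = 1:2,
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    b <- if (cs$pat == 1) b1 else b2
    draws <- list(u_death = cs$u_death, u_disc = 0.2)
    got <- simulate_arm(b, cs$arm, config = cfg, draws = draws)
    want <- scalar_oracle(b, cs$arm, cs$u_death, 0.2,
                          duration_y = cfg$treatment_duration_years)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-9,
                   label = paste(cs$arm, "u_death", cs$u_death, nm))
    expect_equal(got$direct_cost_undisc,
                 want[["drug_undisc"]] + want[["monitoring_undisc"]] +
                   want[["care_undisc"]], tolerance = 1e-9)
    expect_equal(got$total_cost_disc,
                 got$direct_cost_disc + got$caregiver_cost_disc,
                 tolerance = 1e-12)
  }
})

test_that("with treatment effects and prices zeroed all arms coincide
           bitwise", {
  co <- generate_cohort(population_spec(n = 200, random_seed = 11))
  p0 <- null_treatment_parameters()
  cfg <- default_config(horizon_years = 5)
  res <- run_simulation(co, c("none", "donepezil", "memantine"),
                        params = p0, config = cfg, seed = 4)
  a <- as.data.frame(res$none)[, outcome_cols(res$none)]
  b <- as.data.frame(res$donepezil)[, outcome_cols(res$donepezil)]
  c_ <- as.data.frame(res$memantine)[, outcome_cols(res$memantine)]
  expect_identical(a, b)
  expect_identical(a, c_)
})

test_that("survival is identical across arms for every patient", {
  co <- generate_cohort(population_spec(n = 100, random_seed = 13))
  res <- run_simulation(co, c("none", "donepezil", "memantine"), seed = 2)
  expect_identical(res$none$death_years, res$donepezil$death_years)
  expect_identical(res$none$death_years, res$memantine$death_years)
  expect_identical(res$none$life_years, res$donepezil$life_years)
  expect_identical(res$none$life_years, res$memantine$life_years)
})

test_that("scores stay inside their scales under repeated extreme steps", {
  b <- make_patient(mmse0 = 2, npi0 = 140, adl0 = 98, iadl0 = 98,
                    delta_mmse = -3, delta_npi = 10, delta_adl = 8,
                    delta_iadl = 8, age = 94)
  s <- list(t_weeks = 0, mmse = 2, npi = 140, adl = 98, iadl = 98,
            prev_rate = 0, o_mmse = 0, t_stop_w = Inf, mmse_year_ago = 2)
  for (k in 1:40) {
    s <- advance_patient(s, b, "donepezil", 6)$state
    s$mmse_year_ago <- 2
    expect_gte(s$mmse, 0); expect_lte(s$mmse, 30)
    expect_gte(s$npi, 0); expect_lte(s$npi, 144)
    expect_gte(s$adl, 0); expect_lte(s$adl, 100)
    expect_gte(s$iadl, 0); expect_lte(s$iadl, 100)
  }
  expect_equal(s$mmse, 0)  # floor reached and held
})

test_that("aggregation takes a weighted mean and validates weights", {
  d <- data.frame(x = c(100, 200))
  expect_equal(aggregate_outcomes(d, weights = c(1, 3))[["x"]], 175)
  expect_equal(aggregate_outcomes(d, weights = c(1, 1))[["x"]], 150)
  expect_error(aggregate_outcomes(d, weights = c(-1, 1)), "invalid argument")
  expect_error(aggregate_outcomes(d, weights = c(0, 0)), "invalid argument")
  # Audit columns are excluded from aggregation.
  d2 <- data.frame(id = 1:2, death_years = c(1, Inf),
                   discontinuation_years = c(Inf, 2), x = c(1, 3))
  expect_identical(names(aggregate_outcomes(d2, weights = c(1, 1))), "x")
})

test_that("halving the reassessment cadence changes mean QALYs by under
           one percent", {
  co <- generate_cohort(population_spec(n = 150, random_seed = 21))
  res6 <- run_simulation(co, "donepezil",
                         config = default_config(update_interval_weeks = 6),
                         seed = 8)
  res3 <- run_simulation(co, "donepezil",
                         config = default_config(update_interval_weeks = 3),
                         seed = 8)
  q6 <- aggregate_outcomes(res6$donepezil)[["qaly_patient_disc"]]
  q3 <- aggregate_outcomes(res3$donepezil)[["qaly_patient_disc"]]
  expect_lt(abs(q6 - q3) / q3, 0.01)
})

test_that("a one-year treatment-duration cap bounds the drug cost", {
  co <- generate_cohort(population_spec(n = 100, random_seed = 31))
  cfg <- default_config(treatment_duration_years = 1)
  res <- run_simulation(co, "donepezil", config = cfg, seed = 5)
  expect_true(all(res$donepezil$drug_undisc <= 4.20 * 365.25 + 1e-9))
  # And treatment indeed ends within the first year for everyone.
  expect_true(all(res$donepezil$monitoring_undisc <= 53.47 * 4 + 1e-9))
})

test_that("donepezil slows MMSE decline relative to no treatment while on
           treatment", {
  b <- make_patient()
  s0 <- list(t_weeks = 0, mmse = 20, npi = 20, adl = 30, iadl = 40,
             prev_rate = 0, o_mmse = 0, mmse_year_ago = 20)
  s_none <- c(s0, list(t_stop_w = 0))
  s_don <- c(s0, list(t_stop_w = Inf))
  for (k in 1:8) {
    s_none <- advance_patient(s_none, b, "none", 6)$state
    s_none$mmse_year_ago <- 20
    s_don <- advance_patient(s_don, b, "donepezil", 6)$state
    s_don$mmse_year_ago <- 20
    expect_gt(s_don$mmse, s_none$mmse)
  }
})
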