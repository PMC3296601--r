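test_that("incremental comparison classifies the four plane cases and the
           self comparison", {
  co <- generate_cohort(population_spec(n = 60, random_seed = 17))
  res <- run_simulation(co, c("none", "donepezil"), seed = 3)

  self <- compare_arms(res$none, res$none)
  expect_equal(self$delta_cost, 0)
  expect_equal(self$delta_qaly, 0)
  expect_identical(self$status, "indeterminate")
  expect_true(is.na(self$icer))

  cmp <- compare_arms(res$none, res$donepezil, perspective = "societal")
  expect_identical(cmp$reference, "none")
  expect_identical(cmp$intervention, "donepezil")
  expect_true(cmp$status %in% c("dominant", "dominated", "icer",
                                "lower-cost-lower-QALY", "indeterminate"))
  # QALY decomposition is internally consistent.
  expect_equal(cmp$delta_qaly,
               cmp$delta_qaly_all[["patient"]] +
                 cmp$delta_qaly_all[["caregiver"]], tolerance = 1e-12)
  # Direct perspective excludes caregiver-time costs, so its cost delta
  # differs from the societal one by the caregiver-cost delta.
  cmp_d <- compare_arms(res$none, res$donepezil, perspective = "direct")
  ag_n <- aggregate_outcomes(res$none)
  ag_i <- aggregate_outcomes(res$donepezil)
  expect_equal(cmp$delta_cost - cmp_d$delta_cost,
               ag_i[["caregiver_cost_disc"]] - ag_n[["caregiver_cost_disc"]],
               tolerance = 1e-9)
})

test_that("outcomes from different cohorts or configs cannot be compared", {
  co1 <- generate_cohort(population_spec(n = 10, random_seed = 1))
  co2 <- generate_cohort(population_spec(n = 10, random_seed = 2))
  r1 <- run_simulation(co1, "none", seed = 1)$none
  r2 <- run_simulation(co2, "donepezil", seed = 1)$donepezil
  expect_error(compare_arms(r1, r2), "incomparable arms")
  r3 <- run_simulation(co1, "donepezil",
                       config = default_config(horizon_years = 5),
                       seed = 1)$donepezil
  expect_error(compare_arms(r1, r3), "incomparable arms")
})

test_that("the 25%-of-mean rule gives the frozen standard errors", {
  expect_equal(se_from_mean(100), 12.755336423116, tolerance = 1e-12)
  expect_equal(se_from_mean(0), 0)
  expect_equal(se_from_mean(-4.44), 0.566336937186, tolerance = 1e-12)
})

test_that("beta moment matching recovers the frozen shape parameters and
           the drawn mean", {
  # mean 0.4, se 0.1 -> k = 0.4*0.6/0.01 - 1 = 23 -> shapes (9.2, 13.8).
  m <- 0.4; s <- 0.1
  k <- m * (1 - m) / s^2 - 1
  expect_equal(m * k, 9.2, tolerance = 1e-12)
  expect_equal((1 - m) * k, 13.8, tolerance = 1e-12)
  set.seed(55)
  draws <- replicate(4000, adesim:::.draw_proportion(m, s))
  expect_true(all(draws > 0 & draws < 1))
  expect_lt(abs(mean(draws) - m), 3 * s / sqrt(4000))
  expect_lt(abs(sd(draws) - s), 0.01)
  # Infeasible (se too large for the mean): clipped-normal fallback warns.
  expect_warning(adesim:::.draw_proportion(0.5, 0.6), "clipped normal")
})

test_that("PSA parameter draws are reproducible and leave unlisted
           parameters untouched", {
  p <- default_parameters()
  d1 <- draw_psa_parameters(p, seed = 9, replicate = 3)
  d2 <- draw_psa_parameters(p, seed = 9, replicate = 3)
  expect_identical(d1, d2)
  d3 <- draw_psa_parameters(p, seed = 9, replicate = 4)
  expect_false(identical(d1$caregiver_time, d3$caregiver_time))
  # Progression base coefficients are not in the spec and stay fixed.
  expect_identical(d1$progression$mmse, p$progression$mmse)
  expect_identical(d1$mortality, p$mortality)
  # The rebuilt 0-6-month risk keeps every drawn schedule monotone.
  for (r in 1:25) {
    d <- draw_psa_parameters(p, seed = 123, replicate = r)
    expect_gte(d$persistence$donepezil[["m0_6"]],
               d$persistence$donepezil[["m0_3"]])
    expect_gte(d$persistence$memantine[["m0_6"]],
               d$persistence$memantine[["m0_3"]])
  }
})

test_that("zero-variance PSA collapses onto the base-case comparison", {
  co <- generate_cohort(population_spec(n = 40, random_seed = 23))
  spec0 <- default_psa_spec()
  spec0$se <- 0
  psa <- run_psa(co, n_replications = 5, spec = spec0, seed = 6)
  base <- run_simulation(co, c("none", "donepezil"), seed = 6)
  cmp <- compare_arms(base$none, base$donepezil, perspective = "societal")
  soc <- psa$replicates[psa$replicates$perspective == "societal", ]
  expect_equal(soc$delta_cost, rep(cmp$delta_cost, 5), tolerance = 1e-9)
  expect_equal(soc$delta_qaly, rep(cmp$delta_qaly, 5), tolerance = 1e-9)
  # All mass in a single quadrant, shares summing to one.
  expect_equal(max(psa$quadrant_shares["societal", ]), 1)
  expect_equal(rowSums(psa$quadrant_shares), c(direct = 1, societal = 1),
               tolerance = 1e-12)
})

test_that("PSA summaries are internally consistent and reproducible", {
  co <- generate_cohort(population_spec(n = 30, random_seed = 29))
  psa1 <- run_psa(co, n_replications = 8, seed = 14,
                  lambda_grid = c(0, 30000))
  psa2 <- run_psa(co, n_replications = 8, seed = 14,
                  lambda_grid = c(0, 30000))
  expect_identical(psa1$replicates, psa2$replicates)
  expect_equal(rowSums(psa1$quadrant_shares), c(direct = 1, societal = 1),
               tolerance = 1e-12)
  # CEAC at lambda = 0 is the probability of being cost-saving.
  soc <- psa1$replicates[psa1$replicates$perspective == "societal", ]
  p0 <- psa1$ceac$probability[psa1$ceac$lambda == 0 &
                                psa1$ceac$perspective == "societal"]
  expect_equal(p0, mean(soc$delta_cost < 0), tolerance = 1e-12)
  expect_error(run_psa(co, n_replications = 0), "invalid argument")
})

test_that("quadrant classification covers all sign patterns", {
  expect_identical(classify_quadrant(-1000, 0.1), "lower_right")
  expect_identical(classify_quadrant(1000, 0.1), "upper_right")
  expect_identical(classify_quadrant(-1000, -0.1), "lower_left")
  expect_identical(classify_quadrant(1000, -0.1), "upper_left")
  expect_identical(classify_quadrant(0, 0.1), "axes")
  expect_identical(classify_quadrant(c(-1, 1), c(1, 1)),
                   c("lower_right", "upper_right"))
  expect_error(classify_quadrant(NA_real_, 1), "is.finite")
})

test_that("scenario machinery: base is a no-op, names are exhaustive and
           transforms change what they claim", {
  p <- default_parameters()
  cfg <- default_config()
  sc <- apply_scenario("base", p, cfg)
  expect_identical(sc$params, p)
  expect_identical(sc$config, cfg)
  expect_error(apply_scenario("bogus"), "unknown scenario")
  for (nm in scenario_names()) {
    sc <- apply_scenario(nm, p, cfg)
    expect_named(sc, c("params", "config"))
  }
  expect_equal(apply_scenario("care_cost_down_25")$params$costs$care_monthly$cost,
               p$costs$care_monthly$cost * 0.75)
  expect_equal(apply_scenario("horizon_5y")$config$horizon_years, 5)
  expect_equal(apply_scenario("no_discontinuation")$params$persistence$donepezil,
               p$persistence$donepezil * 0)
  expect_identical(apply_scenario("stop_mmse_lt_10")$config$stopping_rule,
                   "mmse_below_10")

  # run_scenario("base") reproduces the direct comparison.
  co <- generate_cohort(population_spec(n = 30, random_seed = 37))
  cmp_s <- run_scenario("base", co, seed = 2)
  res <- run_simulation(co, c("none", "donepezil"), seed = 2)
  cmp_b <- compare_arms(res$none, res$donepezil, perspective = "societal")
  expect_equal(cmp_s$delta_cost, cmp_b$delta_cost, tolerance = 1e-12)
  expect_equal(cmp_s$delta_qaly, cmp_b$delta_qaly, tolerance = 1e-12)

  # No discontinuation keeps everyone on treatment: drug costs rise.
  res_nd <- run_simulation(co, "donepezil",
                           apply_scenario("no_discontinuation")$params,
                           seed = 2)
  expect_gt(aggregate_outcomes(res_nd$donepezil)[["drug_undisc"]],
            aggregate_outcomes(res$donepezil)[["drug_undisc"]])
})
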