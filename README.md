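# adesim

Patient-level discrete event simulation for the cost-effectiveness of
antidementia drug treatment in Alzheimer's disease, comparing **no
treatment**, **donepezil** and **memantine** on a common synthetic cohort.

Each simulated patient carries four correlated disease scales — MMSE
(cognition, 0–30, higher better), NPI (behaviour, 0–144, higher worse),
ADL and IADL (function, 0–100, 0 best) — plus demographics, caregiver
attributes and per-scale random intercepts. Disease trajectories follow
published mixed-model progression equations (an annual-rate equation for
MMSE, change-from-baseline equations for NPI/ADL/IADL); treatment adds
time-limited offsets that taper away over six weeks after
discontinuation. Treatment persistence is a piecewise-exponential
time-to-event model; survival is a calibrated Gompertz residual-life law
with a dementia hazard multiplier, drawn once per patient and shared
across arms (common random numbers). Costs are 2008 German tariffs
(severity-banded care costs, drug and monitoring costs while on
treatment, caregiver time at a shadow wage); utilities are regression
based for patient and caregiver. Results are incremental discounted costs
and QALYs from the payer ("direct") or societal perspective, with one-way
scenarios and probabilistic sensitivity analysis (PSA).

See the methods vignette (`vignettes/methods.Rmd`) for model structure,
assumptions, numerical choices and limitations.

## Worked example

```r
library(adesim)

# 1. Synthetic cohort: 1000 patients, baseline MMSE 10-26.
cohort <- generate_cohort(population_spec(n = 1000, random_seed = 20120101))

# 2. Simulate all three arms over 10 years with common random numbers.
res <- run_simulation(cohort, c("none", "donepezil", "memantine"),
                      seed = 20120101)

# 3. Cohort-mean outcomes per arm.
round(t(sapply(res, function(r) aggregate_outcomes(r)[
  c("life_years", "qaly_patient_disc", "direct_cost_disc",
    "total_cost_disc")])), 3)

# 4. Incremental comparison.
compare_arms(res$none, res$donepezil, perspective = "societal")
```

With the seeds above, this run prints (discounted, per patient):

| arm       | life-years | patient QALYs | direct cost (€) | total cost (€) |
|-----------|-----------:|--------------:|----------------:|---------------:|
| none      | 4.913      | 1.697         | 114 196         | 200 783        |
| donepezil | 4.913      | 1.819         | 108 692         | 191 360        |
| memantine | 4.913      | 1.762         | 115 072         | 199 748        |

and the comparison (combined patient + caregiver QALYs):

```
<comparison> donepezil vs none (societal perspective, combined QALYs)
  dCost  EUR -9423
  dQALY  0.1476
  status dominant
```

From the direct (payer) perspective the same run gives dCost −€5 504 at
the same dQALY, i.e. donepezil dominates from both perspectives on this
synthetic cohort; donepezil also dominates memantine (dCost −€8 388,
dQALY 0.0669). Life-years are identical across arms by construction —
treatment affects quality of life and costs, not survival.

PSA, scenarios and plotting:

```r
psa <- run_psa(cohort, "none", "donepezil", n_replications = 200, seed = 1)
psa$quadrant_shares          # shares of replicates per CE-plane quadrant
psa$ceac                     # acceptability curve
plot_ce_plane(psa)           # requires ggplot2

run_scenario("stop_mmse_lt_10", cohort, seed = 1)   # one-way scenario
```

## Command-line use

```sh
Rscript inst/cli/adesim.R compare --n 500 --seed 1 --out results/
Rscript inst/cli/adesim.R simulate --n 500 --seed 1 --out results/ --scenario horizon_5y
Rscript inst/cli/adesim.R psa --n 500 --seed 1 --replicates 200 --out results/psa.csv
```

Configuration and all model parameters can be overridden from a YAML file
(`--config`; see `load_config()` / `save_config()`).

## Testing

The package ships a testthat (edition 3) suite: per-module unit tests with
frozen hand-computed oracle values, property-based tests (term-by-term
equation oracles, inverse-CDF round-trips, clamping and monotonicity
invariants, bitwise null-treatment equivalence, cost identities), and an
acceptance file with one test per acceptance criterion.

```r
testthat::test_dir("tests/testthat", package = "adesim",
                   load_package = "installed")
```

One acceptance test is intentionally red: the published worked-example
value for the marginal NPI treatment effect (−1.27) does not follow from
the published equation coefficients, which give
1.44 × (−0.64 − 0.22) = −1.2384 → −1.24 to two decimals. The test asserts
the published value so the discrepancy stays visible; everything else in
that equation is verified term-by-term at 1e-9.

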