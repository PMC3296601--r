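---
title: "Model structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`adesim` is a patient-level discrete event microsimulation for the
cost-effectiveness of antidementia drug treatment in Alzheimer's disease,
comparing three strategies on a common synthetic cohort: no antidementia
treatment, donepezil, and memantine. Each simulated patient carries four
disease scales — MMSE (cognition, 0–30, higher is better), NPI (behaviour,
0–144, higher is worse), and ADL/IADL (basic and instrumental function,
0–100, 0 is best) — plus demographics, caregiver attributes and per-scale
random intercepts. Disease trajectories, costs (2008 German euros) and
utilities are accrued per patient; arms are compared as incremental
discounted costs and quality-adjusted life years (QALYs) from either the
payer ("direct") or the societal perspective, the latter adding informal
caregiver time valued at a shadow wage.

Three sources of randomness exist per patient: the baseline draw (cohort
generation), a death-time uniform, and a treatment-discontinuation uniform.
The two uniforms are shared across arms (common random numbers), so
survival is identical in all arms by construction and paired differences
are low-variance.

# Disease progression

Progression is driven by four mixed-model change equations evaluated at
scheduled reassessments:

* **MMSE** follows an *annual rate of change* equation, piecewise-linear in
  the previous MMSE (segments 0–9, 9–18, 18–30), in the previous year's
  rate of change, and in age, plus a patient random intercept. Treatment
  adds a rate offset of 6.16 points/year during the first 20 weeks on
  drug and 2.47 points/year over weeks 20–52; beyond one year continued
  treatment only maintains accumulated gains (offset 0).
* **NPI, ADL and IADL** follow *change-from-baseline* equations in elapsed
  weeks, the baseline and most recent scores, demographics, psychotropic
  co-medication, and the baseline and most recent MMSE. The NPI equation
  operates internally on a normalised 0–100 scale (raw / 1.44); inputs and
  outputs of `change_npi()` stay on the raw 0–144 scale.

Updates within a reassessment are ordered MMSE → NPI → ADL → IADL, each
later equation seeing the newly updated MMSE (and the IADL equation the
newly updated ADL); every score is clamped to its scale after updating.

Memantine has no published head-to-head coefficients, so its treatment
terms are the donepezil coefficients scaled per domain by the ratio of
placebo-adjusted 6-month effects (MMSE 0.48/1.16, NPI −2.76/−2.40,
function −2.35/−4.44, the functional ratio shared by ADL and IADL); see
`memantine_effect_table()`.

## Treatment benefit bookkeeping and the post-discontinuation taper

Treatment benefits are lost linearly over the six weeks following
discontinuation. Operationally the engine keeps, per patient:

* an accumulated MMSE *offset* equal to the exact integral of the piecewise
  treatment rate term over time on drug (`o_mmse`), and
* the *level* treatment terms of the NPI/ADL/IADL equations (for IADL the
  time-varying `donepezil × weeks` term is frozen at the stop time).

All of these are multiplied by a taper factor that is 1 while on treatment
and declines linearly to 0 over the six weeks after stopping. This makes
"benefits lost over six weeks" well-defined for both the rate-based MMSE
equation and the level-based equations, and makes the null-treatment limit
exact: with all treatment coefficients and drug prices set to zero, the
three arms produce bitwise-identical outcomes (a tested invariant).

# Treatment persistence and stopping rules

Discontinuation is modelled as a piecewise-exponential time-to-event
distribution constructed from cumulative risks at 3 and 6 months, an
interval risk over months 6–12, and an annual risk thereafter
(`hazards_from_cumulative_risks()`). Interval risks are read as
conditional on still being on treatment at the interval start, and each
interval's hazard is `-log(1 - risk) / width`. Discontinuation times are
drawn by closed-form inverse-CDF from the shared per-patient uniform, so
the same draw maps to each arm's own schedule. Optional clinical stopping
rules (`mmse_below_10`, `deterioration_any_scale_after_6mo`) are evaluated
at reassessments and cap the time on treatment, as does the configurable
maximum treatment duration.

# Mortality

Survival uses a Gompertz residual-life law with sex-specific level
parameters, a common shape, and a dementia hazard multiplier of 2. The
closed-form inverse of the conditional survival function converts the
shared uniform into a death time. The parameters
(`default_parameters()$mortality`) were calibrated so that a 60 %-female
cohort aged 75 has a 10-year truncated life expectancy of 4.89 years,
reproducing the level of period-life-table-based survival with a doubled
hazard; the calibration is pinned by a quadrature test. This is a
parametric stand-in for a life-table construction: it matches truncated
mean survival by design, not the full age pattern of a specific national
life table.

# Economics

* **Care costs** are a step function of MMSE severity (five bands from
  €184/month at MMSE ≥ 25 to €2 981/month below 10), applied regardless of
  care setting.
* **Drug costs** are €4.20 (donepezil) and €3.83 (memantine) per day,
  accrued only while on treatment, as is quarterly monitoring (€53.47).
* **Caregiver time** comes from a linear regression on caregiver age/sex,
  patient sex, the four scales and psychotropic co-medication, floored at
  zero and valued at €5.21/hour; an optional MMSE-band table can replace
  the regression.
* **Institutionalisation** is carried as an expected fraction
  `max(0, 0.6435 − 0.0286·MMSE)` rather than as individual transitions.
* **Utilities**: patient utility is linear in MMSE, NPI, the
  institutionalised fraction and living-with-caregiver (capped at 1);
  caregiver utility is linear in caregiver and patient attributes with a
  zero MMSE coefficient. QALYs are reported for patient, caregiver and
  combined.
* **Discounting** is continuous at the annual-equivalent force
  `δ = ln(1 + 0.03)`, so a unit-rate stream over `[t0, t1]` has present
  value `(e^{−δ t0} − e^{−δ t1})/δ`.

# Synthetic cohort generator

No patient-level trial data ship with the package; cohorts are synthetic
(`generate_cohort()`). Correlation among age and the four baseline scales
is induced by a Gaussian copula on a configurable latent correlation
matrix (default: mild negative age–MMSE and MMSE–function correlations,
positive function–function correlation). Marginals are truncated normals:
age TN(75, 8) on [50, 95], MMSE TN(18, 5) restricted to the requested
range, and NPI/ADL/IADL with conditional means increasing linearly in
(30 − MMSE). Sixty percent of patients are female; race, psychotropic
medication, caregiver attributes and living situation are drawn from
configurable categorical margins. Per-scale random intercepts are normal
with trial-plausible spreads. `reweight_to_marginals()` post-stratifies to
external age–sex margins; `filter_subgroup()` selects MMSE subgroups.

The generator reproduces the *kind* of baseline structure a trial cohort
has (ranges, plausible central tendencies, severity-linked correlation and
caregiver burden), but it is not calibrated to any proprietary baseline
dataset; headline cost and QALY levels therefore carry generator
uncertainty, which is why distribution-level results are checked
directionally rather than against point values (see the test suite).

# Numerical choices

* **Model year**: 52 weeks; drug costs are annualised with 365.25 days.
* **Reassessment grid**: fixed 6-week cadence to the horizon (the horizon
  endpoint is appended if off-grid). A halved cadence changes mean
  discounted QALYs by well under 1 % (tested).
* **Accrual rule**: costs and utilities accrue at the start-of-interval
  state (left endpoint). Death and discontinuation truncate the affected
  accruals in continuous time within the interval; zero-width intervals
  contribute exactly zero, so no masking is needed.
* **Previous-year MMSE rate**: the rate covariate uses the MMSE 52 weeks
  before the evaluation time, linearly interpolated on the stored history
  grid; before one year has elapsed, annualisation is anchored at
  baseline, and the covariate starts at 0.
* **Treatment rate integral**: the 20/52-week breakpoints of the MMSE
  treatment term are integrated exactly within each interval, so cadence
  does not bias the accumulated benefit.
* **Deterministic inverses**: discontinuation and death times use
  closed-form inverse-CDFs (no root finding in the hot path).

# Sensitivity analyses

`apply_scenario()` provides one-way scenarios (care costs, caregiver time,
institutionalisation, utilities or treatment effects scaled by 0.75;
stopping rules; 5-year horizon; treatment-duration caps; zero or doubled
discontinuation; an MMSE-band caregiver-time table). `run_psa()` performs
probabilistic sensitivity analysis: continuous parameters are drawn from
normal distributions and proportions from moment-matched betas, with
standard errors defaulting to the 25 %-of-mean rule
(`SE = 0.25·|mean| / 1.96`); the 0–6-month discontinuation risk is rebuilt
from the drawn 0–3-month risk to keep schedules monotone. Replicates reuse
the same patient-level draws (common random numbers), and results are
summarised as cost-effectiveness-plane quadrant shares and an
acceptability curve.

# Design decisions and open-question resolutions

* Plain S3 on data.frames: the data are tabular per-patient records, not
  sequence/range/assay structures, so no specialised container classes are
  used.
* The `NPI_base × weeks` interaction uses the baseline NPI (not the
  recent), matching its naming; the analogous IADL interaction uses
  baseline IADL.
* Monitoring is billed quarterly while on treatment only.
* The institutionalised fraction is capped at 1 (no harder cap by
  default); `institutionalization_cap` is configurable.
* "Doubled discontinuation" doubles each interval risk (capped below 1)
  before hazard conversion.
* Problem sizes used in validation: cohorts of 100–1 000 patients, 10-year
  horizon, 6-week cadence (≈ 87 updates), PSA with 200 replicates; a
  1 000-patient two-arm 10-year run takes well under a minute on one CPU.

# Limitations

* Mortality is treatment-independent and not score-dependent; the model
  cannot express survival gains or severity-linked excess mortality.
* Institutionalisation is an expected fraction, so person-level nursing
  home transitions (and their cost dynamics) are not simulated.
* The memantine effect scaling assumes proportionality across scales from
  6-month aggregate effects.
* Cost inputs are 2008 German tariffs; no inflation or jurisdiction
  adjustment is applied.
* The synthetic generator is a structural stand-in for trial baselines;
  absolute cost/QALY levels should be read as model-consistent, not as
  re-estimates of any published cohort.
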