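# Shared fixtures built in code.

# A one-row cohort with fully controlled attributes (random intercepts zero
# unless stated), for deterministic hand-traceable runs.
make_patient <- function(age = 75, male = 1, race = "White", psy_med = 0,
                         mmse0 = 20, npi0 = 20, adl0 = 30, iadl0 = 40,
                         cg_age = 70, cg_male = 0, lives_with_cg = 1,
                         weight = 1, delta_mmse = 0, delta_npi = 0,
                         delta_adl = 0, delta_iadl = 0, id = 1L) {
  df <- data.frame(id = id, age = age, male = male,
                   race = factor(race, levels = c("White", "Black", "Other")),
                   psy_med = psy_med, mmse0 = mmse0, npi0 = npi0,
                   adl0 = adl0, iadl0 = iadl0, cg_age = cg_age,
                   cg_male = cg_male, lives_with_cg = lives_with_cg,
                   weight = weight, delta_mmse = delta_mmse,
                   delta_npi = delta_npi, delta_adl = delta_adl,
                   delta_iadl = delta_iadl)
  class(df) <- c("adesim_cohort", "data.frame")
  df
}

# Stack several make_patient() rows into one cohort.
make_cohort <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(seq_along(rows), function(i) {
    rows[[i]]$id <- i
    as.data.frame(rows[[i]])
  }))
  class(df) <- c("adesim_cohort", "data.frame")
  df
}

# Parameters for a placebo-like comparison: treatment affects nothing and
# costs nothing, so all three arms must coincide exactly.
null_treatment_parameters <- function() {
  p <- default_parameters()
  p$progression$donepezil_rate[] <- 0
  p$progression$npi[["donepezil"]] <- 0
  p$progression$adl[["donepezil"]] <- 0
  p$progression$iadl[["donepezil"]] <- 0
  p$progression$iadl[["donepezil_weeks"]] <- 0
  p$costs$drug_daily[] <- 0
  p$costs$monitoring_quarterly <- 0
  p
}

# Outcome columns that describe results (excludes audit columns that carry
# arm-specific treatment metadata).
outcome_cols <- function(x) {
  setdiff(names(x), c("id", "death_years", "discontinuation_years"))
}
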