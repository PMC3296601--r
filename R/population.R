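#' Specify a synthetic baseline population
#'
#' Describes the joint distribution from which synthetic baseline cohorts are
#' drawn. The generator uses a latent Gaussian copula over (age, MMSE, NPI,
#' ADL, IADL): a multivariate-normal latent vector supplies both the
#' cross-attribute correlation and the marginal quantiles, which are mapped
#' through truncated-normal marginals. The behavioural and functional scores
#' additionally have conditional means that are linear in (30 - MMSE), so
#' that behaviour and function worsen as cognition falls. Binary attributes
#' (sex, psychiatric-medication use, lives-with-caregiver) and race are drawn
#' independently; caregiver age is normal around (patient age - 5).
#'
#' Per-patient random intercepts for the four progression equations are drawn
#' at generation time (normal, mean zero) so that all treatment arms of one
#' patient share the same individual progression pattern.
#'
#' @param n Number of patients.
#' @param age_mean,age_sd,age_range Truncated-normal age marginal (years).
#' @param prop_female Probability the patient is female.
#' @param race_probs Named probabilities for White/Black/Other; must sum to 1.
#' @param prop_psy_med Probability of psychiatric-medication use at baseline.
#' @param prop_lives_with_cg Probability the patient lives with the caregiver.
#' @param mmse_mean,mmse_sd Truncated-normal MMSE marginal.
#' @param mmse_range Closed interval to which baseline MMSE is restricted.
#' @param score_slopes Named vector (`npi`, `adl`, `iadl`): increase in the
#'   conditional mean per point of (30 - MMSE).
#' @param score_sds Named vector of conditional standard deviations.
#' @param latent_cor Correlation matrix on the latent scale, dimensions
#'   5x5 ordered (age, mmse, npi, adl, iadl). Must be symmetric positive
#'   semidefinite.
#' @param cg_age_offset,cg_age_sd Caregiver age: normal around patient age +
#'   offset, clamped to 18-100.
#' @param prop_cg_opposite_sex Probability the caregiver's sex is opposite
#'   the patient's.
#' @param delta_sds Named vector of random-intercept standard deviations for
#'   the four progression equations (score units; MMSE's applies to the
#'   annual rate). Defaults are 10% of each scale's range.
#' @param random_seed Integer seed; identical seeds give identical cohorts.
#' @return A list of class `population_spec`.
#' @export
#' @examples
#' spec <- population_spec(n = 100, random_seed = 1)
#' cohort <- generate_cohort(spec)
population_spec <- function(n,
                            age_mean = 75, age_sd = 8, age_range = c(50, 95),
                            prop_female = 0.60,
                            race_probs = c(White = 0.80, Black = 0.10, Other = 0.10),
                            prop_psy_med = 0.25,
                            prop_lives_with_cg = 0.70,
                            mmse_mean = 18, mmse_sd = 5,
                            mmse_range = c(0, 30),
                            score_slopes = c(npi = 1.5, adl = 2.0, iadl = 2.5),
                            score_sds = c(npi = 12, adl = 12, iadl = 15),
                            latent_cor = default_latent_cor(),
                            cg_age_offset = -5, cg_age_sd = 10,
                            prop_cg_opposite_sex = 0.70,
                            delta_sds = c(mmse = 3.0, npi = 14.4,
                                          adl = 10, iadl = 10),
                            random_seed = 1L) {
  if (n < 1) stop("invalid argument: n must be >= 1")
  if (abs(sum(race_probs) - 1) > 1e-8)
    stop("invalid argument: race_probs must sum to 1")
  probs <- c(prop_female, prop_psy_med, prop_lives_with_cg,
             prop_cg_opposite_sex, race_probs)
  if (any(probs < 0 | probs > 1))
    stop("invalid argument: probabilities must lie in [0, 1]")
  if (mmse_range[1] > mmse_range[2] || mmse_range[1] < 0 || mmse_range[2] > 30)
    stop("invalid argument: mmse_range must be within [0, 30]")
  latent_cor <- as.matrix(latent_cor)
  if (nrow(latent_cor) != 5 || ncol(latent_cor) != 5 ||
      max(abs(latent_cor - t(latent_cor))) > 1e-10)
    stop("invalid argument: latent_cor must be a symmetric 5x5 matrix")
  ev <- eigen(latent_cor, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("invalid argument: latent_cor is not positive semidefinite")
  spec <- as.list(environment())
  class(spec) <- c("population_spec", "list")
  spec
}

#' Default latent correlation matrix
#'
#' Modest residual correlations on the latent scale, ordered
#' (age, mmse, npi, adl, iadl). Most of the MMSE-to-score dependence is
#' carried by the conditional means; the copula adds residual association,
#' strongest between the two functional scales.
#'
#' @return A 5x5 correlation matrix.
#' @export
default_latent_cor <- function() {
  nm <- c("age", "mmse", "npi", "adl", "iadl")
  m <- diag(5)
  dimnames(m) <- list(nm, nm)
  m["age", "mmse"] <- m["mmse", "age"] <- -0.10
  m["mmse", "npi"] <- m["npi", "mmse"] <- -0.20
  m["mmse", "adl"] <- m["adl", "mmse"] <- -0.25
  m["mmse", "iadl"] <- m["iadl", "mmse"] <- -0.25
  m["npi", "adl"] <- m["adl", "npi"] <- 0.20
  m["npi", "iadl"] <- m["iadl", "npi"] <- 0.15
  m["adl", "iadl"] <- m["iadl", "adl"] <- 0.50
  m
}

# Truncated-normal quantile: p in [0,1] -> value in [lo, hi].
qtnorm <- function(p, mean, sd, lo, hi) {
  a <- pnorm(lo, mean, sd)
  b <- pnorm(hi, mean, sd)
  qnorm(a + p * (b - a), mean, sd)
}

#' Generate a synthetic baseline cohort
#'
#' Draws `spec$n` simulated patients with baseline disease scores, caregiver
#' profiles and per-equation random intercepts. All scores are clamped to
#' their legal ranges; MMSE is restricted to `spec$mmse_range` by marginal
#' truncation. Identical seeds yield identical cohorts.
#'
#' @param spec A [population_spec()].
#' @return A data.frame of class `adesim_cohort`, one row per patient, with
#'   columns `id`, `age`, `male`, `race`, `psy_med`, `mmse0`, `npi0`, `adl0`,
#'   `iadl0`, `cg_age`, `cg_male`, `lives_with_cg`, `weight`, and
#'   `delta_mmse`, `delta_npi`, `delta_adl`, `delta_iadl`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n
  set.seed(spec$random_seed)

  # Latent MVN via Cholesky-like factor robust to semidefinite matrices.
  eg <- eigen(spec$latent_cor, symmetric = TRUE)
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 5)
  z <- matrix(rnorm(n * 5), n, 5) %*% t(L)
  u <- pnorm(z)

  age <- qtnorm(u[, 1], spec$age_mean, spec$age_sd,
                spec$age_range[1], spec$age_range[2])
  mmse0 <- qtnorm(u[, 2], spec$mmse_mean, spec$mmse_sd,
                  max(spec$mmse_range[1], 0), min(spec$mmse_range[2], 30))
  sev <- 30 - mmse0
  npi0 <- qtnorm(u[, 3], spec$score_slopes[["npi"]] * sev,
                 spec$score_sds[["npi"]], 0, 144)
  adl0 <- qtnorm(u[, 4], spec$score_slopes[["adl"]] * sev,
                 spec$score_sds[["adl"]], 0, 100)
  iadl0 <- qtnorm(u[, 5], spec$score_slopes[["iadl"]] * sev,
                  spec$score_sds[["iadl"]], 0, 100)

  male <- rbinom(n, 1, 1 - spec$prop_female)
  race <- factor(
    sample(names(spec$race_probs), n, replace = TRUE, prob = spec$race_probs),
    levels = c("White", "Black", "Other"))
  psy_med <- rbinom(n, 1, spec$prop_psy_med)
  lives_with_cg <- rbinom(n, 1, spec$prop_lives_with_cg)
  cg_age <- pmin(pmax(age + spec$cg_age_offset +
                        rnorm(n, 0, spec$cg_age_sd), 18), 100)
  opposite <- rbinom(n, 1, spec$prop_cg_opposite_sex)
  cg_male <- ifelse(opposite == 1, 1 - male, male)

  cohort <- data.frame(
    id = seq_len(n),
    age = age, male = male, race = race, psy_med = psy_med,
    mmse0 = pmin(pmax(mmse0, 0), 30),
    npi0 = pmin(pmax(npi0, 0), 144),
    adl0 = pmin(pmax(adl0, 0), 100),
    iadl0 = pmin(pmax(iadl0, 0), 100),
    cg_age = cg_age, cg_male = cg_male, lives_with_cg = lives_with_cg,
    weight = rep(1, n),
    delta_mmse = rnorm(n, 0, spec$delta_sds[["mmse"]]),
    delta_npi = rnorm(n, 0, spec$delta_sds[["npi"]]),
    delta_adl = rnorm(n, 0, spec$delta_sds[["adl"]]),
    delta_iadl = rnorm(n, 0, spec$delta_sds[["iadl"]])
  )
  class(cohort) <- c("adesim_cohort", "data.frame")
  cohort
}

#' Restrict a cohort to a baseline MMSE subgroup
#'
#' Retains patients with `mmse_low <= mmse0 <= mmse_high` (inclusive bounds
#' by default; the moderate-severity subgroup compared against memantine uses
#' an exclusive upper bound of 20). Row order is preserved.
#'
#' @param cohort An `adesim_cohort`.
#' @param mmse_low,mmse_high Subgroup bounds on baseline MMSE.
#' @param upper_inclusive If `FALSE`, the upper bound is exclusive.
#' @return The filtered cohort.
#' @export
#' @examples
#' spec <- population_spec(n = 50, random_seed = 7)
#' mild_mod <- filter_subgroup(generate_cohort(spec), 10, 26)
filter_subgroup <- function(cohort, mmse_low, mmse_high,
                            upper_inclusive = TRUE) {
  if (mmse_low > mmse_high)
    stop("invalid argument: mmse_low must be <= mmse_high")
  keep <- cohort$mmse0 >= mmse_low &
    (if (upper_inclusive) cohort$mmse0 <= mmse_high
     else cohort$mmse0 < mmse_high)
  out <- cohort[keep, , drop = FALSE]
  if (nrow(out) == 0)
    stop("empty subgroup: no patients with baseline MMSE in the requested range")
  rownames(out) <- NULL
  out
}

#' Reweight a cohort to target age-band x sex marginals
#'
#' Post-stratification: each patient's weight becomes
#' `target proportion / observed proportion` for their cell, rescaled so the
#' weights sum to the cohort size. Weighted cell proportions then equal the
#' targets exactly for every cell present in the cohort.
#'
#' @param cohort An `adesim_cohort`.
#' @param targets A data.frame with columns `age_min`, `age_max` (bands are
#'   `[age_min, age_max)`), `male` (0/1) and `prop`; proportions must sum
#'   to 1.
#' @return The cohort with updated `weight` column.
#' @export
reweight_to_marginals <- function(cohort, targets) {
  stopifnot(all(c("age_min", "age_max", "male", "prop") %in% names(targets)))
  if (abs(sum(targets$prop) - 1) > 1e-8)
    stop("invalid argument: target proportions must sum to 1")
  n <- nrow(cohort)
  cell <- rep(NA_integer_, n)
  for (j in seq_len(nrow(targets))) {
    in_cell <- cohort$age >= targets$age_min[j] &
      cohort$age < targets$age_max[j] & cohort$male == targets$male[j]
    cell[in_cell] <- j
  }
  if (anyNA(cell))
    stop("invalid argument: some patients fall outside every target cell")
  counts <- tabulate(cell, nbins = nrow(targets))
  infeasible <- which(targets$prop > 0 & counts == 0)
  if (length(infeasible))
    stop("infeasible weighting: target cell with no cohort members ",
         "(age ", targets$age_min[infeasible[1]], "-",
         targets$age_max[infeasible[1]], ", male = ",
         targets$male[infeasible[1]], ")")
  share <- counts / n
  w <- targets$prop[cell] / share[cell]
  cohort$weight <- w * n / sum(w)
  cohort
}

#' Write / read a cohort as CSV
#'
#' One patient per row, stable column order, header row.
#'
#' @param cohort An `adesim_cohort`.
#' @param path File path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns
#'   the cohort.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$race <- factor(df$race, levels = c("White", "Black", "Other"))
  class(df) <- c("adesim_cohort", "data.frame")
  df
}

#' @export
print.adesim_cohort <- function(x, ...) {
  cat("<adesim cohort> ", nrow(x), " patients; mean age ",
      round(mean(x$age), 1), "; ", round(100 * mean(x$male == 0)),
      "% female; baseline MMSE ", round(min(x$mmse0), 1), "-",
      round(max(x$mmse0), 1), "\n", sep = "")
  print(head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("... and", nrow(x) - 4, "more rows\n")
  invisible(x)
}
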