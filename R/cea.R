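#' Incremental cost-effectiveness of one arm versus another
#'
#' Computes incremental discounted costs and QALYs (intervention minus
#' reference) for a chosen perspective and classifies the result on the
#' cost-effectiveness plane: *dominant* (lower cost, more QALYs),
#' *dominated* (higher cost, fewer QALYs), or an ICER in the two
#' off-diagonal cases (the south-west case is reported as
#' `lower-cost-lower-QALY` with its ratio). Both outcome sets must come from
#' the same cohort, configuration and random draws (common random numbers);
#' mismatched cohort fingerprints raise an error.
#'
#' @param reference,intervention `arm_outcomes` from [simulate_arm()] /
#'   [run_simulation()] on the same cohort.
#' @param perspective `"direct"` (GKV/SPV: drug + monitoring + care) or
#'   `"societal"` (direct + caregiver-time costs).
#' @param qaly `"combined"` (patient + caregiver, the headline measure),
#'   `"patient"` or `"caregiver"`.
#' @return A list of class `adesim_comparison` with `delta_cost`,
#'   `delta_qaly` (all three QALY flavours), `status`, `icer`, and the
#'   undiscounted increments.
#' @export
compare_arms <- function(reference, intervention,
                         perspective = c("societal", "direct"),
                         qaly = c("combined", "patient", "caregiver")) {
  perspective <- match.arg(perspective)
  qaly <- match.arg(qaly)
  if (!identical(attr(reference, "cohort_hash"),
                 attr(intervention, "cohort_hash")))
    stop("incomparable arms: outcomes come from different cohorts or configurations")
  ra <- aggregate_outcomes(reference)
  ia <- aggregate_outcomes(intervention)
  cost_col <- if (perspective == "direct") "direct_cost_disc" else "total_cost_disc"
  cost_col_u <- sub("_disc$", "_undisc", cost_col)
  dq_all <- c(
    patient = ia[["qaly_patient_disc"]] - ra[["qaly_patient_disc"]],
    caregiver = ia[["qaly_caregiver_disc"]] - ra[["qaly_caregiver_disc"]]
  )
  dq_all["combined"] <- dq_all[["patient"]] + dq_all[["caregiver"]]
  dc <- ia[[cost_col]] - ra[[cost_col]]
  dq <- dq_all[[qaly]]
  status <- if (dc < 0 && dq > 0) "dominant"
    else if (dc > 0 && dq < 0) "dominated"
    else if (dc == 0 && dq == 0) "indeterminate"
    else if (dc < 0 && dq < 0) "lower-cost-lower-QALY"
    else "icer"
  icer <- if (status %in% c("icer", "lower-cost-lower-QALY") && dq != 0)
    dc / dq else NA_real_
  structure(list(
    reference = attr(reference, "arm"),
    intervention = attr(intervention, "arm"),
    perspective = perspective, qaly_basis = qaly,
    delta_cost = dc, delta_qaly = dq, delta_qaly_all = dq_all,
    delta_cost_undisc = ia[[cost_col_u]] - ra[[cost_col_u]],
    status = status, icer = icer
  ), class = "adesim_comparison")
}

#' @export
print.adesim_comparison <- function(x, ...) {
  cat(sprintf("<comparison> %s vs %s (%s perspective, %s QALYs)\n",
              x$intervention, x$reference, x$perspective, x$qaly_basis))
  cat(sprintf("  dCost  EUR %.0f\n  dQALY  %.4f\n  status %s",
              x$delta_cost, x$delta_qaly, x$status))
  if (!is.na(x$icer)) cat(sprintf(" (ratio EUR %.0f /QALY)", x$icer))
  cat("\n")
  invisible(x)
}

#' Standard error from the 25%-of-mean rule
#'
#' Where a parameter's source standard error is unavailable, 25% of the
#' parameter mean is taken as the half-width of an assumed 95% confidence
#' interval, so `SE = |0.25 * mean| / 1.959964`.
#'
#' @param mean Parameter mean(s).
#' @return Standard error(s).
#' @export
#' @examples
#' se_from_mean(100)  # 12.7553
se_from_mean <- function(mean) {
  abs(0.25 * mean) / qnorm(0.975)
}

#' Default probabilistic sensitivity analysis specification
#'
#' Lists the parameters varied in the PSA with their base means and the
#' distribution rule: continuous parameters are drawn from a normal
#' distribution, proportions from a beta distribution matched to (mean, SE)
#' by the method of moments. Standard errors default to the 25%-of-mean
#' rule ([se_from_mean()]); entries may carry explicit `se` values where a
#' source SE is available. Varied here: the treatment-effect coefficients,
#' care costs by severity, caregiver-time regression, both utility
#' regressions, the institutionalization model, and discontinuation risks.
#'
#' @param params Base parameters.
#' @return A data.frame of class `psa_spec` with columns `path` (a `$`-path
#'   into the parameter list), `name` (element name within the target
#'   vector, or `NA` for scalars), `mean`, `se`, `type`
#'   (`"continuous"`/`"proportion"`).
#' @export
default_psa_spec <- function(params = default_parameters()) {
  rows <- list()
  add <- function(path, name, mean, type = "continuous", se = NA_real_) {
    rows[[length(rows) + 1]] <<- data.frame(
      path = path, name = ifelse(is.na(name), NA_character_, name),
      mean = mean, se = se, type = type, stringsAsFactors = FALSE)
  }
  pr <- params$progression
  add("progression$donepezil_rate", "early", pr$donepezil_rate[["early"]])
  add("progression$donepezil_rate", "late", pr$donepezil_rate[["late"]])
  add("progression$npi", "donepezil", pr$npi[["donepezil"]])
  add("progression$adl", "donepezil", pr$adl[["donepezil"]])
  add("progression$iadl", "donepezil", pr$iadl[["donepezil"]])
  add("progression$iadl", "donepezil_weeks", pr$iadl[["donepezil_weeks"]])
  for (j in seq_len(nrow(params$costs$care_monthly)))
    add("costs$care_monthly$cost", as.character(j),
        params$costs$care_monthly$cost[j])
  for (nm in names(params$caregiver_time))
    add("caregiver_time", nm, params$caregiver_time[[nm]])
  for (nm in names(params$utility_patient))
    add("utility_patient", nm, params$utility_patient[[nm]])
  for (nm in names(params$utility_caregiver))
    add("utility_caregiver", nm, params$utility_caregiver[[nm]])
  add("institutionalization", "intercept",
      params$institutionalization[["intercept"]], type = "proportion")
  add("institutionalization", "mmse_slope",
      params$institutionalization[["mmse_slope"]])
  # The 0-6-month cumulative risk is not varied independently: the draw
  # perturbs the 0-3-month risk and the conditional 3-6-month risk is held
  # at its base value, keeping the schedule monotone (see
  # draw_psa_parameters).
  for (arm in c("donepezil", "memantine"))
    for (nm in setdiff(names(params$persistence[[arm]]), "m0_6"))
      add(paste0("persistence$", arm), nm, params$persistence[[arm]][[nm]],
          type = "proportion")
  spec <- do.call(rbind, rows)
  class(spec) <- c("psa_spec", "data.frame")
  spec
}

# Beta(alpha, beta) by method of moments from (mean, se); falls back to a
# clipped normal with a warning when no beta matches.
.draw_proportion <- function(m, s) {
  if (s == 0) return(m)
  if (m <= 0 || m >= 1 || s^2 >= m * (1 - m)) {
    warning("beta moment-matching infeasible for mean ", signif(m, 4),
            ", se ", signif(s, 4), "; using clipped normal")
    return(min(max(rnorm(1, m, s), 0), 1 - 1e-9))
  }
  k <- m * (1 - m) / s^2 - 1
  stats::rbeta(1, m * k, (1 - m) * k)
}

# Assign `value` at params<path>[[name]] (path is a $-path string; `name`
# indexes into the terminal vector by name, or by position when unnamed).
.assign_param <- function(params, path, name, value) {
  keys <- strsplit(path, "$", fixed = TRUE)[[1]]
  if (!is.na(name)) keys <- c(keys, name)
  setr <- function(x, keys) {
    k <- keys[1]
    idx <- if (!is.null(names(x)) && k %in% names(x)) k
           else suppressWarnings(as.integer(k))
    if (is.na(idx) || (is.integer(idx) && idx > length(x)))
      stop("unknown parameter path element: ", k)
    if (length(keys) == 1) x[[idx]] <- value
    else x[[idx]] <- setr(x[[idx]], keys[-1])
    x
  }
  setr(params, keys)
}

#' Draw one PSA parameter replicate
#'
#' Perturbs the base parameters according to a PSA specification:
#' continuous entries are drawn normal(mean, SE), proportions beta by
#' moment matching; entries with `se = 0` (or not listed) keep their base
#' values. Missing SEs are filled by the 25%-of-mean rule. Replicate `i`
#' under seed `s` is fully reproducible.
#'
#' @param params Base parameters.
#' @param spec A [default_psa_spec()]-style data.frame.
#' @param seed PSA seed.
#' @param replicate Replicate index (>= 1).
#' @return A perturbed parameter list.
#' @export
draw_psa_parameters <- function(params, spec = default_psa_spec(params),
                                seed = 1L, replicate = 1L) {
  stopifnot(replicate >= 1)
  set.seed(seed + 7919L * as.integer(replicate))
  out <- params
  for (j in seq_len(nrow(spec))) {
    m <- spec$mean[j]
    s <- spec$se[j]
    if (is.na(s)) s <- se_from_mean(m)
    v <- if (spec$type[j] == "proportion") .draw_proportion(m, s)
         else rnorm(1, m, s)
    out <- .assign_param(out, spec$path[j], spec$name[j], v)
  }
  # Keep each arm's discontinuation schedule monotone: the 0-6-month
  # cumulative risk is rebuilt from the drawn 0-3-month risk and the base
  # conditional risk over months 3-6.
  for (arm in c("donepezil", "memantine")) {
    base <- params$persistence[[arm]]
    r36 <- 1 - (1 - base[["m0_6"]]) / (1 - base[["m0_3"]])
    out$persistence[[arm]][["m0_6"]] <-
      max(1 - (1 - out$persistence[[arm]][["m0_3"]]) * (1 - r36),
          out$persistence[[arm]][["m0_3"]])
  }
  out
}

#' Classify a point on the cost-effectiveness plane
#'
#' Quadrants follow the usual convention with incremental QALYs on the
#' horizontal axis and incremental costs on the vertical axis:
#' `lower_right` = dominant (more QALYs, lower cost), `upper_right` = more
#' QALYs at extra cost, `lower_left` = fewer QALYs and lower cost,
#' `upper_left` = dominated. Points on an axis are classified `"axes"`.
#'
#' @param dcost,dqaly Incremental cost(s) and QALY(s). Vectorised.
#' @return Character vector of quadrant labels.
#' @export
#' @examples
#' classify_quadrant(-1000, 0.1)  # "lower_right"
classify_quadrant <- function(dcost, dqaly) {
  stopifnot(all(is.finite(dcost)), all(is.finite(dqaly)))
  out <- rep("axes", length(dcost))
  out[dqaly > 0 & dcost < 0] <- "lower_right"
  out[dqaly > 0 & dcost > 0] <- "upper_right"
  out[dqaly < 0 & dcost < 0] <- "lower_left"
  out[dqaly < 0 & dcost > 0] <- "upper_left"
  out
}

#' Probabilistic sensitivity analysis
#'
#' Re-runs the paired comparison under parameter uncertainty: for each
#' replicate the varied parameters are redrawn, both arms are re-simulated
#' on the same cohort with the same patient-level draws (common random
#' numbers), and the incremental discounted cost and combined QALYs are
#' recorded per perspective. Summaries include quadrant shares and the
#' cost-effectiveness acceptability curve
#' `CEAC(lambda) = P(lambda * dQALY - dCost > 0)`.
#'
#' @param cohort An `adesim_cohort`.
#' @param reference,intervention Arm names.
#' @param params,config Base parameters and configuration.
#' @param spec PSA specification ([default_psa_spec()]).
#' @param n_replications Number of replicates (>= 1).
#' @param lambda_grid Willingness-to-pay grid (euro/QALY) for the CEAC.
#' @param seed Seed governing both the patient-level draws and the
#'   parameter draws.
#' @return A list of class `adesim_psa` with `replicates` (data.frame:
#'   replicate, perspective, delta_cost, delta_qaly, quadrant),
#'   `quadrant_shares` (per perspective) and `ceac` (data.frame: lambda,
#'   perspective, probability).
#' @export
run_psa <- function(cohort, reference = "none", intervention = "donepezil",
                    params = default_parameters(), config = default_config(),
                    spec = default_psa_spec(params), n_replications = 200,
                    lambda_grid = seq(0, 50000, by = 5000), seed = 1L) {
  if (n_replications < 1)
    stop("invalid argument: n_replications must be >= 1")
  set.seed(seed)
  n <- nrow(cohort)
  draws <- list(u_death = runif(n), u_disc = runif(n))
  res <- vector("list", n_replications)
  for (i in seq_len(n_replications)) {
    pi <- draw_psa_parameters(params, spec, seed = seed, replicate = i)
    ref <- simulate_arm(cohort, reference, pi, config, draws)
    int <- simulate_arm(cohort, intervention, pi, config, draws)
    rows <- lapply(c("direct", "societal"), function(pp) {
      cmp <- compare_arms(ref, int, perspective = pp)
      data.frame(replicate = i, perspective = pp,
                 delta_cost = cmp$delta_cost, delta_qaly = cmp$delta_qaly)
    })
    res[[i]] <- do.call(rbind, rows)
  }
  reps <- do.call(rbind, res)
  reps$quadrant <- classify_quadrant(reps$delta_cost, reps$delta_qaly)
  shares <- lapply(split(reps, reps$perspective), function(d) {
    tab <- table(factor(d$quadrant, levels = c("lower_right", "upper_right",
                                               "lower_left", "upper_left",
                                               "axes")))
    as.numeric(tab) / nrow(d)
  })
  shares <- do.call(rbind, shares)
  colnames(shares) <- c("lower_right", "upper_right", "lower_left",
                        "upper_left", "axes")
  ceac <- do.call(rbind, lapply(lambda_grid, function(l) {
    agg <- vapply(split(reps, reps$perspective), function(d)
      mean(l * d$delta_qaly - d$delta_cost > 0), numeric(1))
    data.frame(lambda = l, perspective = names(agg), probability = agg,
               row.names = NULL)
  }))
  structure(list(replicates = reps, quadrant_shares = shares, ceac = ceac,
                 reference = reference, intervention = intervention),
            class = "adesim_psa")
}

#' @export
print.adesim_psa <- function(x, ...) {
  cat(sprintf("<PSA> %s vs %s | %d replicates\n", x$intervention,
              x$reference, max(x$replicates$replicate)))
  cat("  quadrant shares (rows: perspective):\n")
  print(round(x$quadrant_shares, 3))
  invisible(x)
}

#' Cost-effectiveness plane scatter plot
#'
#' @param psa An `adesim_psa` object.
#' @param perspective Which perspective to plot.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, perspective = "societal") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  d <- psa$replicates[psa$replicates$perspective == perspective, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$delta_qaly, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Incremental QALYs (patient + caregiver)",
                  y = "Incremental cost (EUR)",
                  title = sprintf("%s vs %s (%s perspective)",
                                  psa$intervention, psa$reference, perspective))
}
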