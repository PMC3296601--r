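#' Load configuration and model parameters from a YAML file
#'
#' Reads a structured config file with optional top-level keys `config`
#' (simulation settings) and `parameters` (model inputs). Anything not
#' specified falls back to the shipped defaults ([default_config()],
#' [default_parameters()]), so an empty file loads the full default
#' parameter set. Unknown keys produce a warning naming the key; invalid
#' values produce an error naming the key (via [validate_parameters()]).
#'
#' @param path Path to a YAML file.
#' @return List with elements `config` and `params`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  unknown <- setdiff(names(user), c("config", "parameters"))
  if (length(unknown))
    warning("unknown top-level key(s) ignored: ",
            paste(unknown, collapse = ", "))

  cfg <- default_config()
  if (!is.null(user$config)) {
    unknown <- setdiff(names(user$config), names(cfg))
    if (length(unknown))
      warning("unknown config key(s) ignored: ",
              paste(unknown, collapse = ", "))
    cfg <- modifyList(cfg, user$config[intersect(names(user$config),
                                                 names(cfg))])
    if (cfg$horizon_years <= 0) stop("invalid value for key horizon_years")
    if (cfg$update_interval_weeks <= 0)
      stop("invalid value for key update_interval_weeks")
    if (!cfg$stopping_rule %in%
        c("none", "mmse_below_10", "deterioration_any_scale_after_6mo"))
      stop("invalid value for key stopping_rule")
  }

  params <- default_parameters()
  if (!is.null(user$parameters)) {
    up <- user$parameters
    unknown <- setdiff(names(up), names(params))
    if (length(unknown))
      warning("unknown parameter key(s) ignored: ",
              paste(unknown, collapse = ", "))
    for (k in intersect(names(up), names(params))) {
      v <- up[[k]]
      # YAML gives plain lists; coerce band tables back to data.frames and
      # named lists of numerics onto the default structure.
      params[[k]] <- .merge_param(params[[k]], v)
    }
  }
  validate_parameters(params)
  list(config = cfg, params = params)
}

.merge_param <- function(base, value) {
  if (is.data.frame(base)) {
    df <- as.data.frame(lapply(value, unlist))
    stopifnot(all(names(base) %in% names(df)))
    return(df[names(base)])
  }
  if (is.list(base)) {
    for (k in names(value)) base[[k]] <- .merge_param(base[[k]], value[[k]])
    return(base)
  }
  if (!is.null(names(base)) && is.list(value)) {
    v <- unlist(value)
    base[names(v)] <- v
    return(base)
  }
  out <- unlist(value)
  if (!is.null(names(base)) && length(out) == length(base) &&
      is.null(names(out)))
    names(out) <- names(base)
  out
}

#' Save configuration and parameters to YAML
#'
#' Round-trips with [load_config()].
#'
#' @param config,params Objects as returned by [load_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, params, path) {
  # Unset optional entries (NULLs) are omitted so that save -> load -> save
  # is byte-stable.
  drop_null <- function(x) {
    if (is.data.frame(x) || !is.list(x)) return(x)
    x <- lapply(x, drop_null)
    x[!vapply(x, is.null, logical(1))]
  }
  dump <- list(config = drop_null(unclass(config)),
               parameters = drop_null(unclass(params)))
  yaml::write_yaml(dump, path)
  invisible(path)
}

#' Stable hash of a configuration
#'
#' Keys are sorted recursively before hashing, so the hash is invariant to
#' key order in the source file.
#'
#' @param x A list (config, parameters, or both).
#' @return A character hash.
#' @export
config_hash <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v)) {
      if (!is.null(names(v)) && any(nzchar(names(v))))
        v <- v[order(names(v))]
      return(lapply(v, sort_rec))
    }
    if (!is.null(names(v))) return(v[order(names(v))])
    v
  }
  rlang::hash(sort_rec(unclass(x)))
}

# Table rows reported per arm, in presentation order.
.report_rows <- function(agg) {
  c("Survival (undiscounted, years)" = agg[["life_years"]],
    "Drug costs" = agg[["drug_disc"]],
    "Monitoring costs" = agg[["monitoring_disc"]],
    "Care costs" = agg[["care_disc"]],
    "Total non-drug direct costs" = agg[["monitoring_disc"]] + agg[["care_disc"]],
    "Total direct costs" = agg[["direct_cost_disc"]],
    "Indirect costs (caregiver time)" = agg[["caregiver_cost_disc"]],
    "Total costs" = agg[["total_cost_disc"]],
    "Years with MMSE > 10" = agg[["years_mmse_above"]],
    "Years with NPI < 28" = agg[["years_npi_below"]],
    "Years with ADL < 50" = agg[["years_adl_below"]],
    "Years with IADL < 50" = agg[["years_iadl_below"]],
    "Years in institution" = agg[["years_institution"]],
    "Total care time (years)" = agg[["caregiver_time_years"]],
    "QALYs (patient)" = agg[["qaly_patient_disc"]],
    "QALYs (caregiver)" = agg[["qaly_caregiver_disc"]],
    "QALYs (patient + caregiver)" =
      agg[["qaly_patient_disc"]] + agg[["qaly_caregiver_disc"]])
}

#' Write simulation results and a run manifest
#'
#' Writes one CSV of per-arm cohort-mean outcomes (rows in the standard
#' reporting order: survival, cost components, time-in-state tallies,
#' QALYs), one CSV of pairwise comparisons, and a JSON manifest recording
#' the configuration hash, seeds, package version, scenario name,
#' timestamp and output file list. Numbers are written at fixed precision
#' so reruns with the same seeds are byte-identical.
#'
#' @param results Named list of `arm_outcomes` (as from
#'   [run_simulation()]).
#' @param comparisons List of `adesim_comparison` objects (may be empty).
#' @param dir Output directory (created if missing).
#' @param config Simulation configuration (hashed into the manifest).
#' @param seed Seed(s) used for the run.
#' @param scenario Scenario name recorded in the manifest.
#' @return Invisible character vector of the files written.
#' @export
write_results <- function(results, comparisons, dir,
                          config = default_config(), seed = NA,
                          scenario = "base") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  aggs <- lapply(results, function(r) .report_rows(aggregate_outcomes(r)))
  tab <- data.frame(outcome = names(aggs[[1]]))
  for (arm in names(aggs)) tab[[arm]] <- round(unname(aggs[[arm]]), 6)
  f1 <- file.path(dir, "outcomes.csv")
  write.csv(tab, f1, row.names = FALSE)
  files <- c(files, f1)

  f2 <- file.path(dir, "comparisons.csv")
  if (length(comparisons)) {
    ctab <- do.call(rbind, lapply(comparisons, function(cmp)
      data.frame(intervention = cmp$intervention, reference = cmp$reference,
                 perspective = cmp$perspective,
                 delta_cost = round(cmp$delta_cost, 6),
                 delta_qaly = round(cmp$delta_qaly, 6),
                 status = cmp$status,
                 icer = round(cmp$icer, 6))))
  } else {
    ctab <- data.frame(intervention = character(0), reference = character(0),
                       perspective = character(0), delta_cost = numeric(0),
                       delta_qaly = numeric(0), status = character(0),
                       icer = numeric(0))
  }
  write.csv(ctab, f2, row.names = FALSE)
  files <- c(files, f2)

  manifest <- list(
    package = "adesim",
    version = as.character(utils::packageVersion("adesim")),
    config_hash = config_hash(config),
    seed = seed,
    scenario = scenario,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    files = basename(files)
  )
  f3 <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f3, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, f3))
}
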