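# Package-wide configuration: a nested key/value YAML file whose complete
# annotated default ships with the package.  User files override any subset
# of keys; unknown keys are rejected so typos cannot silently fall back to
# defaults.

#' Path to the annotated default configuration
#'
#' @return Path to the YAML file holding every package default.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml",
              package = "hipscreen", mustWork = TRUE)
}

#' Load the (merged) run configuration
#'
#' Reads the package default configuration and, if `path` is given, overlays
#' the user file on top.  Any key in the user file that does not exist in
#' the defaults raises a config error naming the offending key.
#'
#' @param path Optional user YAML file overriding defaults.
#' @return Nested named list (`run_config`).
#' @export
#' @examples
#' cfg <- load_config()
#' cfg$costs$per_assessment_dxa
load_config <- function(path = NULL) {
  defaults <- yaml::read_yaml(default_config_path())
  if (is.null(path)) {
    return(structure(defaults, class = "run_config"))
  }
  if (!file.exists(path)) abort_config(paste0("Config file not found: ", path))
  user <- yaml::read_yaml(path)
  if (!is.list(user)) abort_config("Config file must contain a key/value mapping.")
  check_known_keys(user, defaults, prefix = NULL)
  structure(merge_config(defaults, user), class = "run_config")
}

check_known_keys <- function(user, defaults, prefix) {
  if (is.null(names(user))) return(invisible())
  for (key in names(user)) {
    full <- paste(c(prefix, key), collapse = ".")
    if (!key %in% names(defaults)) {
      abort_config(paste0("Unknown configuration key: `", full, "`."))
    }
    if (is.list(user[[key]]) && !is.null(names(user[[key]]))) {
      if (!is.list(defaults[[key]])) {
        abort_config(paste0("Configuration key `", full, "` must be a scalar."))
      }
      check_known_keys(user[[key]], defaults[[key]], prefix = c(prefix, key))
    }
  }
  invisible()
}

merge_config <- function(defaults, user) {
  for (key in names(user)) {
    if (is.list(user[[key]]) && !is.null(names(user[[key]])) &&
        is.list(defaults[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]])
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

# --- constructors from a run_config -------------------------------------

config_cohort_spec <- function(config, random_seed = NULL) {
  co <- config$cohort
  cohort_spec(
    n_pairs = co$n_pairs,
    mean_strength = co$mean_strength,
    auc_mss = co$auc_mss,
    auc_abmd = co$auc_abmd,
    see_fraction = co$see_fraction,
    ser_fraction = co$ser_fraction,
    tscore_reference_mean = co$tscore_reference_mean,
    tscore_reference_sd = co$tscore_reference_sd,
    abmd_slope = co$abmd_slope,
    abmd_intercept = co$abmd_intercept,
    age_min = co$age_min, age_max = co$age_max,
    weight_mean = co$weight_mean, weight_sd = co$weight_sd,
    height_mean = co$height_mean, height_sd = co$height_sd,
    min_strength = co$min_strength,
    random_seed = random_seed %||% config$random_seed
  )
}

config_pathway <- function(config, name) {
  th <- config$thresholds
  pathway_definition(name,
                     tscore_treat_cutoff = th$tscore_treat_cutoff,
                     tscore_safe_cutoff = th$tscore_safe_cutoff,
                     mss_cutoff = th$mss_cutoff)
}

config_costs <- function(config) do.call(cost_parameters, config$costs)

config_qaly <- function(config) do.call(qaly_parameters, config$qaly)

config_treatment <- function(config) treatment_model(config$treatment$efficacy)

config_radiation <- function(config) {
  rad <- config$radiation
  rad$dose_ct_protocol_msv <- unlist(rad$dose_ct_protocol_msv)
  do.call(radiation_scenario, rad)
}
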