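#' Default run configuration
#'
#' The baseline configuration used when a config file omits keys: baseline
#' observer parameters, the standard seven aspect ratios at a single
#' representative orientation, 100 trials per cell, the default 75-individual
#' population, expected-frequency mode and seed 1.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    observer = list(
      c_stim = 5, kappa_stim_l1 = 20, kappa_sens_l1 = 20,
      kappa_stim_l2 = 20, kappa_sens_l2 = 18, kappa_perc_l1 = 10,
      w_stim_l1 = 0.60, w_perc_l1 = 0.50,
      prior_kind = "uniform", variant = "hierarchical", grid_step = 1
    ),
    design = list(
      aspect_ratios = default_aspect_ratios(),
      orientations = 0,
      n_per_condition = 100
    ),
    population = list(
      n_individuals = 75,
      means = c(5, 6.5, 5),
      covariance = as.vector(default_population_covariance()),
      lower = c(0, 0, 0),
      upper = c(Inf, 10, 10),
      weight_rescale = 10
    ),
    mode = "expected",
    n_boot = 2000,
    seed = 1
  ), class = "run_config")
}

config_schema <- function() {
  lapply(default_config(), function(section) {
    if (is.list(section)) names(section) else NULL
  })
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills unset keys with the baseline defaults of
#' [default_config()], rejects unknown keys by name, and validates parameter
#' ranges. An empty file yields the full default configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "dotlattice_config_error")
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(user)
}

#' Build a run configuration from a list
#'
#' @param user Named list of overrides, structured like [default_config()].
#' @return A validated `run_config` list.
#' @export
merge_config <- function(user = list()) {
  defaults <- default_config()
  schema <- config_schema()
  bad <- setdiff(names(user), names(defaults))
  if (length(bad) > 0) {
    abort(sprintf("Unknown config key: %s", paste(bad, collapse = ", ")),
          class = "dotlattice_config_error")
  }
  for (section in names(user)) {
    if (is.list(defaults[[section]]) && !is.null(schema[[section]])) {
      bad <- setdiff(names(user[[section]]), schema[[section]])
      if (length(bad) > 0) {
        abort(sprintf("Unknown config key: %s.%s", section,
                      paste(bad, collapse = ", ")),
              class = "dotlattice_config_error")
      }
    }
  }
  config <- utils::modifyList(defaults, user)
  # "Inf" arrives as a string from YAML
  config$population$upper <- as.numeric(config$population$upper)
  validate_config(config)
}

validate_config <- function(config) {
  do.call(observer_params, config$observer) # validates observer block
  if (!config$mode %in% c("expected", "sampled")) {
    abort("`mode` must be \"expected\" or \"sampled\".",
          class = "dotlattice_config_error")
  }
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    abort("`seed` must be a single integer.", class = "dotlattice_config_error")
  }
  cov <- matrix(as.numeric(config$population$covariance), 3, 3)
  do.call(population_spec,
          c(config$population[setdiff(names(config$population), "covariance")],
            list(covariance = cov)))
  do.call(experiment_design, config$design)
  structure(config, class = "run_config")
}

#' Save a run configuration to YAML
#'
#' @param config A `run_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

config_params <- function(config) {
  do.call(observer_params, config$observer)
}

config_design <- function(config, seed = config$seed) {
  do.call(experiment_design, c(config$design, list(seed = seed)))
}

config_population <- function(config, seed = config$seed) {
  cov <- matrix(as.numeric(config$population$covariance), 3, 3)
  do.call(population_spec,
          c(config$population[setdiff(names(config$population), "covariance")],
            list(covariance = cov, seed = seed)))
}
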