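# Structured-text (YAML) configuration: [world], [pfts], [fire], [experiment]
# sections mirroring world_config(), default_pfts(), fire_params() and the
# run_experiment() arguments.

#' Default experiment configuration
#'
#' @return A nested list with components `world`, `pfts`, `fire`,
#'   `experiment`, suitable for [write_config()] and [run_experiment_config()].
#' @export
default_config <- function() {
  w <- unclass(world_config())
  list(
    world = w[c("nlat", "nlon", "years", "seed", "lat_centers", "lon_factors",
      "wet_persistence", "gamma_shape", "temp_noise_sd", "temp_noise_ar",
      "seasonality")],
    pfts = lapply(seq_len(nrow(default_pfts())), function(i) {
      as.list(default_pfts()[i, ])
    }),
    fire = fire_params(),
    experiment = list(
      o2_levels = default_o2_levels(),
      spinup_years = 200,
      out_years = 10,
      bands = c(20, 40, 60)
    )
  )
}

#' Read / write a configuration file
#'
#' Configurations are YAML with sections `world`, `pfts`, `fire`,
#' `experiment`; missing entries fall back to the package defaults.
#'
#' @param path File path.
#' @param config A configuration list (see [default_config()]).
#' @return `read_config()` returns the merged configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  for (section in intersect(names(user), names(base))) {
    if (section == "pfts") {
      base$pfts <- user$pfts
    } else {
      base[[section]][names(user[[section]])] <- user[[section]]
    }
  }
  base
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

config_world <- function(config) {
  do.call(world_config, config$world[setdiff(names(config$world), character())])
}

config_pfts <- function(config) {
  dplyr::bind_rows(lapply(config$pfts, tibble::as_tibble))
}

config_params <- function(config) {
  do.call(fire_params, config$fire)
}

#' Run the sweep experiment from a configuration
#'
#' @param config A configuration list from [read_config()] or
#'   [default_config()].
#' @param ... Overrides passed to [run_experiment()].
#' @return An `oxfire_sweep` object.
#' @export
run_experiment_config <- function(config, ...) {
  args <- list(
    world = config_world(config),
    o2_levels = config$experiment$o2_levels,
    spinup_years = config$experiment$spinup_years,
    out_years = config$experiment$out_years,
    pfts = config_pfts(config),
    params = config_params(config),
    bands = config$experiment$bands
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(run_experiment, args)
}
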