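# Seedable synthetic climate/lightning forcing on a latitude-longitude grid:
# wet tropics, arid subtropics, seasonally dry mid-latitudes and cold,
# low-evaporative-demand high latitudes, with a two-state Markov chain for
# precipitation occurrence and gamma-distributed amounts.

DAYS_PER_YEAR <- 365L

#' Configuration of the synthetic world
#'
#' @param nlat,nlon Grid shape; the default 18 x 36 gives 10-degree cells
#'   spanning both hemispheres.
#' @param years Number of simulated years (365-day calendar).
#' @param seed Integer seed; output is fully deterministic given the seed.
#' @param lat_centers Optional explicit latitude centres (deg N), length
#'   `nlat`; defaults to an even global spacing.
#' @param lon_factors Optional per-longitude wetness multipliers, length
#'   `nlon`, creating maritime-to-continental contrast within each latitude
#'   band; defaults to a smooth cycle in `[0.7, 1.4]`.
#' @param wet_persistence Lag-1 autocorrelation of the wet/dry occurrence
#'   chain.
#' @param gamma_shape Shape of the gamma distribution of wet-day amounts.
#' @param temp_noise_sd,temp_noise_ar Daily temperature noise (deg C) and its
#'   AR(1) coefficient.
#' @param seasonality Multiplier in `[0, 1]` on all seasonal amplitudes
#'   (setting 0 yields a stationary climate, useful for calibration checks).
#' @return A list of class `oxfire_world_config`.
#' @export
world_config <- function(nlat = 18, nlon = 36, years = 30, seed = 1,
                         lat_centers = NULL, lon_factors = NULL,
                         wet_persistence = 0.2, gamma_shape = 0.8,
                         temp_noise_sd = 1.5, temp_noise_ar = 0.7,
                         seasonality = 1) {
  if (nlat < 1 || nlon < 1 || years < 1) {
    stop("grid shape and years must be positive", call. = FALSE)
  }
  if (is.null(lat_centers)) {
    half <- 180 / nlat / 2
    lat_centers <- seq(-90 + half, 90 - half, length.out = nlat)
  }
  stopifnot(length(lat_centers) == nlat)
  if (is.null(lon_factors)) {
    lon_factors <- 1.05 + 0.35 * sin(2 * pi * seq_len(nlon) / nlon)
  }
  stopifnot(length(lon_factors) == nlon)
  structure(
    list(
      nlat = nlat, nlon = nlon, years = as.integer(years), seed = as.integer(seed),
      lat_centers = lat_centers, lon_factors = lon_factors,
      wet_persistence = wet_persistence, gamma_shape = gamma_shape,
      temp_noise_sd = temp_noise_sd, temp_noise_ar = temp_noise_ar,
      seasonality = seasonality
    ),
    class = "oxfire_world_config"
  )
}

#' Mini-world configuration for tests and desk-scale experiments
#'
#' A 6 x 3 grid whose latitude rows sample the main climate archetypes:
#' wet tropics (5 deg), arid subtropics (20), winter-wet mid-latitudes (35),
#' moist mid-latitudes (50), boreal (65) and tundra (80); the three
#' longitudes span dry, average and wet variants of each row.
#'
#' @inheritParams world_config
#' @param ... Passed on to [world_config()].
#' @export
mini_world_config <- function(years = 5, seed = 42, ...) {
  world_config(
    nlat = 6, nlon = 3, years = years, seed = seed,
    lat_centers = c(5, 20, 35, 50, 65, 80),
    lon_factors = c(0.7, 1.0, 1.4),
    ...
  )
}

# zonal climate normals as smooth functions of |latitude|
climate_normals <- function(lat) {
  a <- abs(lat) / 90
  knots <- c(0, 10, 20, 27, 40, 55, 70, 90)
  tibble::tibble(
    lat = lat,
    t_mean = 28 - 43 * a^1.8,
    t_amp = 1 + 34 * a^1.5,
    p_ann = approx(knots, c(2400, 2000, 500, 230, 800, 850, 480, 200), abs(lat))$y,
    pw_mean = approx(knots, c(0.85, 0.65, 0.07, 0.12, 0.28, 0.70, 0.60, 0.45), abs(lat))$y,
    pw_amp = approx(knots, c(0.10, 0.25, 0.60, 0.20, 0.20, 0.05, 0.10, 0.20), abs(lat))$y,
    # convective (summer) wet peak in the tropics and high latitudes,
    # winter-wet regime in between
    pw_peak_summer = abs(lat) < 20 | abs(lat) >= 55,
    light_ann = approx(knots, c(8, 6, 5, 3, 5, 2.2, 3, 1), abs(lat))$y,
    # calm subtropical (horse-latitude) belt between trade winds and westerlies
    wind_mean = approx(knots, c(2.5, 3.0, 3.4, 2.4, 3.2, 3.4, 3.2, 3.0), abs(lat))$y
  )
}

#' Wet-day occurrence probabilities of the precipitation chain
#'
#' The two-state (wet/dry) occurrence chain is parameterised by its
#' stationary wet-day probability `pw` and a persistence `rho`:
#' `P(wet | dry) = (1 - rho) * pw` and `P(wet | wet) = pw + rho * (1 - pw)`,
#' so the chain's stationary distribution is exactly `pw` and its lag-1
#' autocorrelation is `rho`. Returned per day of year for one cell.
#'
#' @param config See [world_config()].
#' @param lat Latitude of the cell, deg N.
#' @param lon_factor Wetness multiplier of the cell's longitude.
#' @param doy Day of year, 1..365.
#' @return Tibble with `pw` (stationary wet probability), `p_wet_dry`,
#'   `p_wet_wet`.
#' @export
wet_day_params <- function(config, lat, lon_factor = 1, doy = seq_len(DAYS_PER_YEAR)) {
  nm <- climate_normals(lat)
  peak <- ifelse(nm$pw_peak_summer, 196, 15) + if (lat < 0) 182.5 else 0
  seas <- 1 + config$seasonality * nm$pw_amp * cos(2 * pi * (doy - peak) / DAYS_PER_YEAR)
  pw <- pmin(pmax(nm$pw_mean * seas * lon_factor^0.6, 0.02), 0.95)
  rho <- config$wet_persistence
  tibble::tibble(
    doy = doy, pw = pw,
    p_wet_dry = (1 - rho) * pw,
    p_wet_wet = pw + rho * (1 - pw)
  )
}

# simulate one cell's daily weather for all years; uses the current RNG stream
simulate_cell_weather <- function(config, lat, lon_factor, ndays) {
  nm <- climate_normals(lat)
  doy <- rep(seq_len(DAYS_PER_YEAR), length.out = ndays)
  wp <- wet_day_params(config, lat, lon_factor, seq_len(DAYS_PER_YEAR))

  # wet/dry occurrence chain
  p_wd <- wp$p_wet_dry[doy]
  p_ww <- wp$p_wet_wet[doy]
  u <- runif(ndays)
  wet <- logical(ndays)
  state <- u[1] < wp$pw[doy[1]]
  wet[1] <- state
  for (t in 2:ndays) {
    state <- u[t] < if (state) p_ww[t] else p_wd[t]
    wet[t] <- state
  }

  # gamma amounts targeting the zonal annual total
  f_seas <- (1 + config$seasonality * nm$pw_amp *
    cos(2 * pi * (doy - ifelse(nm$pw_peak_summer, 196, 15) -
      if (lat < 0) 182.5 else 0) / DAYS_PER_YEAR)) / DAYS_PER_YEAR
  mu <- nm$p_ann * lon_factor * pmax(f_seas, 1e-4) / pmax(wp$pw[doy], 0.02)
  prec <- numeric(ndays)
  nwet <- sum(wet)
  if (nwet > 0) {
    prec[wet] <- rgamma(nwet, shape = config$gamma_shape,
      scale = mu[wet] / config$gamma_shape)
  }

  # temperature: seasonal cycle + AR(1) noise, slightly cooler on wet days
  t_peak <- if (lat >= 0) 196 else 15
  t_seas <- nm$t_mean + config$seasonality * nm$t_amp *
    cos(2 * pi * (doy - t_peak) / DAYS_PER_YEAR)
  noise <- as.numeric(filter(
    rnorm(ndays, 0, config$temp_noise_sd * sqrt(1 - config$temp_noise_ar^2)),
    config$temp_noise_ar,
    method = "recursive"
  ))
  temp <- t_seas + noise - 1.5 * wet

  # relative-humidity proxy: smoothed wet-day frequency plus low evaporative
  # demand when cold
  s <- as.numeric(filter(wet / 30, 1 - 1 / 30, method = "recursive",
    init = mean(wp$pw)))
  rh <- pmin(pmax(0.05 + 0.9 * s^1.1 + 0.1 * pmin(pmax(1 - temp / 15, 0), 1.25),
    0.03), 0.97)

  # wind: lognormal daily values around the zonal mean
  wind <- nm$wind_mean * exp(rnorm(ndays, -0.08, 0.4))

  # lightning climatology peaks with warm, convectively active conditions
  conv <- pmax(temp - 10, 0) * (0.4 + 0.6 * s)
  mean_conv <- mean(conv)
  light <- if (mean_conv > 0) nm$light_ann / DAYS_PER_YEAR * conv / mean_conv else
    rep(0, ndays)

  tibble::tibble(
    doy = doy, temp = temp, prec = prec, rh = rh, wind = wind,
    lightning = light
  )
}

#' Generate gridded daily forcing for the synthetic world
#'
#' Daily temperature, precipitation, relative-humidity proxy, wind and
#' lightning strike density for every cell and year of the configured world.
#' Output is deterministic for a fixed seed. Latitude structure follows the
#' configured zonal normals: year-round rain in the equatorial band, a
#' pronounced dry season in the mid-latitudes, arid subtropical bands, and
#' cold high latitudes whose low evaporative demand keeps the humidity proxy
#' high.
#'
#' @param config See [world_config()].
#' @return A tibble of class `oxfire_forcing` with columns `cell`, `lat`,
#'   `lon`, `area_km2`, `year`, `doy`, `temp` (deg C), `prec` (mm/day), `rh`
#'   (0-1), `wind` (m/s), `lightning` (strikes/km2/day).
#' @export
#' @examples
#' f <- generate_forcing(mini_world_config(years = 2))
#' dplyr::count(f, cell)
generate_forcing <- function(config) {
  stopifnot(inherits(config, "oxfire_world_config"))
  ndays <- config$years * DAYS_PER_YEAR
  grid <- tidyr::expand_grid(
    lat = config$lat_centers,
    lon_index = seq_len(config$nlon)
  ) |>
    dplyr::mutate(
      lon = (.data$lon_index - 0.5) * 360 / config$nlon - 180,
      lon_factor = config$lon_factors[.data$lon_index],
      cell = dplyr::row_number(),
      area_km2 = cell_area_km2(
        .data$lat,
        if (config$nlat > 1) stats::median(diff(config$lat_centers)) else 180 / config$nlat,
        360 / config$nlon
      )
    )

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  weather <- purrr::map(seq_len(nrow(grid)), function(i) {
    simulate_cell_weather(config, grid$lat[i], grid$lon_factor[i], ndays) |>
      dplyr::mutate(
        cell = grid$cell[i],
        year = rep(seq_len(config$years), each = DAYS_PER_YEAR)
      )
  }) |>
    purrr::list_rbind()

  out <- weather |>
    dplyr::left_join(
      dplyr::select(grid, "cell", "lat", "lon", "area_km2"),
      by = "cell"
    ) |>
    dplyr::select(
      "cell", "lat", "lon", "area_km2", "year", "doy",
      "temp", "prec", "rh", "wind", "lightning"
    )
  class(out) <- c("oxfire_forcing", class(out))
  out
}

# spherical cell area
cell_area_km2 <- function(lat, dlat, dlon) {
  r <- 6371
  lat1 <- pmax(lat - dlat / 2, -90) * pi / 180
  lat2 <- pmin(lat + dlat / 2, 90) * pi / 180
  2 * pi * r^2 * (dlon / 360) * abs(sin(lat2) - sin(lat1))
}

#' Deterministic forcing fixtures
#'
#' Tiny forcing sets for unit tests: `"single_cell_wet"` (one warm cell with
#' rain above 4 mm every day, 2 years), `"single_cell_dry"` (one hot cell
#' with rain only during the first 90 days of the series, 2 years) and
#' `"mini_world"` (the seeded 6 x 3 grid of [mini_world_config()], 5 years).
#'
#' @param name One of `"single_cell_wet"`, `"single_cell_dry"`,
#'   `"mini_world"`.
#' @return A forcing tibble as from [generate_forcing()].
#' @export
make_fixture <- function(name = c("single_cell_wet", "single_cell_dry", "mini_world")) {
  name <- match.arg(name)
  if (name == "mini_world") {
    return(generate_forcing(mini_world_config(years = 5, seed = 42)))
  }
  ndays <- 2L * DAYS_PER_YEAR
  day <- seq_len(ndays)
  doy <- rep(seq_len(DAYS_PER_YEAR), 2)
  base <- tibble::tibble(
    cell = 1L,
    lat = if (name == "single_cell_wet") 5 else 20,
    lon = 0,
    area_km2 = cell_area_km2(if (name == "single_cell_wet") 5 else 20, 10, 20),
    year = rep(1:2, each = DAYS_PER_YEAR),
    doy = doy
  )
  out <- if (name == "single_cell_wet") {
    dplyr::mutate(base,
      temp = 26 + 1.5 * cos(2 * pi * (doy - 196) / DAYS_PER_YEAR),
      prec = 6 + cos(2 * pi * doy / DAYS_PER_YEAR),
      rh = 0.9, wind = 2.5, lightning = 8 / DAYS_PER_YEAR
    )
  } else {
    dplyr::mutate(base,
      temp = 28 + 6 * cos(2 * pi * (doy - 196) / DAYS_PER_YEAR),
      prec = ifelse(day <= 90, 5, 0),
      rh = 0.15, wind = 4, lightning = 2 / DAYS_PER_YEAR
    )
  }
  class(out) <- c("oxfire_forcing", class(out))
  out
}
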