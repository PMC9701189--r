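# Simplified SPITFIRE-style daily fire behaviour: danger index, lightning
# ignitions, moisture-damped rate of spread, Byram fireline intensity,
# elliptical burned area and saturating fire mortality. All oxygen dependence
# enters through the flammability scalings.

#' Model parameters for the fire engine and its surroundings
#'
#' Single flat list of every tunable constant in the fire engine, the fuel
#' and moisture dynamics and the vegetation surrogate. All values are
#' config-exposed; defaults are conventional fire-science or LPJ-family
#' magnitudes. Units are given per entry.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters.
#'
#' @details Key entries:
#' \describe{
#'   \item{pi_floor}{smallest PAL ignition rating used in the scaling
#'     denominator (rating points, default 1); see [ignition_scaling()].}
#'   \item{duration}{representative burn duration of a fire, minutes
#'     (default 240; single-day fires, no multi-day coalescence).}
#'   \item{ground_strike_frac}{fraction of lightning flashes striking ground
#'     and able to ignite (default 0.2).}
#'   \item{ros_max}{base rate-of-spread scale, m min^-1.}
#'   \item{k_wind}{linear wind response of spread, per m s^-1.}
#'   \item{bd_ref}{reference fuel bulk density, kg m^-3; spread falls off as
#'     `1 / (1 + bulk_density / bd_ref)`.}
#'   \item{fuel_half}{fuel load at which fuel continuity halves spread,
#'     kg m^-2.}
#'   \item{me_fine, me_woody}{native (PAL) moisture of extinction per fuel
#'     class, % dry mass; multiplied by [moisture_extinction_scaling()].}
#'   \item{cc_fine, cc_woody}{combustion completeness per fuel class.}
#'   \item{i_half}{fireline intensity at which tree mortality
#'     half-saturates, kW m^-1.}
#'   \item{rain_reset, nesterov_ref}{precipitation (mm) that resets the
#'     dryness index, and the index value (deg C days) at which the fire
#'     danger index reaches 1 - 1/e.}
#'   \item{tau_nl, tau_o}{relaxation times (days) of the fast (1-h + live
#'     grass) and woody fuel moistures.}
#'   \item{m_soaked}{fuel-moisture equilibrium on rain days, % dry mass.}
#' }
#' @export
fire_params <- function(...) {
  p <- list(
    # ignition
    pi_floor = 1,
    ground_strike_frac = 0.35,
    # spread
    ros_max = 18, # m/min
    q_ig_half = 28, # % moisture at which the ignition heat sink halves spread
    k_wind = 0.54, # per m/s
    bd_ref = 4, # kg/m3
    fuel_half = 0.05, # kg/m2
    duration = 240, # min
    lb_max = 1, # length-to-breadth ellipse: LB = 1 + lb_max*(1 - exp(-0.2 wind))
    # fuel classes
    me_fine = 16, # % dry mass at PAL
    me_woody = 15,
    damping_exp = 3, # steepness of moisture damping toward extinction
    cc_fine = 0.8,
    cc_woody = 0.25,
    # mortality
    i_half = 150, # kW/m
    # fire danger
    rain_reset = 3, # mm/day
    nesterov_ref = 300, # degC days
    # fuel moisture dynamics
    tau_nl = 7, # days
    tau_o = 25,
    m_soaked = 70, # % dry mass on rain days
    m_dry_min = 4,
    m_rh_range = 170,
    m_rh_exp = 1.6,
    # vegetation surrogate
    fpc_space = 0.95,
    seed_fpc = 5e-4,
    decay_excluded = 0.2, # yr^-1 fractional decay outside bioclimatic limits
    k_pet = 0.17, # mm per degC day, crude evaporative demand
    tree_mi = c(0.28, 0.75), # moisture-index ramp for tree carrying capacity
    grass_mi = c(0.04, 0.25),
    k_tree_max = 0.95,
    k_grass_max = 0.90,
    # fuel pools
    fine_prod_grass = 0.30, # kg/m2/yr per unit FPC
    fine_prod_tree = 0.20,
    woody_prod_tree = 0.15,
    dec_fine = 0.35, # yr^-1
    dec_woody = 0.15,
    wood_fuel_per_fpc = 4, # kg/m2 of woody fuel from a fully killed tree canopy
    bd_bare = 1.2 # kg/m3 bulk density used for (near-)bare cells
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
    p[names(dots)] <- dots
  }
  p
}

#' Fire danger index from daily weather
#'
#' Nesterov-style cumulative dryness index mapped to `[0, 1]`. Each dry day
#' adds `max(temp, 0) * (1 - rh)` to the index; a day with precipitation
#' above `rain_reset` resets it to zero. The returned danger for day *t* is
#' `1 - exp(-N[t-1] / nesterov_ref)`, i.e. the dryness accumulated through
#' the previous day, so the day after heavy rain has zero danger.
#'
#' @param temp Daily mean temperature, deg C.
#' @param prec Daily precipitation, mm.
#' @param rh Daily relative-humidity proxy in `[0, 1]`.
#' @param params See [fire_params()].
#' @return Numeric vector of fire danger in `[0, 1]`, same length as input.
#' @export
#' @examples
#' fire_danger_index(rep(30, 10), c(10, rep(0, 9)), rep(0.2, 10))
fire_danger_index <- function(temp, prec, rh, params = fire_params()) {
  n <- length(temp)
  stopifnot(length(prec) == n, length(rh) == n)
  wet <- prec > params$rain_reset
  incr <- pmax(temp, 0) * (1 - rh)
  incr[wet] <- 0
  seg <- cumsum(wet)
  nest <- ave(incr, seg, FUN = cumsum)
  lagged <- c(0, nest[-n])
  1 - exp(-lagged / params$nesterov_ref)
}

#' Expected lightning ignitions per cell per day
#'
#' @param lightning Cloud-to-anything flash density, strikes km^-2 day^-1.
#' @param ieff Overall ignition efficiency (see
#'   [overall_ignition_efficiency()]).
#' @param cell_area_km2 Grid-cell area, km^2.
#' @param ground_strike_frac Fraction of flashes that strike ground.
#' @return Expected number of fires started, per cell per day.
#' @export
expected_ignitions <- function(lightning, ieff, cell_area_km2,
                               ground_strike_frac = 0.2) {
  if (any(lightning < 0)) stop("`lightning` must be non-negative", call. = FALSE)
  if (any(ieff < 0)) stop("`ieff` must be non-negative", call. = FALSE)
  lightning * ground_strike_frac * cell_area_km2 * ieff
}

#' Construct a fuel bed
#'
#' Tidy row-wise container for the fuel state entering [rate_of_spread()]:
#' fine (1-h dead + live grass) and woody (10-h to 1000-h) loads, the bulk
#' density of the packed bed, the two fuel moistures, and the native (PAL)
#' moisture-of-extinction constants per class.
#'
#' @param fine_load,woody_load Fuel loads, kg m^-2.
#' @param bulk_density Fuel-bed bulk density, kg m^-3.
#' @param moisture_nl Fast (1-h + live grass) fuel moisture, % dry mass.
#' @param moisture_o Woody fuel moisture, % dry mass.
#' @param me_fine,me_woody Native moisture of extinction per class, % dry
#'   mass at PAL.
#' @return A tibble with one row per fuel bed.
#' @export
fuel_bed <- function(fine_load, woody_load, bulk_density,
                     moisture_nl, moisture_o,
                     me_fine = fire_params()$me_fine,
                     me_woody = fire_params()$me_woody) {
  out <- tibble::tibble(
    fine_load = fine_load, woody_load = woody_load,
    bulk_density = bulk_density,
    moisture_nl = moisture_nl, moisture_o = moisture_o,
    me_fine = me_fine, me_woody = me_woody
  )
  if (any(out$fine_load < 0) || any(out$woody_load < 0) || any(out$bulk_density < 0)) {
    stop("fuel loads and bulk density must be non-negative", call. = FALSE)
  }
  if (any(out$moisture_nl <= 0) || any(out$moisture_o <= 0)) {
    stop("fuel moistures must be positive", call. = FALSE)
  }
  out
}

# Moisture damping on the ratio of fuel moisture to the (oxygen-scaled)
# moisture of extinction: (1 - r)^k for r < 1, zero at and beyond
# extinction. Steeper than the classic Rothermel cubic near extinction, so
# marginally dry fuels carry only creeping fire.
moisture_damping <- function(ratio, exponent = 1.5) {
  pmax(1 - ratio, 0)^exponent
}

# core spread kernel shared by the exported wrapper and the simulator
ros_kernel <- function(m_eff, me_eff, wind, bulk_density, fuel_load, params) {
  damp <- moisture_damping(m_eff / me_eff, params$damping_exp)
  # heat sink: energy spent preheating and evaporating fuel water slows the
  # front even well below extinction
  sink <- 1 / (1 + m_eff / params$q_ig_half)
  continuity <- fuel_load / (fuel_load + params$fuel_half)
  packing <- 1 / (1 + bulk_density / params$bd_ref)
  ros <- params$ros_max * (1 + params$k_wind * wind) * packing * continuity *
    damp * sink
  ros[fuel_load <= 0] <- 0
  ros
}

#' Forward rate of spread of a surface fire
#'
#' Rothermel-flavoured spread rate: a base scale increased linearly by wind,
#' reduced by fuel-bed bulk density, sparse fuel and an ignition heat sink
#' (the energy spent preheating and evaporating fuel water,
#' `1 / (1 + m / q_ig_half)`), and damped by the ratio of the load-weighted
#' fuel moisture to the effective moisture of extinction,
#' `(1 - m / Me_eff)^damping_exp`. The effective moisture of extinction is
#' the load-weighted native constant multiplied by
#' [moisture_extinction_scaling()], so spread is non-decreasing in oxygen;
#' at or above extinction the spread rate is exactly zero.
#'
#' @param fuel A fuel bed, see [fuel_bed()]; one row per case.
#' @param wind Wind speed, m s^-1, recycled against rows of `fuel`.
#' @param o2 Atmospheric oxygen, % vol.
#' @param params See [fire_params()].
#' @return Rate of spread, m min^-1.
#' @export
#' @examples
#' fb <- fuel_bed(0.4, 0.1, 2, moisture_nl = 12, moisture_o = 25)
#' rate_of_spread(fb, wind = 4, o2 = c(20.95))
#' rate_of_spread(fb, wind = 4, o2 = 35) # weaker moisture damping
rate_of_spread <- function(fuel, wind, o2 = PAL_O2, params = fire_params()) {
  if (any(wind < 0)) stop("`wind` must be non-negative", call. = FALSE)
  check_o2(o2)
  total <- fuel$fine_load + fuel$woody_load
  m_eff <- ifelse(total > 0,
    (fuel$fine_load * fuel$moisture_nl + fuel$woody_load * fuel$moisture_o) / total,
    fuel$moisture_nl
  )
  me_native <- ifelse(total > 0,
    (fuel$fine_load * fuel$me_fine + fuel$woody_load * fuel$me_woody) / total,
    fuel$me_fine
  )
  me_eff <- me_native * moisture_extinction_scaling(o2)
  ros_kernel(m_eff, me_eff, wind, fuel$bulk_density, total, params)
}

#' Byram fireline intensity
#'
#' Energy release rate per unit length of fire front,
#' `I = h * consumed * ros / 60` (kW m^-1), with the heat of combustion in
#' kJ kg^-1, the fuel consumed in kg m^-2 and the spread rate in m min^-1.
#'
#' @param h Heat of combustion, kJ kg^-1 (grid-cell FPC-weighted average).
#' @param fuel_consumed Fuel consumed in the flaming front, kg m^-2.
#' @param ros Rate of spread, m min^-1.
#' @return Fireline intensity, kW m^-1.
#' @export
#' @examples
#' fireline_intensity(18000, 1, 60) # 18,000 kW/m
fireline_intensity <- function(h, fuel_consumed, ros) {
  if (any(h < 0) || any(fuel_consumed < 0) || any(ros < 0)) {
    stop("all inputs must be non-negative", call. = FALSE)
  }
  h * fuel_consumed * ros / 60
}

# ellipse area (km^2) of a single fire from spread rate and wind
fire_ellipse_area_km2 <- function(ros, wind, params = fire_params()) {
  length_m <- ros * params$duration
  lb <- 1 + params$lb_max * (1 - exp(-0.2 * wind))
  (pi / 4) * length_m * (length_m / lb) / 1e6
}

#' Daily burned area as a fraction of the grid cell
#'
#' Each fire burns an ellipse whose length is `ros * duration` and whose
#' length-to-breadth ratio grows with wind. The day's newly burned fraction
#' is `n_ignitions` times the per-fire area over the cell area, capped at
#' the cell fraction that remains unburned this year.
#'
#' @param n_ignitions Expected fires today (see [expected_ignitions()]).
#' @param ros Rate of spread, m min^-1.
#' @param wind Wind speed, m s^-1.
#' @param cell_area_km2 Cell area, km^2.
#' @param cum_burned Fraction of the cell already burned this calendar year.
#' @param params See [fire_params()].
#' @return Newly burned fraction of the cell, in `[0, 1 - cum_burned]`.
#' @export
burned_area <- function(n_ignitions, ros, wind, cell_area_km2,
                        cum_burned = 0, params = fire_params()) {
  if (any(n_ignitions < 0) || any(ros < 0) || any(wind < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  if (any(cum_burned < 0 | cum_burned > 1)) {
    stop("`cum_burned` must lie in [0, 1]", call. = FALSE)
  }
  raw <- n_ignitions * fire_ellipse_area_km2(ros, wind, params) / cell_area_km2
  pmin(raw, 1 - cum_burned)
}

#' Fire-caused mortality per PFT
#'
#' Kill fraction as a saturating function of fireline intensity scaled by a
#' per-PFT susceptibility: `kill = susceptibility * I / (I + i_half)`. The
#' asymptote is the susceptibility itself, so kill never exceeds 1. Grasses
#' carry high susceptibility but regrow within a season; trees lose FPC
#' durably.
#'
#' @param intensity Fireline intensity, kW m^-1.
#' @param susceptibility Per-PFT susceptibility in `[0, 1]`.
#' @param i_half Intensity of half-maximal mortality, kW m^-1.
#' @return Kill fraction in `[0, 1]`.
#' @export
fire_mortality <- function(intensity, susceptibility, i_half = fire_params()$i_half) {
  if (any(intensity < 0)) stop("`intensity` must be non-negative", call. = FALSE)
  if (any(susceptibility < 0 | susceptibility > 1)) {
    stop("`susceptibility` must lie in [0, 1]", call. = FALSE)
  }
  susceptibility * intensity / (intensity + i_half)
}
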