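# Oxygen dependence of flammability: probability of ignition, moisture of
# extinction and heat of combustion, all normalised at the present atmospheric
# level (PAL, 20.95% vol O2).

check_o2 <- function(o2, lower = O2_RANGE[1], upper = O2_RANGE[2]) {
  if (!is.numeric(o2) || length(o2) == 0 || anyNA(o2)) {
    stop("`o2` must be numeric and non-missing", call. = FALSE)
  }
  if (any(o2 < lower | o2 > upper)) {
    stop(sprintf(
      "`o2` must lie in [%g, %g] %% vol; combustion data are not extrapolated outside this range",
      lower, upper
    ), call. = FALSE)
  }
  invisible(o2)
}

# polynomial coefficients of the ignition-probability surface:
# PI(o2, m) = pi_lnm_coef(o2) * ln(m) + pi_const_coef(o2)
pi_lnm_coef <- function(o2) {
  308.02 - 27.406 * o2 + 0.634 * o2^2 - 0.0044 * o2^3
}

pi_const_coef <- function(o2) {
  -633.54 + 42.327 * o2 - 0.2194 * o2^2 - 0.0075 * o2^3
}

#' Probability of ignition as a function of oxygen and fuel moisture
#'
#' Rating (in %) of the likelihood that a lightning stroke ignites a
#' successful fire in dead, fine fuel, as an empirical function of the
#' atmospheric oxygen mixing ratio and the fuel moisture content. The
#' underlying combustion-experiment fit is a cubic polynomial in oxygen for
#' both the `ln(moisture)` slope and the intercept. Being an empirical fit it
#' can stray outside `[0, 100]` at extreme inputs, so the returned rating is
#' clamped to that interval.
#'
#' @param o2 Atmospheric oxygen, % by volume. Must lie in `[16, 35]`, the
#'   validated range of the combustion experiments; values outside raise an
#'   error rather than extrapolating.
#' @param moisture Fuel moisture content, % of dry mass; must be strictly
#'   positive (the fit is logarithmic in moisture). May exceed 100% (live or
#'   soaked fuels hold more water than their own dry mass).
#'
#' @return Numeric vector (or array, matching the shape of the recycled
#'   inputs) of ignition probabilities in `[0, 100]`.
#'
#' @details At `moisture = 1` the logarithm vanishes and the rating equals the
#' oxygen-only intercept. At PAL (20.95% vol) the rating reaches zero near
#' 22.3% moisture; wetter fuels are unignitable at PAL but become ignitable as
#' oxygen rises, which is exactly the behaviour the normalised scaling in
#' [ignition_scaling()] propagates into the fire engine.
#'
#' @seealso [ignition_scaling()], [moisture_of_extinction()]
#' @export
#' @examples
#' ignition_probability(20.95, c(1, 5, 10, 20))
#' ignition_probability(35, 20) # far more ignitable under high oxygen
ignition_probability <- function(o2, moisture) {
  check_o2(o2)
  if (!is.numeric(moisture) || anyNA(moisture) || any(moisture <= 0)) {
    stop("`moisture` must be positive (% of dry mass); the fit is logarithmic in moisture",
      call. = FALSE
    )
  }
  raw <- pi_lnm_coef(o2) * log(moisture) + pi_const_coef(o2)
  pmin(pmax(raw, 0), 100)
}

# moisture (%) at which the PAL ignition-probability rating equals `pi_floor`;
# used to keep the PAL normalisation away from its zero crossing (~22.3%)
ignition_moisture_cap <- function(pi_floor = 1) {
  if (!is.numeric(pi_floor) || length(pi_floor) != 1 || pi_floor <= 0 ||
    pi_floor >= pi_const_coef(PAL_O2)) {
    stop("`pi_floor` must be a single value in (0, PI(20.95, 1))", call. = FALSE)
  }
  exp((pi_floor - pi_const_coef(PAL_O2)) / pi_lnm_coef(PAL_O2))
}

#' Oxygen scaling of ignition efficiency
#'
#' Dimensionless factor `PI(o2, m) / PI(20.95, m)` by which the prescribed
#' ignition efficiency of a plant functional type is multiplied to account
#' for the oxygen dependence of ignition. The factor is exactly 1 at PAL.
#' Applied with the 1-h/live-grass moisture for grass fuels and with the
#' woody fuel moisture for woody fuels.
#'
#' @inheritParams ignition_probability
#' @param pi_floor Smallest PAL ignition rating (in rating points) admitted in
#'   the denominator. The PAL rating crosses zero near 22.3% moisture, where a
#'   naive ratio diverges; moistures beyond the corresponding cap (about 21.5%
#'   for the default floor of one rating point, roughly the resolution below
#'   which the empirical rating is indistinguishable from zero) are evaluated
#'   at the cap instead, so very wet fuels receive the largest finite scaling
#'   (about 64 at 35% O2) rather than an unbounded one.
#'
#' @return Numeric vector of non-negative scaling factors; exactly 1 when
#'   `o2 = 20.95` for any valid moisture.
#' @seealso [scale_pft_ignition()] for applying the factor per PFT.
#' @export
#' @examples
#' ignition_scaling(20.95, 15) # 1 by construction
#' ignition_scaling(c(25, 30, 35), 15) # rises steeply with oxygen
ignition_scaling <- function(o2, moisture, pi_floor = 1) {
  check_o2(o2)
  if (!is.numeric(moisture) || anyNA(moisture) || any(moisture <= 0)) {
    stop("`moisture` must be positive (% of dry mass)", call. = FALSE)
  }
  m_cap <- ignition_moisture_cap(pi_floor)
  m_used <- pmin(moisture, m_cap)
  ignition_probability(o2, m_used) / ignition_probability(PAL_O2, m_used)
}

#' Scale per-PFT ignition efficiencies by growth form
#'
#' Grass fuels respond to oxygen through the fast (1-h + live grass) fuel
#' moisture and woody fuels through the woody fuel moisture, so the two
#' growth forms carry distinct oxygen scaling factors.
#'
#' @param ieff Base ignition efficiency per PFT, in `[0, 1]`.
#' @param form Character or factor, `"grass"` or `"tree"`, recycled against
#'   `ieff`.
#' @param s_grass,s_woody Non-negative oxygen scaling factors for grass and
#'   woody fuels (see [ignition_scaling()]).
#' @return Scaled per-PFT ignition efficiencies.
#' @export
#' @examples
#' scale_pft_ignition(c(0.5, 0.2), c("tree", "grass"), s_grass = 2, s_woody = 3)
scale_pft_ignition <- function(ieff, form, s_grass, s_woody) {
  if (any(ieff < 0 | ieff > 1)) stop("`ieff` must lie in [0, 1]", call. = FALSE)
  form <- as.character(form)
  if (!all(form %in% c("grass", "tree"))) {
    stop('`form` must be "grass" or "tree"', call. = FALSE)
  }
  if (any(s_grass < 0) || any(s_woody < 0)) {
    stop("scaling factors must be non-negative", call. = FALSE)
  }
  ifelse(form == "grass", ieff * s_grass, ieff * s_woody)
}

#' FPC-weighted average of a per-PFT quantity
#'
#' Average of a per-PFT quantity weighted by foliar projective cover (FPC),
#' used both for the grid-cell ignition efficiency and for the grid-cell heat
#' of combustion.
#'
#' @param fpc Non-negative per-PFT foliar projective cover.
#' @param values Per-PFT quantity, same length as `fpc`.
#' @return The weighted mean, or `NA_real_` when total cover is zero (bare
#'   ground: the caller must treat the cell as non-flammable rather than
#'   propagate the missing value into fire behaviour).
#' @export
#' @examples
#' fpc_weighted_average(c(0.6, 0.3), c(17500, 16500))
fpc_weighted_average <- function(fpc, values) {
  if (length(fpc) != length(values)) {
    stop("`fpc` and `values` must have the same length", call. = FALSE)
  }
  if (anyNA(fpc) || any(fpc < 0)) stop("`fpc` must be non-negative", call. = FALSE)
  total <- sum(fpc)
  if (total <= 0) {
    return(NA_real_)
  }
  sum(fpc * values) / total
}

#' Overall ignition efficiency of a grid cell
#'
#' Triple product of the fire danger index, the vegetation-weighted ignition
#' efficiency and the burned-area attenuation factor.
#'
#' @param fdi Fire danger index in `[0, 1]`.
#' @param ieff_avg FPC-weighted ignition efficiency (may exceed 1 under high
#'   oxygen).
#' @param ieff_bf Burned-area attenuation in `[0, 1]`: one minus the fraction
#'   of the cell already burned this calendar year.
#' @return `fdi * ieff_avg * ieff_bf`.
#' @export
overall_ignition_efficiency <- function(fdi, ieff_avg, ieff_bf) {
  for (x in list(fdi, ieff_avg, ieff_bf)) {
    if (any(!is.finite(x)) || any(x < 0)) {
      stop("all factors must be finite and non-negative", call. = FALSE)
    }
  }
  fdi * ieff_avg * ieff_bf
}

#' Moisture of extinction as a function of oxygen
#'
#' Fuel moisture content (% of dry mass) above which a spreading fire cannot
#' be sustained, rising linearly with atmospheric oxygen:
#' `Me = 8 * o2 - 128`. The line crosses zero at 16% vol O2, consistent with
#' combustion experiments in which dry fuels fail to ignite below roughly
#' 17% vol; values of `o2` below 16 raise an error. At high oxygen the
#' moisture of extinction exceeds 100% (152% at 35% vol), which is physical:
#' moisture on a dry-mass basis is unbounded above.
#'
#' @inheritParams ignition_probability
#' @return Moisture of extinction, % of dry mass.
#' @export
#' @examples
#' moisture_of_extinction(c(16, 20.95, 35))
moisture_of_extinction <- function(o2) {
  check_o2(o2)
  8 * o2 - 128
}

#' Oxygen scaling of the moisture of extinction
#'
#' `Me(o2) / Me(20.95)`, the dimensionless factor applied to each fuel
#' class's native (PAL) moisture-of-extinction constant in the spread model.
#' Equal to 1 at PAL and strictly increasing in oxygen.
#'
#' @inheritParams ignition_probability
#' @return Dimensionless scaling factor.
#' @export
#' @examples
#' moisture_extinction_scaling(35) # 152 / 39.6
moisture_extinction_scaling <- function(o2) {
  moisture_of_extinction(o2) / moisture_of_extinction(PAL_O2)
}

#' Per-PFT heat of combustion as a function of oxygen
#'
#' Heat released per unit mass of fuel burned, `h = alpha / o2 + beta`
#' (kJ kg^-1). `beta` is the asymptotic, complete-combustion heat content
#' approached as oxygen becomes abundant; with `alpha < 0` the heat released
#' in a natural fire rises toward `beta` as oxygen increases, reflecting more
#' complete combustion. Grid-cell averages are formed with
#' [fpc_weighted_average()], replacing the legacy single constant of
#' 18,000 kJ kg^-1.
#'
#' @param o2 Atmospheric oxygen, % by volume; must be positive.
#' @param alpha Hyperbolic coefficient, kJ kg^-1 (% O2).
#' @param beta Asymptotic heat of combustion, kJ kg^-1; must be positive.
#' @return Heat of combustion, kJ kg^-1.
#' @export
#' @examples
#' heat_of_combustion(20.95, alpha = -52375, beta = 20000) # 17,500 at PAL
heat_of_combustion <- function(o2, alpha, beta) {
  if (any(o2 <= 0)) stop("`o2` must be positive", call. = FALSE)
  if (any(beta <= 0)) stop("`beta` must be positive", call. = FALSE)
  h <- alpha / o2 + beta
  if (any(h <= 0)) {
    stop("heat of combustion is non-positive: `alpha`/`beta` are inconsistent",
      call. = FALSE
    )
  }
  h
}
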