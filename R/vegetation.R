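# Minimal PFT population layer: bioclimatic filtering, logistic growth toward
# climate-set carrying capacities, fire mortality, and a fire-off mode used as
# the no-fire baseline of the suppression metric.

#' Default plant functional type parameters
#'
#' Nine PFTs (2 tropical trees, 3 temperate trees, 2 boreal trees, 2 grasses)
#' with LPJ-family bioclimatic limits, base ignition efficiencies, heat-of-
#' combustion coefficients, fuel bulk densities, fire susceptibilities and
#' regrowth rates. The heat-of-combustion coefficients follow the scheme
#' `alpha = (h_PAL - beta) * 20.95` with `beta` a complete-combustion value
#' per growth form (trees 20,000, grasses 18,500 kJ/kg) and `h_PAL` the
#' natural-fire heat at present oxygen (trees 17,500, grasses
#' 16,500 kJ/kg), so heat released rises toward `beta` with oxygen. All
#' values are config-exposed placeholders in the sense that no single
#' authoritative source prescribes them; see the package vignette.
#'
#' @return A tibble with one row per PFT: `name`, `form` ("tree"/"grass"),
#'   `tc_min`/`tc_max` (coldest-month mean temperature limits, deg C),
#'   `gdd_min` (growing degree days base 5 deg C), `ieff` (base ignition
#'   efficiency), `alpha`/`beta` (heat-of-combustion coefficients, kJ/kg),
#'   `bulk_density` (kg/m3), `susceptibility` (fire mortality), `regrowth`
#'   (logistic rate, yr^-1).
#' @export
default_pfts <- function() {
  tree_alpha <- (17500 - 20000) * PAL_O2
  grass_alpha <- (16500 - 18500) * PAL_O2
  tibble::tribble(
    ~name, ~form, ~tc_min, ~tc_max, ~gdd_min, ~ieff, ~bulk_density, ~susceptibility, ~regrowth,
    "tropical_broadleaf_evergreen", "tree", 15.5, Inf, 0, 0.10, 22, 0.30, 0.06,
    "tropical_broadleaf_raingreen", "tree", 15.5, Inf, 0, 0.25, 18, 0.45, 0.06,
    "temperate_needleleaf_evergreen", "tree", -2, 22, 900, 0.35, 18, 0.45, 0.04,
    "temperate_broadleaf_evergreen", "tree", 3, 18.8, 1200, 0.15, 20, 0.85, 0.04,
    "temperate_broadleaf_summergreen", "tree", -17, 15.5, 1200, 0.20, 20, 0.45, 0.04,
    "boreal_needleleaf_evergreen", "tree", -32.5, -2, 600, 0.35, 18, 0.30, 0.04,
    "boreal_summergreen", "tree", -Inf, -2, 600, 0.35, 17, 0.30, 0.04,
    "c3_grass", "grass", -Inf, 15.5, 0, 0.15, 1.2, 0.90, 3.0,
    "c4_grass", "grass", 15.5, Inf, 0, 0.55, 1.2, 0.90, 3.0
  ) |>
    dplyr::mutate(
      alpha = ifelse(.data$form == "tree", tree_alpha, grass_alpha),
      beta = ifelse(.data$form == "tree", 20000, 18500),
      fine_prod = ifelse(.data$form == "grass",
        fire_params()$fine_prod_grass, fire_params()$fine_prod_tree
      ),
      woody_prod = ifelse(.data$form == "tree", fire_params()$woody_prod_tree, 0)
    )
}

validate_pfts <- function(pfts) {
  stopifnot(is.data.frame(pfts), nrow(pfts) == 9)
  if (sum(pfts$form == "grass") != 2 || sum(pfts$form == "tree") != 7) {
    stop("expected 7 tree PFTs and 2 grass PFTs", call. = FALSE)
  }
  invisible(pfts)
}

# exact annual step of continuous-time logistic growth toward carrying
# capacity K at rate r; composes exactly, so iterating matches the closed form
logistic_step <- function(x, k, r) {
  out <- ifelse(k > 1e-12,
    k * x * exp(r) / (k + x * (exp(r) - 1)),
    x * exp(-r)
  )
  pmax(out, 0)
}

ramp <- function(x, bounds) {
  pmin(pmax((x - bounds[1]) / (bounds[2] - bounds[1]), 0), 1)
}

#' Annual climate summaries from daily forcing
#'
#' Per cell and year: growing degree days above 5 deg C, coldest ~30-day
#' month mean temperature, annual precipitation and a crude evaporative
#' demand (`k_pet` mm per positive degree day), from which the moisture
#' index `precip / pet` drives the carrying capacities.
#'
#' @param forcing A forcing tibble (see [generate_forcing()]).
#' @param params See [fire_params()].
#' @return Tibble with one row per `cell` x `year`: `gdd5`, `t_cold`,
#'   `precip`, `pet`, `mi`.
#' @export
climate_summary <- function(forcing, params = fire_params()) {
  forcing |>
    dplyr::mutate(month = pmin((.data$doy - 1) %/% 31 + 1, 12)) |>
    dplyr::group_by(.data$cell, .data$year) |>
    dplyr::summarise(
      gdd5 = sum(pmax(.data$temp - 5, 0)),
      t_cold = min(tapply(.data$temp, .data$month, mean)),
      precip = sum(.data$prec),
      pet = params$k_pet * sum(pmax(.data$temp, 0)),
      .groups = "drop"
    ) |>
    dplyr::mutate(mi = .data$precip / pmax(.data$pet, 1))
}

#' Carrying capacities from the moisture index
#'
#' Trees require a moist climate (linear ramp of the moisture index between
#' `tree_mi`); grasses tolerate semi-arid climates (`grass_mi` ramp) and are
#' additionally limited to the space trees leave.
#'
#' @param mi Moisture index, annual precipitation over evaporative demand.
#' @param params See [fire_params()].
#' @return A list with numeric vectors `tree` and `grass` (potential FPC).
#' @export
carrying_capacity <- function(mi, params = fire_params()) {
  list(
    tree = params$k_tree_max * ramp(mi, params$tree_mi),
    grass = params$k_grass_max * ramp(mi, params$grass_mi)
  )
}

# eligibility of each PFT (rows) in each cell (columns)
pft_eligibility <- function(pfts, t_cold, gdd5) {
  ncell <- length(t_cold)
  el <- matrix(FALSE, nrow(pfts), ncell)
  for (i in seq_len(nrow(pfts))) {
    el[i, ] <- t_cold >= pfts$tc_min[i] & t_cold <= pfts$tc_max[i] &
      gdd5 >= pfts$gdd_min[i]
  }
  el
}

# guild-level logistic update distributed proportionally over eligible members
grow_guild <- function(fpc, members, eligible, k, r_pft, params) {
  ncell <- ncol(fpc)
  el <- eligible & matrix(members, nrow(eligible), ncell)
  # establishment seed for eligible members of a viable guild
  seed_mask <- el & fpc < params$seed_fpc & matrix(k > 0, nrow(el), ncell, byrow = TRUE)
  fpc[seed_mask] <- params$seed_fpc
  tot <- colSums(fpc * el)
  r_bar <- ifelse(tot > 0, colSums(fpc * el * r_pft) / tot, 0)
  new_tot <- logistic_step(tot, k, r_bar)
  factor <- ifelse(tot > 0, new_tot / tot, 1)
  fpc * ifelse(el, rep(factor, each = nrow(fpc)), 1)
}

#' Annual establishment and growth of PFTs
#'
#' PFTs inside their bioclimatic limits grow logistically toward the cell's
#' climate-set carrying capacity (trees pre-empt space; grasses fill what
#' remains), using the exact annual step of the continuous logistic so a
#' constant-climate trajectory matches the closed-form solution. PFTs
#' outside their limits decay. Total FPC never exceeds `fpc_space`.
#'
#' @param fpc Matrix of FPC, PFTs in rows, cells in columns (a plain vector
#'   is treated as a single cell).
#' @param pfts PFT table, see [default_pfts()].
#' @param climate List or tibble with per-cell `t_cold`, `gdd5`, `mi`.
#' @param params See [fire_params()].
#' @return Updated FPC matrix of the same shape.
#' @export
establishment_and_growth <- function(fpc, pfts, climate, params = fire_params()) {
  validate_pfts(pfts)
  vec_in <- is.null(dim(fpc))
  if (vec_in) fpc <- matrix(fpc, ncol = 1)
  stopifnot(nrow(fpc) == nrow(pfts))
  el <- pft_eligibility(pfts, climate$t_cold, climate$gdd5)
  caps <- carrying_capacity(climate$mi, params)
  is_tree <- pfts$form == "tree"

  fpc <- grow_guild(fpc, is_tree, el, caps$tree, pfts$regrowth, params)
  tree_tot <- colSums(fpc * is_tree)
  k_grass <- pmin(caps$grass, pmax(params$fpc_space - tree_tot, 0))
  fpc <- grow_guild(fpc, !is_tree, el, k_grass, pfts$regrowth, params)

  # decay outside bioclimatic limits
  fpc <- fpc * ifelse(el, 1, 1 - params$decay_excluded)

  # numerical guard: total cover can never exceed the available space
  tot <- colSums(fpc)
  over <- tot > params$fpc_space
  if (any(over)) {
    fpc[, over] <- fpc[, over, drop = FALSE] *
      rep(params$fpc_space / tot[over], each = nrow(fpc))
  }
  if (vec_in) fpc[, 1] else fpc
}

#' Apply fire mortality to FPC
#'
#' `fpc <- fpc * (1 - kill * burned_fraction)`: only the burned part of the
#' cell loses cover, in proportion to the kill fraction.
#'
#' @param fpc FPC matrix (PFTs x cells) or vector.
#' @param kill Kill fraction per PFT (and cell), in `[0, 1]`; recycled.
#' @param burned_fraction Fraction of each cell burned this year, `[0, 1]`.
#' @return Updated FPC of the same shape.
#' @export
apply_fire_mortality <- function(fpc, kill, burned_fraction) {
  if (any(kill < 0 | kill > 1)) stop("`kill` must lie in [0, 1]", call. = FALSE)
  if (any(burned_fraction < 0 | burned_fraction > 1)) {
    stop("`burned_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(dim(fpc))) {
    return(fpc * (1 - kill * burned_fraction))
  }
  fpc * (1 - kill * rep(burned_fraction, each = nrow(fpc)))
}
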