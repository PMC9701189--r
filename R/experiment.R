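# Experiment driver: oxygen sweep with a no-fire baseline, global
# diagnostics (fire counts, burned area, tree and forest cover, suppression)
# and the moisture-band rate-of-spread analysis.

default_o2_levels <- function() c(PAL_O2, 21:35)

#' Run the oxygen-sweep experiment
#'
#' Spins up the fire-vegetation system once per oxygen level (and once with
#' fire disabled), all under identical seeded forcing, and averages the final
#' `out_years` years into per-level global diagnostics: total fires and
#' burned area per year, global tree cover, forest cover (area with tree
#' cover above 60%), the forest-suppression metric relative to the no-fire
#' baseline, and mean rate of spread per fuel-moisture band. Global totals
#' are area-weighted (cell areas from the spherical grid, proportional to
#' the cosine of latitude).
#'
#' @param world World configuration, see [world_config()]; its `years` field
#'   is ignored in favour of `spinup_years`. Defaults to the desk-scale
#'   [mini_world_config()]; note that a full 10-degree global grid over a
#'   200-year spin-up holds several gigabytes of daily fields in memory.
#' @param o2_levels Oxygen levels to sweep, % vol within `[20.95, 35]`.
#' @param spinup_years Total simulated years per level; the last `out_years`
#'   are analysed. The default 200 is a desk-scale reduction of a much
#'   longer equilibration; a drift check warns when the final decades still
#'   trend.
#' @param out_years Averaging window, years.
#' @param pfts,params See [default_pfts()] and [fire_params()].
#' @param bands Fuel-moisture band edges (% dry mass) for the
#'   rate-of-spread analysis.
#' @param forcing Optional pre-built forcing (overrides `world`).
#' @return An object of class `oxfire_sweep` with elements `summary` (one
#'   row per oxygen level), `cells` (per-level per-cell diagnostics),
#'   `bands` (per-level per-band mean rate of spread), `baseline` (the
#'   no-fire run summary row), `log` (per-level drift diagnostics).
#' @export
#' @examples
#' \donttest{
#' sw <- run_experiment(mini_world_config(), spinup_years = 60,
#'   o2_levels = c(20.95, 28, 35))
#' tidy(sw)
#' }
run_experiment <- function(world = mini_world_config(), o2_levels = default_o2_levels(),
                           spinup_years = 200, out_years = 10,
                           pfts = default_pfts(), params = fire_params(),
                           bands = c(20, 40, 60), forcing = NULL) {
  if (any(o2_levels < PAL_O2 | o2_levels > O2_RANGE[2])) {
    stop("`o2_levels` must lie within [20.95, 35] %% vol", call. = FALSE)
  }
  o2_levels <- sort(unique(o2_levels))
  if (is.null(forcing)) {
    world$years <- as.integer(spinup_years)
    forcing <- generate_forcing(world)
  }
  fm <- forcing_matrices(forcing)
  cache <- precompute_forcing(fm, params)

  runs <- purrr::map(o2_levels, function(o2) {
    simulate_world(fm, o2 = o2, pfts = pfts, params = params,
      fire = TRUE, oxygen = TRUE, out_years = out_years, cache = cache)
  })
  base_run <- simulate_world(fm, o2 = PAL_O2, pfts = pfts, params = params,
    fire = FALSE, oxygen = TRUE, out_years = out_years, cache = cache)

  summarise_run <- function(run) {
    c0 <- run$cells
    area <- c0$area_km2
    tibble::tibble(
      fires_per_yr = sum(c0$fires_per_yr),
      burned_area_km2 = sum(c0$burned_frac_per_yr * area),
      tree_cover = sum(c0$tree_cover * area) / sum(area),
      forest_area_km2 = sum(area[c0$forest]),
      mean_ros = sum(c0$mean_ros * area) / sum(area)
    )
  }

  base_summary <- summarise_run(base_run)
  summary <- purrr::map2(runs, o2_levels, function(run, o2) {
    dplyr::mutate(summarise_run(run), o2 = o2, .before = 1)
  }) |>
    purrr::list_rbind() |>
    dplyr::mutate(
      suppression = suppression_metric(.data$forest_area_km2,
        base_summary$forest_area_km2)
    )

  cells <- purrr::map2(runs, o2_levels, function(run, o2) {
    dplyr::mutate(run$cells, o2 = o2, .before = 1)
  }) |>
    purrr::list_rbind()

  out <- structure(
    list(
      summary = summary,
      cells = cells,
      baseline = dplyr::mutate(base_summary,
        cells = list(base_run$cells), .before = 1),
      bands = NULL,
      band_edges = bands,
      o2_levels = o2_levels,
      out_years = out_years,
      spinup_years = fm$nyears,
      log = tibble::tibble(
        o2 = c(o2_levels, NA),
        fire = c(rep(TRUE, length(o2_levels)), FALSE),
        tree_cover_drift = c(purrr::map_dbl(runs, "drift"), base_run$drift)
      )
    ),
    class = "oxfire_sweep"
  )
  out$bands <- moisture_band_analysis(out)
  out
}

#' Forest-suppression metric
#'
#' Percentage decrease of forest cover relative to a world without fire:
#' `100 * (1 - cover / cover_no_fire)`, floored at zero. The no-fire
#' reference itself maps to exactly 0.
#'
#' @param forest_cover Forest cover (area or fraction) per oxygen level.
#' @param forest_cover_no_fire Forest cover of the fire-off baseline; must
#'   be positive.
#' @return Suppression, % in `[0, 100]`.
#' @export
#' @examples
#' suppression_metric(c(8, 6, 4), 8)
suppression_metric <- function(forest_cover, forest_cover_no_fire) {
  if (!is.numeric(forest_cover_no_fire) || length(forest_cover_no_fire) != 1 ||
    is.na(forest_cover_no_fire) || forest_cover_no_fire <= 0) {
    stop("no-fire forest cover must be a single positive value; the suppression metric is undefined otherwise",
      call. = FALSE
    )
  }
  if (any(forest_cover < 0)) stop("`forest_cover` must be non-negative", call. = FALSE)
  pmax(100 * (1 - forest_cover / forest_cover_no_fire), 0)
}

#' Mean rate of spread per fuel-moisture band
#'
#' Bins cells by their 10-year-mean fuel moisture into the configured bands
#' (default `<20`, `20-40`, `40-60`, `>60` % dry mass; the moisture
#' diagnostic depends only on the forcing, so every cell falls in the same
#' band at every oxygen level) and tabulates the area-weighted mean rate of
#' spread per band against oxygen. A cell's rate of spread is that of the
#' fires that actually burned it (burned-area weighted); cells that never
#' burn contribute zero, as in gridded fire-model output. The change column `ros_change_rel_pal`
#' expresses each band's change since PAL relative to the global PAL mean
#' rate of spread — a common denominator, since bands too wet to carry fire
#' at PAL have no spread of their own to normalise by. Empty bands are
#' reported as missing (`NA`), not zero.
#'
#' @param x An `oxfire_sweep` object, or its `cells` tibble (columns `o2`,
#'   `fuel_moisture`, `mean_ros`, `area_km2`).
#' @param bands Band edges, % dry mass.
#' @return Tibble with one row per band x oxygen level: `band`, `o2`,
#'   `n_cells`, `mean_ros`, `ros_change_rel_pal`.
#' @export
moisture_band_analysis <- function(x, bands = c(20, 40, 60)) {
  cells <- if (inherits(x, "oxfire_sweep")) {
    bands <- x$band_edges
    x$cells
  } else {
    x
  }
  edges <- c(-Inf, bands, Inf)
  labels <- band_labels(bands)
  cells <- dplyr::mutate(cells,
    band = cut(.data$fuel_moisture, breaks = edges, labels = labels, right = FALSE)
  )
  full <- tidyr::expand_grid(band = factor(labels, levels = labels),
    o2 = sort(unique(cells$o2)))
  per_band <- cells |>
    dplyr::group_by(.data$band, .data$o2) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      mean_ros = sum(.data$mean_ros * .data$area_km2) / sum(.data$area_km2),
      .groups = "drop"
    )
  global_pal <- cells |>
    dplyr::filter(.data$o2 == min(.data$o2)) |>
    dplyr::summarise(g = sum(.data$mean_ros * .data$area_km2) / sum(.data$area_km2)) |>
    dplyr::pull(.data$g)
  pal <- per_band |>
    dplyr::filter(.data$o2 == min(.data$o2)) |>
    dplyr::select("band", ros_pal = "mean_ros")
  full |>
    dplyr::left_join(per_band, by = c("band", "o2")) |>
    dplyr::left_join(pal, by = "band") |>
    dplyr::mutate(
      n_cells = dplyr::coalesce(.data$n_cells, 0L),
      ros_change_rel_pal = ifelse(.data$n_cells > 0,
        (.data$mean_ros - .data$ros_pal) / global_pal, NA_real_)
    ) |>
    dplyr::select(-"ros_pal")
}

band_labels <- function(bands) {
  c(
    paste0("<", bands[1]),
    paste0(bands[-length(bands)], "-", bands[-1]),
    paste0(">", bands[length(bands)])
  )
}

#' @export
print.oxfire_sweep <- function(x, ...) {
  cat(sprintf(
    "<oxfire_sweep> %d oxygen levels (%.2f-%.2f%% vol) + no-fire baseline\n",
    length(x$o2_levels), min(x$o2_levels), max(x$o2_levels)
  ))
  cat(sprintf("  %d-yr runs, final %d-yr means\n", x$spinup_years, x$out_years))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Tidy an oxygen sweep
#'
#' @param x An `oxfire_sweep` object.
#' @param ... Unused.
#' @return The per-level summary tibble: one row per oxygen level with fire
#'   counts, burned area, tree/forest cover and suppression.
#' @export
tidy.oxfire_sweep <- function(x, ...) {
  x$summary
}

#' One-row summary of an oxygen sweep
#'
#' @param x An `oxfire_sweep` object.
#' @param ... Unused.
#' @return A one-row tibble: number of levels, fire-count and burned-area
#'   ratios between the top and bottom of the sweep, suppression at PAL and
#'   at the top level, and the no-fire forest area.
#' @export
glance.oxfire_sweep <- function(x, ...) {
  s <- x$summary
  lo <- s[which.min(s$o2), ]
  hi <- s[which.max(s$o2), ]
  tibble::tibble(
    n_levels = nrow(s),
    o2_min = lo$o2, o2_max = hi$o2,
    fire_count_ratio = hi$fires_per_yr / lo$fires_per_yr,
    burned_area_ratio = hi$burned_area_km2 / lo$burned_area_km2,
    suppression_pal = lo$suppression,
    suppression_max = hi$suppression,
    forest_area_no_fire_km2 = x$baseline$forest_area_km2
  )
}

#' Plot an oxygen sweep
#'
#' @param object An `oxfire_sweep` object.
#' @param type `"sweep"` (fire counts and burned area vs oxygen, each
#'   normalised to PAL), `"suppression"`, or `"bands"` (mean rate of spread
#'   per fuel-moisture band).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oxfire_sweep <- function(object, type = c("sweep", "suppression", "bands"),
                                  ...) {
  type <- match.arg(type)
  s <- object$summary
  if (type == "sweep") {
    dat <- s |>
      dplyr::transmute(
        o2 = .data$o2,
        `number of fires` = .data$fires_per_yr / .data$fires_per_yr[1],
        `burned area` = .data$burned_area_km2 / .data$burned_area_km2[1]
      ) |>
      tidyr::pivot_longer(-"o2", names_to = "series")
    ggplot2::ggplot(dat, ggplot2::aes(.data$o2, .data$value,
      linetype = .data$series)) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "atmospheric oxygen (% vol)",
        y = "relative to present atmospheric level",
        linetype = NULL
      )
  } else if (type == "suppression") {
    ggplot2::ggplot(s, ggplot2::aes(.data$o2, .data$suppression)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(
        x = "atmospheric oxygen (% vol)",
        y = "forest-cover suppression vs no-fire world (%)"
      )
  } else {
    ggplot2::ggplot(
      dplyr::filter(object$bands, .data$n_cells > 0),
      ggplot2::aes(.data$o2, .data$mean_ros, colour = .data$band)
    ) +
      ggplot2::geom_line() +
      ggplot2::labs(
        x = "atmospheric oxygen (% vol)",
        y = "mean rate of spread (m/min)",
        colour = "fuel moisture (%)"
      )
  }
}

#' Write sweep outputs to a directory
#'
#' Writes `summary.csv` (one row per oxygen level), `bands.csv`, `cells.csv`
#' (long-format gridded per-level maps: latitude, longitude, tree cover,
#' rate of spread, burned fraction, fuel moisture), `baseline_cells.csv`
#' and `run_log.csv`.
#'
#' @param sweep An `oxfire_sweep` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sweep_outputs <- function(sweep, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(sweep$summary, file.path(dir, "summary.csv"), row.names = FALSE)
  write.csv(sweep$bands, file.path(dir, "bands.csv"), row.names = FALSE)
  write.csv(sweep$cells, file.path(dir, "cells.csv"), row.names = FALSE)
  write.csv(sweep$baseline$cells[[1]], file.path(dir, "baseline_cells.csv"),
    row.names = FALSE)
  write.csv(sweep$log, file.path(dir, "run_log.csv"), row.names = FALSE)
  invisible(dir)
}
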