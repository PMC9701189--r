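test_that("the suppression metric is the floored percentage decrease", {
  expect_equal(suppression_metric(8, 8), 0)
  expect_equal(suppression_metric(4, 8), 50)
  expect_equal(suppression_metric(c(8, 6, 0), 8), c(0, 25, 100))
  expect_equal(suppression_metric(10, 8), 0) # floored at zero
  expect_error(suppression_metric(5, 0), "undefined")
  expect_error(suppression_metric(-1, 8), "non-negative")
})

test_that("moisture banding partitions every cell exactly once", {
  cells <- tidyr::expand_grid(
    o2 = c(20.95, 35),
    tibble::tibble(
      cell = 1:8,
      fuel_moisture = c(5, 19.9, 20, 39.9, 40, 59, 60.1, 140),
      mean_ros = runif(8, 0, 10),
      area_km2 = runif(8, 1, 2) * 1e6
    )
  )
  bands <- moisture_band_analysis(cells, bands = c(20, 40, 60))
  expect_equal(sum(bands$n_cells[bands$o2 == 35]), 8)
  # matches an independent histogram of band membership
  want <- as.integer(table(cut(c(5, 19.9, 20, 39.9, 40, 59, 60.1, 140),
    c(-Inf, 20, 40, 60, Inf),
    right = FALSE
  )))
  expect_equal(bands$n_cells[bands$o2 == 35], want)
  # area-weighted band mean equals a direct computation
  sub <- cells[cells$o2 == 35 & cells$fuel_moisture < 20, ]
  expect_equal(
    bands$mean_ros[bands$o2 == 35 & bands$band == "<20"],
    sum(sub$mean_ros * sub$area_km2) / sum(sub$area_km2)
  )
})

test_that("empty bands are reported as missing, not zero", {
  cells <- tidyr::expand_grid(
    o2 = c(20.95, 35),
    tibble::tibble(cell = 1:2, fuel_moisture = c(5, 10), mean_ros = 1, area_km2 = 1)
  )
  bands <- moisture_band_analysis(cells)
  expect_true(all(is.na(bands$mean_ros[bands$band != "<20"])))
  expect_equal(bands$n_cells[bands$band == ">60"], c(0L, 0L))
})

test_that("a small sweep returns coherent tidy, glance and plot objects", {
  sw <- suppressWarnings(run_experiment(
    mini_world_config(),
    o2_levels = c(20.95, 35), spinup_years = 120
  ))
  td <- tidy(sw)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$o2, c(20.95, 35))
  expect_true(all(c("fires_per_yr", "burned_area_km2", "suppression") %in% names(td)))
  gl <- glance(sw)
  expect_equal(nrow(gl), 1)
  expect_gt(gl$fire_count_ratio, 1)
  for (type in c("sweep", "suppression", "bands")) {
    expect_s3_class(autoplot(sw, type = type), "ggplot")
  }
  expect_output(print(sw), "oxygen levels")

  dir <- withr::local_tempdir()
  write_sweep_outputs(sw, dir)
  expect_true(all(file.exists(file.path(
    dir, c("summary.csv", "bands.csv", "cells.csv", "baseline_cells.csv", "run_log.csv")
  ))))
  back <- read.csv(file.path(dir, "summary.csv"))
  expect_equal(back$o2, c(20.95, 35))
})

test_that("sweeps reject oxygen levels outside the validated window", {
  expect_error(run_experiment(o2_levels = c(19, 35)), "20.95")
  expect_error(run_experiment(o2_levels = c(21, 36)), "20.95")
})

test_that("configuration files round-trip and drive the experiment", {
  cfg <- default_config()
  expect_named(cfg, c("world", "pfts", "fire", "experiment"))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$fire$me_fine, cfg$fire$me_fine)
  expect_equal(back$experiment$o2_levels, cfg$experiment$o2_levels)
  expect_equal(length(back$pfts), 9)
  # a partial config falls back to defaults elsewhere
  yaml::write_yaml(list(fire = list(ros_max = 5)), path)
  merged <- read_config(path)
  expect_equal(merged$fire$ros_max, 5)
  expect_equal(merged$fire$me_fine, cfg$fire$me_fine)
  sw <- suppressWarnings(run_experiment_config(
    merged,
    world = mini_world_config(), o2_levels = c(20.95, 30), spinup_years = 120
  ))
  expect_s3_class(sw, "oxfire_sweep")
})
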