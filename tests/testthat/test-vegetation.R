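test_that("the PFT table has the canonical composition", {
  pfts <- default_pfts()
  expect_equal(nrow(pfts), 9)
  expect_equal(sum(pfts$form == "grass"), 2)
  expect_equal(sum(grepl("^tropical", pfts$name)), 2)
  expect_equal(sum(grepl("^temperate", pfts$name)), 3)
  expect_equal(sum(grepl("^boreal", pfts$name)), 2)
  expect_true(all(pfts$ieff >= 0 & pfts$ieff <= 1))
  expect_true(all(pfts$beta > 0))
  # heat at PAL is positive and below the complete-combustion asymptote
  h_pal <- heat_of_combustion(20.95, pfts$alpha, pfts$beta)
  expect_true(all(h_pal > 0 & h_pal < pfts$beta))
})

test_that("growth follows the closed-form logistic on a constant climate", {
  pfts <- default_pfts()
  params <- fire_params()
  # warm, wet tropical cell: only tropical trees and C4 grass are eligible
  climate <- list(t_cold = 26, gdd5 = 9000, mi = 2)
  fpc <- matrix(0, 9, 1)
  fpc[1, 1] <- 0.10 # one tropical tree PFT present
  years <- 60
  traj <- numeric(years)
  x <- fpc
  for (t in seq_len(years)) {
    x <- establishment_and_growth(x, pfts, climate, params)
    traj[t] <- x[1, 1]
  }
  k <- carrying_capacity(2, params)$tree
  # other eligible PFTs only hold seed-level cover, so the guild is one PFT
  want <- oracle_logistic(0.10, k, pfts$regrowth[1], seq_len(years))
  expect_equal(traj, want, tolerance = 0.02)
  # long-run equilibrium is the carrying capacity
  for (t in 1:200) x <- establishment_and_growth(x, pfts, climate, params)
  expect_equal(x[1, 1] + x[2, 1], k, tolerance = 0.01)
})

test_that("PFTs outside their bioclimatic limits decay and cold deserts empty", {
  pfts <- default_pfts()
  params <- fire_params()
  # hyper-arid and frigid: trees fail the bioclimatic filter, grasses the
  # moisture ramp
  climate <- list(t_cold = -45, gdd5 = 100, mi = 0.02)
  fpc <- matrix(0.08, 9, 1)
  for (t in 1:25) fpc <- establishment_and_growth(fpc, pfts, climate, params)
  expect_true(all(fpc < 1e-3))
})

test_that("zero regrowth is a fixed point absent fire", {
  pfts <- default_pfts()
  pfts$regrowth <- 0
  params <- fire_params()
  climate <- list(t_cold = 26, gdd5 = 9000, mi = 2)
  fpc <- matrix(c(0.3, 0.1, rep(0, 6), 0.2), 9, 1)
  out <- establishment_and_growth(fpc, pfts, climate, params)
  # eligible PFTs with zero rate keep their cover (up to seeding of absentees)
  expect_equal(out[1, 1], 0.3)
  expect_equal(out[2, 1], 0.1)
  expect_equal(out[9, 1], 0.2)
})

test_that("total cover never exceeds the available space", {
  pfts <- default_pfts()
  params <- fire_params()
  set.seed(9)
  fpc <- matrix(runif(9 * 5, 0, 0.2), 9, 5)
  climate <- list(
    t_cold = c(26, 10, -5, -20, 18),
    gdd5 = c(9000, 4000, 2500, 900, 6000),
    mi = c(2, 0.6, 1.2, 1.5, 0.15)
  )
  for (t in 1:50) {
    fpc <- establishment_and_growth(fpc, pfts, climate, params)
    expect_true(all(colSums(fpc) <= params$fpc_space + 1e-9))
  }
})

test_that("climate summaries aggregate the forcing per cell and year", {
  cs <- climate_summary(make_fixture("single_cell_wet"))
  expect_equal(nrow(cs), 2) # one cell, two years
  expect_true(all(cs$gdd5 > 7000)) # warm all year at 26 C
  expect_true(all(cs$t_cold > 20))
  expect_equal(cs$precip, rep(6 * 365, 2), tolerance = 0.01)
  expect_true(all(cs$mi > 1)) # wet tropics: moisture index above unity
})

test_that("fire mortality removes cover in proportion to burning", {
  fpc <- matrix(c(0.6, 0.3), 2, 1)
  expect_equal(apply_fire_mortality(fpc, kill = c(0.5, 1), burned_fraction = 0), fpc)
  out <- apply_fire_mortality(fpc, kill = c(1, 1), burned_fraction = 1)
  expect_equal(as.numeric(out), c(0, 0))
  out <- apply_fire_mortality(fpc, kill = matrix(c(0.4, 0.8), 2, 1), burned_fraction = 0.5)
  expect_equal(as.numeric(out), c(0.6 * (1 - 0.2), 0.3 * (1 - 0.4)))
  expect_error(apply_fire_mortality(fpc, kill = 2, burned_fraction = 0.5), "0, 1")
})

test_that("a humid tropical cell reaches forest without fire", {
  pfts <- default_pfts()
  params <- fire_params()
  climate <- list(t_cold = 25, gdd5 = 8000, mi = 1.8)
  fpc <- matrix(0.05, 9, 1)
  for (t in 1:120) fpc <- establishment_and_growth(fpc, pfts, climate, params)
  expect_gt(sum(fpc[pfts$form == "tree", 1]), 0.60)
  # equilibrium equals the climate carrying capacity
  expect_equal(
    sum(fpc[pfts$form == "tree", 1]),
    carrying_capacity(1.8, params)$tree,
    tolerance = 0.01
  )
})
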