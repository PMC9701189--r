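test_that("ignition probability matches the term-by-term oracle and frozen values", {
  expect_equal(ignition_probability(20.95, 1), PI_CONST$pal_m1, tolerance = 1e-12)
  expect_equal(ignition_probability(20.95, 20), PI_CONST$pal_m20, tolerance = 1e-12)
  expect_equal(ignition_probability(20.95, 15), PI_CONST$pal_m15, tolerance = 1e-12)
  expect_equal(ignition_probability(35, 20), PI_CONST$o35_m20, tolerance = 1e-12)
  expect_equal(ignition_probability(25, 20), PI_CONST$o25_m20, tolerance = 1e-12)
  expect_equal(ignition_probability(30, 15), PI_CONST$o30_m15, tolerance = 1e-12)

  grid <- expand.grid(
    o2 = seq(16, 35, length.out = 40),
    m = exp(seq(log(0.5), log(200), length.out = 25))
  )
  got <- ignition_probability(grid$o2, grid$m)
  want <- mapply(oracle_pi, grid$o2, grid$m)
  expect_true(all(abs(got - want) <= 1e-10 * pmax(abs(want), 1)))
})

test_that("ignition probability is clamped to [0, 100] and rejects bad inputs", {
  expect_equal(ignition_probability(20.95, 150), 0) # very wet fuel
  expect_equal(ignition_probability(35, 1), 100) # fit exceeds 100 raw
  expect_error(ignition_probability(15, 10), "16")
  expect_error(ignition_probability(36, 10), "16")
  expect_error(ignition_probability(25, 0), "positive")
  expect_error(ignition_probability(25, -3), "positive")
})

test_that("ignition scaling is exactly 1 at PAL and matches oracle ratios", {
  for (m in c(0.5, 1, 5, 15, 21, 50, 150)) {
    expect_identical(ignition_scaling(20.95, m), 1)
  }
  expect_equal(ignition_scaling(30, 15), PI_CONST$scale_30_15, tolerance = 1e-12)
  expect_equal(ignition_scaling(35, 15), PI_CONST$scale_35_15, tolerance = 1e-12)
  # wet fuels evaluated at the normalisation cap: bounded, positive
  s_wet <- ignition_scaling(35, 150)
  expect_true(is.finite(s_wet) && s_wet > 1)
  expect_error(ignition_scaling(30, 15, pi_floor = 0), "pi_floor")
})

test_that("ignition scaling is non-decreasing in oxygen at fixed moisture", {
  ox <- seq(20.95, 35, by = 0.1)
  for (m in c(5, 12, 15, 21, 40, 120)) {
    s <- ignition_scaling(ox, m)
    expect_true(all(diff(s) >= -1e-12), info = paste("m =", m))
  }
})

test_that("ignition probability is non-increasing in moisture at fixed oxygen", {
  m <- seq(1, 200, by = 0.5)
  for (o2 in c(20.95, 25, 30, 35)) {
    p <- ignition_probability(o2, m)
    expect_true(all(diff(p) <= 1e-12), info = paste("o2 =", o2))
  }
})

test_that("moisture of extinction is the printed linear law", {
  expect_equal(moisture_of_extinction(16), 0)
  expect_equal(moisture_of_extinction(20.95), 39.6)
  expect_equal(moisture_of_extinction(35), 152)
  expect_error(moisture_of_extinction(15.5), "16")
  # exact linearity: Me(a) + Me(b) = 2 Me((a+b)/2)
  a <- runif(50, 16, 35)
  b <- runif(50, 16, 35)
  expect_equal(
    moisture_of_extinction(a) + moisture_of_extinction(b),
    2 * moisture_of_extinction((a + b) / 2),
    tolerance = 1e-12
  )
})

test_that("moisture-of-extinction scaling normalises at PAL and increases with oxygen", {
  expect_identical(moisture_extinction_scaling(20.95), 1)
  expect_equal(moisture_extinction_scaling(35), PI_CONST$me_ratio_35, tolerance = 1e-12)
  s <- moisture_extinction_scaling(seq(20.95, 35, by = 0.1))
  expect_true(all(diff(s) > 0))
})

test_that("heat of combustion follows the hyperbolic law", {
  expect_equal(heat_of_combustion(20.95, alpha = -52375, beta = 20000), 17500)
  # alpha = 0 degenerates to the asymptote for any oxygen
  expect_equal(heat_of_combustion(c(16, 25, 35), 0, 18500), rep(18500, 3))
  # approaches beta from below as oxygen grows when alpha < 0
  h <- heat_of_combustion(c(21, 28, 35, 1000), -41900, 18500)
  expect_true(all(diff(h) > 0) && all(h < 18500))
  expect_equal(heat_of_combustion(20.95, -41900, 18500), -41900 / 20.95 + 18500)
  expect_error(heat_of_combustion(20.95, -1e6, 100), "inconsistent")
  expect_error(heat_of_combustion(-1, 0, 18500), "positive")
})

test_that("FPC-weighted average matches a brute-force oracle and its invariants", {
  expect_equal(fpc_weighted_average(c(0, 0.4, 0), c(1, 7, 3)), 7)
  expect_equal(fpc_weighted_average(rep(0.1, 9), 1:9), mean(1:9))
  set.seed(11)
  for (i in 1:20) {
    fpc <- runif(9)
    v <- rnorm(9, 15000, 3000)
    w <- fpc_weighted_average(fpc, v)
    expect_equal(w, oracle_weighted_mean(fpc, v), tolerance = 1e-12)
    # invariant under uniform rescaling; bounded by the value range
    expect_equal(fpc_weighted_average(fpc * 3.7, v), w, tolerance = 1e-12)
    expect_true(w >= min(v) && w <= max(v))
  }
  expect_true(is.na(fpc_weighted_average(rep(0, 9), 1:9))) # bare ground
  expect_error(fpc_weighted_average(c(-0.1, 0.5), c(1, 2)), "non-negative")
})

test_that("per-PFT ignition scaling applies the right factor per growth form", {
  expect_equal(scale_pft_ignition(0.2, "grass", s_grass = 1, s_woody = 5), 0.2)
  expect_equal(scale_pft_ignition(0, "tree", 10, 10), 0)
  expect_equal(scale_pft_ignition(0.5, "tree", 2, 3), 1.5)
  expect_equal(
    scale_pft_ignition(c(0.5, 0.2), c("tree", "grass"), 2, 3),
    c(1.5, 0.4)
  )
  expect_error(scale_pft_ignition(1.2, "tree", 1, 1), "0, 1")
  expect_error(scale_pft_ignition(0.5, "shrub", 1, 1), "grass")
})

test_that("overall ignition efficiency is the exact triple product", {
  expect_equal(overall_ignition_efficiency(0, 5, 1), 0)
  expect_equal(overall_ignition_efficiency(1, 1, 1), 1)
  expect_equal(overall_ignition_efficiency(0.3, 2.0, 0.5), 0.3)
  # zero iff at least one factor is zero
  set.seed(2)
  f <- matrix(runif(30, 0.01, 2), ncol = 3)
  expect_true(all(overall_ignition_efficiency(f[, 1], f[, 2], f[, 3]) > 0))
  expect_error(overall_ignition_efficiency(-0.1, 1, 1), "non-negative")
})
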