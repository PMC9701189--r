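test_that("fire danger index resets on rain and accumulates dryness", {
  n <- 40
  temp <- rep(30, n)
  rh <- rep(0.2, n)
  prec <- rep(0, n)
  prec[10] <- 12 # heavy rain
  fdi <- fire_danger_index(temp, prec, rh)
  expect_equal(fdi[11], 0) # day after heavy rain
  # monotone non-decreasing over the rain-free warm spell
  expect_true(all(diff(fdi[12:n]) >= 0))
  expect_true(all(fdi >= 0 & fdi <= 1))
})

test_that("fire danger index matches the direct running-sum oracle", {
  set.seed(4)
  temp <- rnorm(120, 22, 6)
  prec <- ifelse(runif(120) < 0.25, rgamma(120, 0.8, scale = 6), 0)
  rh <- runif(120, 0.1, 0.9)
  p <- fire_params()
  expect_equal(
    fire_danger_index(temp, prec, rh, p),
    oracle_fdi(temp, prec, rh, p$rain_reset, p$nesterov_ref),
    tolerance = 1e-12
  )
})

test_that("expected ignitions are linear in lightning and efficiency", {
  expect_equal(expected_ignitions(0.02, 0, 1e6), 0)
  expect_equal(
    expected_ignitions(0.04, 0.3, 1e6, 0.25),
    2 * expected_ignitions(0.02, 0.3, 1e6, 0.25)
  )
  expect_equal(expected_ignitions(0.02, 0.3, 1e6, 0.25), 0.02 * 0.25 * 1e6 * 0.3)
  expect_error(expected_ignitions(-1, 0.3, 1), "non-negative")
})

test_that("rate of spread honours the extinction contract", {
  p <- fire_params()
  # moisture at/above the effective moisture of extinction stops spread
  for (o2 in c(20.95, 25, 30, 35)) {
    me_eff <- p$me_fine * moisture_extinction_scaling(o2)
    fb <- fuel_bed(0.5, 0, 2, moisture_nl = me_eff * c(1, 1.3, 3), moisture_o = 30)
    expect_equal(rate_of_spread(fb, wind = 5, o2 = o2, params = p), rep(0, 3))
  }
  # a fuel bed wetter than the 35%-level effective Me never spreads at any level
  me35 <- p$me_fine * moisture_extinction_scaling(35)
  fb <- fuel_bed(0.5, 0, 2, moisture_nl = me35 + 1, moisture_o = me35 + 1)
  for (o2 in c(20.95, 21:35)) {
    expect_equal(rate_of_spread(fb, wind = 5, o2 = o2, params = p), 0)
  }
})

test_that("rate of spread rises with oxygen and falls with bulk density", {
  p <- fire_params()
  fb <- fuel_bed(0.4, 0.2, 2, moisture_nl = 12, moisture_o = 14)
  ros <- vapply(seq(20.95, 35, by = 0.25), function(o2) {
    rate_of_spread(fb, wind = 4, o2 = o2, params = p)
  }, numeric(1))
  expect_true(all(diff(ros) >= 0))
  expect_gt(ros[length(ros)], ros[1])
  # doubling bulk density does not increase spread; wind increases it
  fb2 <- fuel_bed(0.4, 0.2, 4, moisture_nl = 12, moisture_o = 14)
  expect_lte(
    rate_of_spread(fb2, 4, 25, p),
    rate_of_spread(fb, 4, 25, p)
  )
  expect_gt(rate_of_spread(fb, 8, 25, p), rate_of_spread(fb, 2, 25, p))
})

test_that("fireline intensity is the Byram product", {
  expect_equal(fireline_intensity(18000, 1, 60), 18000)
  expect_equal(fireline_intensity(18000, 1, 0), 0)
  # linear in each argument
  expect_equal(fireline_intensity(9000, 2, 30), fireline_intensity(18000, 1, 30))
  expect_equal(fireline_intensity(500, 0.4, 3), 500 * 0.4 * 3 / 60)
  expect_error(fireline_intensity(-1, 1, 1), "non-negative")
})

test_that("burned area follows the ellipse oracle and conserves unburned area", {
  p <- fire_params()
  expect_equal(burned_area(100, 0, 5, 1e6, params = p), 0)
  got <- burned_area(50, 8, 4, 1e5, cum_burned = 0.2, params = p)
  want <- min(50 * oracle_fire_area_km2(8, 4, p$duration, p$lb_max) / 1e5, 0.8)
  expect_equal(got, want, tolerance = 1e-12)
  # cap at the remaining unburned fraction
  expect_equal(burned_area(1e9, 20, 5, 10, cum_burned = 0.7, params = p), 0.3)
  expect_error(burned_area(1, 1, 1, 1, cum_burned = 1.4), "0, 1")
})

test_that("fire mortality saturates below the susceptibility", {
  expect_equal(fire_mortality(0, 0.5), 0)
  kill <- fire_mortality(c(10, 100, 1000, 1e6), 0.6)
  expect_true(all(diff(kill) > 0))
  expect_true(all(kill <= 0.6))
  expect_equal(fire_mortality(1e12, 1), 1, tolerance = 1e-6)
  expect_error(fire_mortality(10, 1.4), "0, 1")
})
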