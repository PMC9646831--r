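test_that("casson viscosity closed form and limits", {
  # Newtonian limit: tau_y = 0 gives mu_inf exactly at any shear rate
  bp0 <- blood_properties(model = "newtonian", mu_inf = 0.0035)
  expect_equal(casson_viscosity(c(0, 1, 1e4), bp0), rep(0.0035, 3))

  # direct evaluation of the closed form (hand arithmetic)
  bp <- blood_properties(mu_inf = 0.0035, tau_y = 0.005)
  expect_equal(casson_viscosity(100, bp),
               (sqrt(0.0035) + sqrt(0.005 / 100))^2, tolerance = 1e-12)
  expect_equal(casson_viscosity(100, bp), 4.387e-3, tolerance = 1e-3)

  # high-shear asymptote: approaches mu_inf from above, monotonically
  g <- 10^seq(1, 7, by = 0.5)
  mu <- casson_viscosity(g, bp)
  expect_true(all(diff(mu) < 0))
  expect_true(all(mu > bp$mu_inf))
  expect_equal(casson_viscosity(1e12, bp), bp$mu_inf, tolerance = 1e-4)

  # regularization: finite at zero shear, clamped at gamma_min
  expect_equal(casson_viscosity(0, bp), casson_viscosity(bp$gamma_min, bp))
  expect_true(is.finite(casson_viscosity(0, bp)))

  expect_error(casson_viscosity(-1, bp), "non-negative")
})

test_that("shear-thinning and lower-bound properties hold on a grid", {
  for (hct in c(0.35, 0.40, 0.45)) {
    bp <- blood_properties(hct = hct)
    g <- seq(bp$gamma_min, 2000, length.out = 400)
    mu <- casson_viscosity(g, bp)
    expect_true(all(diff(mu) <= 0))          # non-increasing
    expect_true(all(mu >= bp$mu_inf))        # bounded below by mu_inf
  }
})

test_that("default closures rise with haematocrit", {
  hs <- c(0.2, 0.35, 0.40, 0.45, 0.6)
  props <- lapply(hs, function(h) blood_properties(hct = h))
  mu_inf <- vapply(props, `[[`, numeric(1), "mu_inf")
  tau_y <- vapply(props, `[[`, numeric(1), "tau_y")
  expect_true(all(diff(mu_inf) > 0))
  expect_true(all(diff(tau_y) >= 0))
  # calibration anchor of the yield closure: ~5 mPa at HCT 0.40
  expect_equal(blood_properties(hct = 0.40)$tau_y, 0.005, tolerance = 0.01)
})

test_that("blood_properties validates its inputs", {
  expect_error(blood_properties(hct = 0), ">")
  expect_error(blood_properties(hct = 1.2), "<")
  expect_error(blood_properties(density = -1), ">")
  expect_error(blood_properties(mu_inf = 1e-4), "plasma_viscosity")
  expect_error(blood_properties(model = "newtonian", tau_y = 0.01), "tau_y")
})
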