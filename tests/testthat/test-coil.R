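test_that("Kozeny-Carman permeability: hand values, monotonicity, open limit", {
  d_w <- 2.5e-4
  # hand evaluation: eps^3 d^2 / (180 (1-eps)^2)
  expect_equal(permeability_from_porosity(0.79, d_w),
               0.79^3 * d_w^2 / (180 * 0.21^2), tolerance = 1e-12)
  expect_equal(permeability_from_porosity(0.79, d_w), 3.88e-9, tolerance = 1e-2)
  expect_equal(permeability_from_porosity(0.89, d_w), 2.02e-8, tolerance = 1e-2)
  # strictly increasing in porosity; k -> infinity as eps -> 1
  eps <- seq(0.05, 0.999, length.out = 200)
  expect_true(all(diff(permeability_from_porosity(eps, d_w)) > 0))
  expect_gt(permeability_from_porosity(1 - 1e-9, d_w), 1)
  expect_error(permeability_from_porosity(1, d_w), "strictly")
  expect_error(permeability_from_porosity(0, d_w), "strictly")
})

test_that("momentum sink: Darcy arithmetic, zero flow, dissipativity", {
  cp <- coil_properties(0.79, inertial_coef = 0)
  expect_equal(momentum_sink(c(0, 0), 0.0035, 1060, cp), c(0, 0))
  # Darcy term: S = -(mu/k) u
  S <- momentum_sink(c(0.1, 0), 0.0035, 1060, cp)
  expect_equal(S[1], -0.0035 / cp$permeability * 0.1, tolerance = 1e-12)
  expect_equal(S[1], -9.02e4, tolerance = 1e-2)
  expect_equal(S[2], 0)

  # dissipativity S . u <= 0 for random states, with Forchheimer term on
  cp2 <- coil_properties(0.89)
  set.seed(42)
  U <- matrix(rnorm(200), ncol = 2)
  S2 <- momentum_sink(U, 0.004, 1060, cp2)
  expect_true(all(rowSums(S2 * U) <= 0))
})

test_that("coil_properties validates and defaults the Ergun closure", {
  cp <- coil_properties(0.79, wire_diameter = 2.5e-4)
  expect_equal(cp$inertial_coef, 3.5 * 0.21 / (2.5e-4 * 0.79^3), tolerance = 1e-12)
  expect_error(coil_properties(0), ">")
  expect_error(coil_properties(1), "<")
  expect_error(coil_properties(0.8, wire_diameter = 0), ">")
})
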