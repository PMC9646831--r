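zero_pressure_cfg <- function(dt = 4e-4)
  solver_config(dt = dt, cycles_to_run = 1, cycles_to_discard = 0,
                inlet_bc = "pressure", pressure_inlet = function(t) 0)

test_that("solver_config contracts: scheme, cycles, picard budget", {
  expect_error(solver_config(pressure_velocity_scheme = "simple"),
               "not implemented")
  expect_error(solver_config(cycles_to_run = 2, cycles_to_discard = 2),
               "cycles_to_run")
  expect_error(solver_config(inlet_bc = "pressure"), "pressure_inlet")
  expect_error(solver_config(dt = -1), ">")
  cfg <- solver_config()
  expect_identical(cfg$pressure_velocity_scheme, "projection")
})

test_that("null solution is preserved: zero forcing keeps a zero field", {
  m <- generate_mesh(chan_geom(L = 8e-3), 4e-4)
  cfg <- zero_pressure_cfg()
  st <- initial_state(m, newt_blood(), NULL, NULL, cfg)
  for (k in 1:25) st <- advance(st, m, newt_blood(), NULL, NULL, cfg)
  expect_identical(max(abs(st$u)), 0)
  expect_identical(max(abs(st$v)), 0)
  expect_identical(max(abs(st$p)), 0)
})

test_that("advance is deterministic and meets the divergence contract", {
  m <- generate_mesh(chan_geom(L = 8e-3), 4e-4)
  bp <- newt_blood()
  w <- pulsatile_waveform()
  cfg <- solver_config()
  run30 <- function() {
    st <- initial_state(m, bp, NULL, w, cfg)
    for (k in 1:30) st <- advance(st, m, bp, NULL, w, cfg)
    st
  }
  a <- run30(); b <- run30()
  expect_identical(a$u, b$u)
  expect_identical(a$p, b$p)
  expect_lt(a$max_divergence, cfg$divergence_tolerance)
  # discrete mass conservation: inlet flux equals outlet flux
  influx <- sum(a$u[1, ]) * m$hy
  outflux <- sum(a$u[m$nx + 1, ]) * m$hy
  expect_equal(influx, outflux, tolerance = 1e-10)
})

test_that("kinetic energy decays with zero inflow and a dissipative sink", {
  m <- generate_mesh(chan_geom(L = 8e-3), 4e-4)
  m$coil[, 1:4] <- m$fluid[, 1:4]       # partial coil region
  bp <- newt_blood()
  cp <- coil_properties(0.85)
  cfg <- zero_pressure_cfg(dt = 2e-4)
  st <- initial_state(m, bp, cp, NULL, cfg)
  # smooth initial blob (deterministic), not divergence-free on purpose
  st$u <- outer(sin(pi * seq_len(m$nx + 1) / (m$nx + 1)),
                sin(pi * seq_len(m$ny) / m$ny)) * 0.2
  st$u[!st$.ws$u_int] <- 0
  ke <- numeric(60)
  for (k in seq_along(ke)) {
    st <- advance(st, m, bp, cp, NULL, cfg)
    ke[k] <- sum(st$u^2) + sum(st$v^2)
  }
  expect_true(all(diff(ke) <= 1e-12))
})

test_that("picard loop honours its iteration budget", {
  m <- generate_mesh(chan_geom(L = 8e-3), 4e-4)
  bp <- blood_properties(hct = 0.45)    # nonlinear rheology
  w <- pulsatile_waveform()
  cfg_bad <- solver_config(max_inner_iterations = 2,
                           nonlinear_tolerance = 1e-16)
  # develop a sheared field first so the viscosity iterate actually moves
  cfg0 <- solver_config()
  st <- initial_state(m, bp, NULL, w, cfg0)
  for (k in 1:5) st <- advance(st, m, bp, NULL, w, cfg0)
  expect_error(advance(st, m, bp, NULL, w, cfg_bad),
               "inner iterations")
  # a realistic tolerance converges in a couple of iterations
  cfg_ok <- solver_config(max_inner_iterations = 4,
                          nonlinear_tolerance = 1e-2)
  st2 <- initial_state(m, bp, NULL, w, cfg_ok)
  expect_s3_class(advance(st2, m, bp, NULL, w, cfg_ok), "flow_state")
})

test_that("unstable time steps abort with a non-finite-field error", {
  m <- generate_mesh(chan_geom(L = 8e-3), 4e-4)
  bp <- newt_blood()
  w <- pulsatile_waveform(mean_velocity = 1.5)
  cfg <- solver_config(dt = 0.02)       # grossly CFL-violating
  st <- initial_state(m, bp, NULL, w, cfg)
  expect_error(suppressWarnings({
    for (k in 1:40) st <- advance(st, m, bp, NULL, w, cfg)
  }), "non-finite")
})

test_that("run_pulsatile bookkeeping: samples, snapshots, periodicity metric", {
  m <- generate_mesh(chan_geom(L = 8e-3), 5e-4)
  bp <- newt_blood()
  w <- pulsatile_waveform(period = 0.4, mean_velocity = 0.15)
  cfg <- solver_config(cycles_to_run = 2, cycles_to_discard = 1,
                       periodicity_tolerance = 1)
  res <- run_pulsatile(m, bp, NULL, w, cfg)
  n_per <- res$report$steps_per_cycle
  expect_equal(length(res$wall_series$times), n_per)   # every step recorded
  expect_named(res$snapshots, c("A", "B", "C", "D"))
  expect_true(all(vapply(res$snapshots, inherits, logical(1), "flow_state")))
  expect_true(is.finite(res$report$periodicity))
  expect_equal(nrow(res$wall_series$faces), sum(wall_faces(m)$tag != "inlet"))
  # uniform sampling spanning exactly one period
  expect_equal(diff(range(res$wall_series$times)), w$period * (1 - 1 / n_per),
               tolerance = 1e-9)
})
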