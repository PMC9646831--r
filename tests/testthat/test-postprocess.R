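test_that("OSI hand cases are exact to quadrature tolerance", {
  nt <- 400
  # constant traction -> OSI 0
  s1 <- make_series(matrix(2, 1, nt))
  expect_equal(osi(s1), 0)
  # zero-mean sinusoid along a fixed direction -> OSI 0.5
  s2 <- make_series(matrix(sin(2 * pi * seq_len(nt) / nt), 1, nt))
  expect_equal(osi(s2), 0.5, tolerance = 1e-12)
  # +2 Pa first half-cycle, -1 Pa second -> OSI = (1 - 0.5/1.5)/2 = 1/3
  s3 <- make_series(matrix(rep(c(2, -1), each = nt / 2), 1, nt))
  expect_equal(osi(s3), 1 / 3, tolerance = 1e-12)
  # degenerate all-zero series -> 0 with a warning
  s0 <- make_series(matrix(0, 1, nt))
  expect_warning(v <- osi(s0), "zero traction")
  expect_equal(v, 0)
})

test_that("TAWSS: constant, rectified sine, zero", {
  nt <- 2000
  expect_equal(tawss(make_series(matrix(2, 1, nt))), 2)
  s <- make_series(matrix(abs(sin(pi * seq_len(nt) / nt)), 1, nt))
  expect_equal(tawss(s), 2 / pi, tolerance = 1e-5)
  expect_equal(tawss(make_series(matrix(0, 1, nt))), 0)
})

test_that("OSI/TAWSS scaling invariants and quadrature convergence", {
  set.seed(7)
  nt <- 512
  tt <- 2 * pi * seq_len(nt) / nt
  tx <- rbind(sin(tt) + 0.3, cos(2 * tt) - 0.1, sin(tt) * cos(tt))
  ty <- rbind(cos(tt), sin(3 * tt), 0.2 + 0 * tt)
  s <- make_series(tx, ty)
  o1 <- osi(s); t1 <- tawss(s)
  expect_true(all(o1 >= 0 & o1 <= 0.5))
  # positive rescaling leaves OSI invariant, scales TAWSS linearly
  s4 <- make_series(4 * tx, 4 * ty)
  expect_equal(osi(s4), o1, tolerance = 1e-12)
  expect_equal(tawss(s4), 4 * t1, tolerance = 1e-12)
  # halving the sampling step changes OSI by < 1e-3 on smooth series
  half <- seq(1, nt, by = 2)
  s_half <- make_series(tx[, half], ty[, half])
  expect_lt(max(abs(osi(s_half) - o1)), 1e-3)
})

test_that("windowed OSI restricted to a quarter cycle", {
  nt <- 800
  # traction reverses only in (0.4, 0.6) T: whole-cycle OSI > 0 but a
  # window centred at 0.1 T sees unidirectional stress -> OSI 0
  tx <- matrix(1, 1, nt)
  tx[1, (0.4 * nt):(0.6 * nt)] <- -1
  s <- make_series(tx)
  expect_gt(osi(s), 0.2)
  expect_equal(osi(s, center = 0.1), 0)
  # window (0.375, 0.625]: +1 on 0.05 of it, -1 on 0.2 -> OSI = (1 - 0.6)/2
  expect_equal(osi(s, center = 0.5), 0.2, tolerance = 0.02)
})

test_that("high-risk regions: empty, single and double arcs", {
  nt <- 10
  nf <- 40
  base <- make_series(matrix(1, nf, nt))
  df <- base$faces
  df$osi <- rep(0, nf)
  expect_equal(nrow(high_risk_regions(df, 0.2)), 0)
  # one contiguous arc
  df$osi[10:15] <- 0.35
  r1 <- high_risk_regions(df, 0.2)
  expect_equal(nrow(r1), 1)
  expect_equal(r1$n_samples, 6)
  expect_equal(r1$peak_osi, 0.35)
  # two arcs separated by a sub-threshold gap (brute-force scan agrees)
  df$osi[25:28] <- 0.4
  r2 <- high_risk_regions(df, 0.2)
  expect_equal(nrow(r2), 2)
  expect_equal(r2$peak_arclength[2], df$arclength[which.max(df$osi)])
  expect_error(high_risk_regions(df, 0.6), "<")
})

test_that("compare_conditions arithmetic and bookkeeping", {
  # build two synthetic indices objects via a minimal fake structure
  fake_ind <- function(vals, eps) {
    per <- data.frame(landmark = c("A", "B", "C", "D"), time = 1:4,
                      max_wss_sac = vals, max_wss_vessel = vals,
                      max_osi_sac = vals / 10,
                      max_pressure_sac = 0, sac_mean_velocity = vals / 2)
    structure(list(per_landmark = per,
                   geometry = build_idealized_aneurysm(),
                   condition = list(porosity = eps, hct = 0.4)),
              class = "hemodynamic_indices")
  }
  a <- fake_ind(c(0.4, 0.4, 0.4, 0.4), 0.89)
  b <- fake_ind(c(0.1, 0.2, 0.3, 0.4), 0.79)
  cmp <- compare_conditions(list(ref = a, low = b), reference = "ref")
  expect_equal(nrow(cmp), 4 * 3)           # landmarks x indices
  expect_equal(cmp$percent_change[cmp$landmark == "A" & cmp$index == "max_wss"], 75)
  expect_equal(cmp$percent_change[cmp$landmark == "D" & cmp$index == "max_wss"], 0)
  # identical conditions -> 0 percent change everywhere
  cmp0 <- compare_conditions(list(x = a, y = a))
  expect_true(all(cmp0$percent_change == 0))
  # three conditions -> (n-1) * landmarks * indices rows
  cmp3 <- compare_conditions(list(r = a, s = b, t = b), reference = "r")
  expect_equal(nrow(cmp3), 2 * 4 * 3)
  # mismatched geometries rejected
  c_bad <- fake_ind(c(1, 1, 1, 1), 0.5)
  c_bad$geometry <- build_idealized_aneurysm(dome_radius = 2.5e-3)
  expect_error(compare_conditions(list(a = a, b = c_bad)), "geometry")
})

test_that("wall shear stress recovers imposed linear and parabolic profiles", {
  # Plane Poiseuille on a synthetic state: u(y) = 6 U y (H - y) / H^2
  g <- chan_geom(L = 8e-3)
  m <- generate_mesh(g, 4e-4)
  U <- 0.1; H <- 4e-3; mu <- 0.0035
  st <- initial_state(m, newt_blood(mu), NULL,
                      pulsatile_waveform(amplitudes = numeric(0),
                                         phases = numeric(0)),
                      solver_config(cycles_to_run = 1, cycles_to_discard = 0))
  yy <- m$yc
  st$u <- matrix(rep(6 * U * yy * (H - yy) / H^2, each = m$nx + 1), m$nx + 1, m$ny)
  w <- wall_shear_stress(st, m, newt_blood(mu))
  walls <- w[w$tag == "vessel_wall", ]
  expect_equal(mean(abs(walls$tx)), 6 * mu * U / H, tolerance = 1e-10)
  # quiescent field: zero traction
  st$u[] <- 0
  w0 <- wall_shear_stress(st, m, newt_blood(mu))
  expect_true(all(w0$wss == 0))
  # linear profile of slope gdot: |WSS| = mu * gdot on the bottom wall
  gdot <- 50
  st$u <- matrix(rep(gdot * yy, each = m$nx + 1), m$nx + 1, m$ny)
  wl <- wall_shear_stress(st, m, newt_blood(mu))
  bottom <- wl[wl$side == "S", ]
  expect_equal(mean(abs(bottom$tx)), mu * gdot, tolerance = 1e-10)
})
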