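test_that("inlet velocity evaluates, is periodic, and has the configured mean", {
  T <- 0.8
  w1 <- pulsatile_waveform(period = T, mean_velocity = 0.3,
                           amplitudes = 0.5, phases = pi / 2)
  # u(t) = U0 (1 + 0.5 sin(2 pi t / T)): at t = T/4 -> 0.45
  expect_equal(inlet_velocity(T / 4, w1), 0.45, tolerance = 1e-12)

  w <- pulsatile_waveform()
  tt <- runif(50, -3, 3)
  expect_equal(inlet_velocity(tt, w), inlet_velocity(tt + w$period, w),
               tolerance = 1e-12)

  # cycle average equals U_mean (quadrature vs configured mean)
  tg <- seq(0, w$period, length.out = 20001)[-20001]
  expect_equal(mean(inlet_velocity(tg, w)), w$mean_velocity, tolerance = 1e-6)

  expect_true(all(inlet_velocity(tg, w) > 0))
})

test_that("phase landmarks: sinusoid closed form and ordering invariants", {
  T <- 0.8
  w <- pulsatile_waveform(period = T, mean_velocity = 0.3,
                          amplitudes = 0.5, phases = pi / 2)
  lm <- landmark_times(phase_landmarks(w))
  expect_equal(unname(lm), c(0, T / 4, T / 2, 3 * T / 4), tolerance = T * 2e-5)

  # default 3-harmonic pulse: ordering A < B < C <= D and derivative checks
  wd <- pulsatile_waveform()
  lmd <- phase_landmarks(wd)
  expect_true(lmd$t_A < lmd$t_B && lmd$t_B < lmd$t_C && lmd$t_C <= lmd$t_D)
  # dense-grid oracle: t_B within one step of brute-force argmax
  tg <- seq(0, T, length.out = 100001)[-100001]
  expect_lt(abs(lmd$t_B - tg[which.max(inlet_velocity(tg, wd))]), 2 * T / 1e5)
  # du/dt at t_A is the global maximum of the derivative
  expect_gte(inlet_velocity(lmd$t_A, wd, deriv = 1) + 1e-9,
             max(inlet_velocity(tg, wd, deriv = 1)))
})

test_that("landmarks shift with time translation of the waveform", {
  T <- 0.8; shift <- 0.23 * T
  w0 <- pulsatile_waveform()
  w1 <- pulsatile_waveform(phases = w0$phases + seq_along(w0$phases) *
                             2 * pi * shift / T)
  lm0 <- landmark_times(phase_landmarks(w0))
  lm1 <- landmark_times(phase_landmarks(w1))
  expect_equal((lm1 - lm0) %% T, rep(shift, 4), tolerance = 1e-3 * T,
               ignore_attr = TRUE)
})

test_that("degenerate waveforms are rejected", {
  w_const <- pulsatile_waveform(amplitudes = numeric(0), phases = numeric(0))
  expect_error(phase_landmarks(w_const), "constant")
  expect_error(pulsatile_waveform(amplitudes = c(2), phases = c(0)),
               "positive")
  expect_error(pulsatile_waveform(amplitudes = c(0.5, 0.2), phases = 0),
               "length")
})
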