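#' Analytic pulsatile inlet waveform
#'
#' A truncated Fourier series surrogate for a carotid-type flow pulse:
#' \deqn{u(t) = U_{mean}\Big(1 + \sum_k a_k \cos(2\pi k t/T - \phi_k)\Big),}
#' smooth (\eqn{C^\infty}), periodic with period \code{T}, and by
#' construction with cycle mean exactly \code{U_mean}.  The default three
#' harmonics (\eqn{a = (0.55, 0.30, 0.12)}, \eqn{\phi_k = 2\pi k \cdot 0.15})
#' place a pronounced systolic peak of \eqn{1.97\,U_{mean}} at
#' \eqn{t = 0.15\,T} and a diastolic minimum of \eqn{0.63\,U_{mean}} — the
#' signal is strictly positive (no inlet flow reversal).
#'
#' @param period cycle duration \code{T}, s. Default 0.8.
#' @param mean_velocity cycle-mean inlet speed \code{U_mean}, m/s. Default 0.3.
#' @param amplitudes relative harmonic amplitudes \eqn{a_k} (dimensionless,
#'   multiply \code{U_mean}).
#' @param phases harmonic phases \eqn{\phi_k}, rad; must match
#'   \code{amplitudes} in length.
#' @return An object of class \code{waveform}.
#' @examples
#' w <- pulsatile_waveform()
#' inlet_velocity(c(0, 0.12, 0.4), w)
#' @export
pulsatile_waveform <- function(period = 0.8, mean_velocity = 0.3,
                               amplitudes = c(0.55, 0.30, 0.12),
                               phases = 2 * pi * c(1, 2, 3) * 0.15) {
  check_scalar(period, "period", 0, strict_lower = TRUE)
  check_scalar(mean_velocity, "mean_velocity", 0, strict_lower = TRUE)
  if (length(amplitudes) != length(phases))
    stopf("amplitudes (%d) and phases (%d) must have equal length",
          length(amplitudes), length(phases))
  w <- structure(list(period = period, mean_velocity = mean_velocity,
                      amplitudes = as.numeric(amplitudes),
                      phases = as.numeric(phases)),
                 class = "waveform")
  if (length(amplitudes) > 0L) {
    tg <- seq(0, period, length.out = 4096L)
    umin <- min(inlet_velocity(tg, w))
    if (umin <= 0)
      stopf("waveform is not strictly positive (min u = %.4g m/s); reduce amplitudes", umin)
  }
  w
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> T = %g s, U_mean = %g m/s, %d harmonic(s)\n",
              x$period, x$mean_velocity, length(x$amplitudes)))
  invisible(x)
}

#' Mean inlet speed at time t
#'
#' Evaluates the waveform; \code{t} is reduced modulo the period, so any
#' real time is accepted.  Vectorized over \code{t}.
#'
#' @param t time(s), s.
#' @param w a \code{\link{pulsatile_waveform}} object.
#' @param deriv 0 for the speed (m/s), 1 for its time derivative (m/s^2).
#' @return Numeric vector, same length as \code{t}.
#' @export
inlet_velocity <- function(t, w, deriv = 0L) {
  if (!inherits(w, "waveform")) stopf("'w' must be a waveform")
  om <- 2 * pi / w$period
  if (deriv == 0L) {
    u <- rep(1, length(t))
    for (k in seq_along(w$amplitudes))
      u <- u + w$amplitudes[k] * cos(k * om * t - w$phases[k])
    w$mean_velocity * u
  } else {
    du <- rep(0, length(t))
    for (k in seq_along(w$amplitudes))
      du <- du - w$amplitudes[k] * k * om * sin(k * om * t - w$phases[k])
    w$mean_velocity * du
  }
}

#' Cardiac-phase landmarks of a waveform
#'
#' Locates the four reporting instants of the cardiac cycle on a dense time
#' grid: maximum acceleration (A, argmax \eqn{du/dt}), peak systole (B,
#' argmax \eqn{u}), maximum deceleration (C, argmin \eqn{du/dt}) and early
#' diastole (D).  "Early diastole" has no universal mathematical
#' definition; the convention here is the minimum of \eqn{u} restricted to
#' the half-cycle following maximum deceleration.  Ties within tolerance
#' resolve to the earliest time, with a warning.
#'
#' @param w a \code{\link{pulsatile_waveform}} object.
#' @param n_grid number of grid points per cycle used for the search.
#' @param tol relative tolerance for declaring non-unique extrema.
#' @return An object of class \code{phase_landmarks}: list with \code{t_A},
#'   \code{t_B}, \code{t_C}, \code{t_D} (s, in [0, T)) and \code{period}.
#' @examples
#' phase_landmarks(pulsatile_waveform())
#' @export
phase_landmarks <- function(w, n_grid = 100000L, tol = 1e-9) {
  if (!inherits(w, "waveform")) stopf("'w' must be a waveform")
  T <- w$period
  tg <- seq(0, T, length.out = n_grid + 1L)[seq_len(n_grid)]
  u <- inlet_velocity(tg, w)
  du <- inlet_velocity(tg, w, deriv = 1L)
  if (diff(range(u)) <= tol * max(abs(u)))
    stopf("waveform is constant: phase landmarks are undefined")
  pick <- function(vals, which_max, label) {
    idx <- if (which_max) which.max(vals) else which.min(vals)
    extreme <- vals[idx]
    near <- abs(vals - extreme) <= tol * max(abs(vals), 1e-300)
    if (sum(near) > 1L && diff(range(which(near))) > 2L) {
      warnf("non-unique %s extremum; earliest time chosen", label)
      idx <- which(near)[1L]
    }
    idx
  }
  iA <- pick(du, TRUE, "max-acceleration")
  iB <- pick(u, TRUE, "peak-systole")
  iC <- pick(du, FALSE, "max-deceleration")
  t_C <- tg[iC]
  # early diastole: min of u in the half-cycle after max deceleration
  rel <- (tg - t_C) %% T
  sel <- which(rel > 0 & rel <= T / 2)
  iD <- sel[pick(u[sel], FALSE, "early-diastole")]
  structure(list(t_A = tg[iA], t_B = tg[iB], t_C = t_C, t_D = tg[iD],
                 period = T),
            class = "phase_landmarks")
}

#' @export
print.phase_landmarks <- function(x, ...) {
  cat(sprintf(
    "<phase_landmarks> T = %g s\n  A (max accel)  %.4f s\n  B (peak systole) %.4f s\n  C (max decel)  %.4f s\n  D (early diastole) %.4f s\n",
    x$period, x$t_A, x$t_B, x$t_C, x$t_D))
  invisible(x)
}

#' @rdname phase_landmarks
#' @param lm a \code{phase_landmarks} object.
#' @return \code{landmark_times()}: named numeric vector (A, B, C, D), s.
#' @export
landmark_times <- function(lm) {
  c(A = lm$t_A, B = lm$t_B, C = lm$t_C, D = lm$t_D)
}
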