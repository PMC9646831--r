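#' Wall shear stress of a flow state
#'
#' Tangential viscous traction \eqn{\tau_w = \mu\,(\partial u_t/\partial
#' n)|_{wall}} at every wall face, with the wall-normal gradient taken
#' one-sided into the fluid (second order where two interior samples
#' exist) and \eqn{\mu} the local apparent viscosity evaluated at the wall
#' shear rate.  The normal traction component is discarded; the wall
#' pressure is reported alongside.
#'
#' @param state a \code{flow_state}.
#' @param mesh the \code{sacflow_mesh} the state lives on.
#' @param props \code{\link{blood_properties}}.
#' @return A data.frame: wall-face table (position, tag, arc length)
#'   plus traction components \code{tx}, \code{ty}, magnitude \code{wss}
#'   and wall \code{pressure}, in boundary-walk order.
#' @export
wall_shear_stress <- function(state, mesh, props) {
  wg <- wall_probe_geometry(mesh)
  ws <- list2env(list(wall_geom = wg), parent = emptyenv())
  tr <- wall_traction(state, ws, props)
  out <- wg$faces
  out$tx <- tr$tx; out$ty <- tr$ty
  out$wss <- sqrt(tr$tx^2 + tr$ty^2)
  out$pressure <- tr$p
  out
}

# uniform-weight periodic integral over the recorded cycle samples;
# optionally restricted to a circular window around `center`
series_weights <- function(series, center = NULL, halfwidth = NULL) {
  T <- series$period
  tt <- series$times
  if (is.null(center)) return(rep(1, length(tt)))
  d <- abs(((tt - center + T / 2) %% T) - T / 2)
  as.numeric(d <= halfwidth + 1e-12)
}

#' Oscillatory shear index
#'
#' Per-wall-sample OSI over one recorded cycle:
#' \deqn{OSI = \frac{1}{2}\left(1 -
#'   \frac{\left|\int_0^T \boldsymbol\tau_w\,dt\right|}
#'        {\int_0^T |\boldsymbol\tau_w|\,dt}\right)}
#' with the traction treated as a vector (norm of the time-integral over
#' the integral of norms), which reduces to the scalar form for
#' unidirectional stress.  Values lie in [0, 0.5]: 0 for steady
#' unidirectional stress, 0.5 for pure zero-mean oscillation.  Samples
#' with an identically zero traction history return 0 with a warning.
#'
#' A phase-resolved variant integrates over a circular window of
#' half-width \code{halfwidth} centred at \code{center} (used for the
#' per-landmark OSI comparisons); the default is the whole cycle.
#'
#' @param series a \code{wall_series} (from \code{\link{run_pulsatile}}).
#' @param center optional window centre, s in [0, T).
#' @param halfwidth window half-width, s; default \code{T/8} when a centre
#'   is given (quarter-cycle window).
#' @return Numeric vector of OSI values, one per wall sample.
#' @export
osi <- function(series, center = NULL, halfwidth = NULL) {
  if (!inherits(series, "wall_series")) stopf("'series' must be a wall_series")
  if (!is.null(center) && is.null(halfwidth)) halfwidth <- series$period / 8
  wgt <- series_weights(series, center, halfwidth)
  if (sum(wgt) == 0) stopf("empty OSI window")
  sx <- drop(series$tx %*% wgt)
  sy <- drop(series$ty %*% wgt)
  mag <- drop(sqrt(series$tx^2 + series$ty^2) %*% wgt)
  out <- numeric(length(mag))
  ok <- mag > 0
  if (any(!ok)) warnf("%d wall sample(s) have identically zero traction; OSI set to 0", sum(!ok))
  out[ok] <- 0.5 * (1 - sqrt(sx[ok]^2 + sy[ok]^2) / mag[ok])
  pmin(pmax(out, 0), 0.5)
}

#' Time-averaged wall shear stress magnitude
#'
#' \eqn{TAWSS = (1/T)\int_0^T |\boldsymbol\tau_w|\,dt \ge 0} per wall
#' sample, on the same recorded cycle as \code{\link{osi}}.
#'
#' @inheritParams osi
#' @return Numeric vector of TAWSS values (Pa), one per wall sample.
#' @export
tawss <- function(series) {
  if (!inherits(series, "wall_series")) stopf("'series' must be a wall_series")
  rowMeans(sqrt(series$tx^2 + series$ty^2))
}

# mean velocity magnitude across the neck section of one state.
# Sampled at fixed physical quadrature points along the neck chord
# (independent of h, so the monitor converges under mesh refinement
# instead of tracking the stair-step neck face set), with velocities
# interpolated linearly from the staggered fields.
neck_mean_speed <- function(state, mesh, n_quad = 64L) {
  cols <- mesh$neck_cols
  if (length(cols) == 0) stopf("geometry has no neck: sac mean inflow velocity undefined")
  ns <- neck_segment(mesh$geom)
  jc <- mesh$ny_channel
  # sample the inner 90% of the chord: the end points sit in the stair-step
  # corner cells whose velocities are not defined at all resolutions
  pad <- 0.05 * (ns[2] - ns[1])
  xq <- seq(ns[1] + pad, ns[2] - pad, length.out = n_quad)
  # v at the wall line y = D: v-faces (i, jc+1) at x = (i - 1/2) hx
  xv <- (cols - 0.5) * mesh$hx
  v <- state$v[cols, jc + 1L]
  vq <- stats::approx(xv, v, xout = xq, rule = 2)$y
  # u averaged to the same line from the flanking u-face rows
  ub <- 0.25 * (state$u[cols, jc] + state$u[cols + 1L, jc] +
                  state$u[cols, jc + 1L] + state$u[cols + 1L, jc + 1L])
  uq <- stats::approx(xv, ub, xout = xq, rule = 2)$y
  mean(sqrt(vq^2 + uq^2))
}

#' Sac-mean inflow velocity at the phase landmarks
#'
#' Length-weighted mean of the velocity magnitude across the sac neck
#' section (the chord separating sac and parent vessel) at each of the
#' four landmark snapshots.  The magnitude is used, not the signed flux,
#' so a balanced in/out jet still registers its strength.
#'
#' @param result a \code{sacflow_result} from \code{\link{run_pulsatile}}.
#' @return Named numeric vector (A, B, C, D), m/s.
#' @export
sac_mean_inflow_velocity <- function(result) {
  if (!inherits(result, "sacflow_result")) stopf("'result' must be a sacflow_result")
  vapply(result$snapshots, neck_mean_speed, numeric(1), mesh = result$mesh)
}

#' Iso-velocity area at the phase landmarks
#'
#' Area (m^2) of the region where the velocity magnitude meets or exceeds
#' \code{level}, per landmark snapshot; optionally restricted to the sac.
#'
#' @param result a \code{sacflow_result}.
#' @param level velocity magnitude threshold, m/s.
#' @param sac_only restrict to sac cells (centroid above the wall line)?
#' @return Named numeric vector (A, B, C, D), m^2.
#' @export
iso_velocity_area <- function(result, level = 0.4, sac_only = FALSE) {
  mesh <- result$mesh
  sel <- mesh$fluid
  if (sac_only) {
    sel <- sel & (col(sel) > mesh$ny_channel)
  }
  vapply(result$snapshots, function(st) {
    sp <- cell_velocity(st, mesh)$speed
    sum(sp >= level & sel) * mesh$hx * mesh$hy
  }, numeric(1))
}

#' Hemodynamic indices of a pulsatile run
#'
#' Computes the standard wall indices from the recorded wall series and
#' landmark snapshots: per-sample TAWSS, whole-cycle OSI, peak traction
#' magnitude and peak wall pressure; per-landmark maxima of instantaneous
#' WSS and of the phase-windowed OSI over the aneurysm (sac) wall, and the
#' sac-mean inflow velocity; and the global maxima with their locations.
#' "Max OSI at a landmark" uses the quarter-cycle window centred on the
#' landmark (OSI is a cycle integral and has no instantaneous value).
#'
#' @param result a \code{sacflow_result}.
#' @param osi_threshold threshold used by \code{\link{high_risk_regions}}.
#' @param window_halfwidth half-width (s) of the per-landmark OSI window;
#'   default T/8.
#' @return An object of class \code{hemodynamic_indices}: list with
#'   \code{samples} (per-wall-sample data.frame), \code{per_landmark}
#'   (data.frame keyed by landmark), \code{global} (named list),
#'   \code{osi_threshold}, and run metadata.
#' @export
hemodynamic_indices <- function(result, osi_threshold = 0.2,
                                window_halfwidth = NULL) {
  if (!inherits(result, "sacflow_result")) stopf("'result' must be a sacflow_result")
  series <- result$wall_series
  T <- series$period
  if (is.null(window_halfwidth)) window_halfwidth <- T / 8
  samples <- series$faces
  samples$tawss <- tawss(series)
  samples$osi <- osi(series)
  mag <- sqrt(series$tx^2 + series$ty^2)
  samples$peak_wss <- apply(mag, 1, max)
  samples$peak_pressure <- apply(series$pressure, 1, max)

  sac <- samples$tag == "sac_wall"
  has_sac <- any(sac)
  lmt <- landmark_times(result$landmarks)
  smv <- sac_mean_inflow_velocity_or_na(result)
  per_lm <- do.call(rbind, lapply(names(lmt), function(nm) {
    tl <- lmt[[nm]]
    it <- which.min(abs(((series$times - tl + T / 2) %% T) - T / 2))
    inst <- mag[, it]
    osi_w <- osi(series, center = tl, halfwidth = window_halfwidth)
    data.frame(landmark = nm, time = tl,
               max_wss_sac = if (has_sac) max(inst[sac]) else NA_real_,
               max_wss_vessel = max(inst[!sac]),
               max_osi_sac = if (has_sac) max(osi_w[sac]) else NA_real_,
               max_pressure_sac = if (has_sac) max(series$pressure[sac, it]) else NA_real_,
               sac_mean_velocity = smv[[nm]])
  }))
  imax_wss <- which.max(samples$peak_wss)
  imax_osi <- which.max(samples$osi)
  global <- list(
    max_tawss = max(samples$tawss),
    max_osi = samples$osi[imax_osi],
    max_osi_location = samples[imax_osi, c("x", "y", "arclength", "tag")],
    max_wss = samples$peak_wss[imax_wss],
    max_wss_location = samples[imax_wss, c("x", "y", "arclength", "tag")],
    max_wss_phase = per_lm$landmark[which.max(per_lm$max_wss_sac)]
  )
  structure(list(samples = samples, per_landmark = per_lm, global = global,
                 osi_threshold = osi_threshold, period = T,
                 geometry = result$mesh$geom,
                 condition = list(porosity = if (!is.null(result$coil)) result$coil$porosity else NA_real_,
                                  hct = result$props$hct)),
            class = "hemodynamic_indices")
}

sac_mean_inflow_velocity_or_na <- function(result) {
  if (length(result$mesh$neck_cols) == 0)
    return(stats::setNames(rep(NA_real_, 4), names(result$snapshots)))
  sac_mean_inflow_velocity(result)
}

#' @export
print.hemodynamic_indices <- function(x, ...) {
  cat("<hemodynamic_indices>\n")
  print(x$per_landmark, row.names = FALSE)
  cat(sprintf("  global: max WSS %.4g Pa (%s wall), cycle max OSI %.4g\n",
              x$global$max_wss, x$global$max_wss_location$tag, x$global$max_osi))
  invisible(x)
}

#' High-risk wall regions by OSI threshold
#'
#' Maximal connected arcs of the aneurysm (sac) wall where the whole-cycle
#' OSI meets or exceeds \code{osi_threshold}.  Connectivity follows the
#' boundary-walk ordering of the wall samples; an empty result (no sample
#' above threshold) is legitimate.
#'
#' @param indices a \code{\link{hemodynamic_indices}} object, or a
#'   data.frame with columns \code{osi}, \code{arclength} (and optionally
#'   \code{x}, \code{y}).
#' @param osi_threshold threshold in (0, 0.5).
#' @return data.frame: one row per region with \code{start}, \code{end}
#'   and \code{extent} (arc length, m), \code{n_samples}, \code{peak_osi}
#'   and the peak location.
#' @export
high_risk_regions <- function(indices, osi_threshold = NULL) {
  if (inherits(indices, "hemodynamic_indices")) {
    if (is.null(osi_threshold)) osi_threshold <- indices$osi_threshold
    df <- indices$samples[indices$samples$tag == "sac_wall", , drop = FALSE]
  } else df <- indices
  if (is.null(osi_threshold)) osi_threshold <- 0.2
  check_scalar(osi_threshold, "osi_threshold", 0, 0.5,
               strict_lower = TRUE, strict_upper = TRUE)
  if (nrow(df) == 0 || !any(df$osi >= osi_threshold))
    return(data.frame(start = numeric(0), end = numeric(0),
                      extent = numeric(0), n_samples = integer(0),
                      peak_osi = numeric(0), peak_arclength = numeric(0)))
  hot <- df$osi >= osi_threshold
  run_id <- cumsum(c(TRUE, diff(hot) != 0))
  out <- lapply(split(seq_len(nrow(df)), run_id), function(idx) {
    if (!hot[idx[1]]) return(NULL)
    sl <- df[idx, , drop = FALSE]
    ip <- which.max(sl$osi)
    data.frame(start = min(sl$arclength), end = max(sl$arclength),
               extent = max(sl$arclength) - min(sl$arclength) +
                 if ("length" %in% names(sl)) mean(sl$length) else 0,
               n_samples = nrow(sl),
               peak_osi = sl$osi[ip], peak_arclength = sl$arclength[ip])
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Compare hemodynamic indices across conditions
#'
#' Percent change of each per-landmark index (max WSS on the sac wall,
#' max phase-windowed OSI on the sac wall, sac-mean inflow velocity)
#' against a declared reference condition:
#' \eqn{100\,(x_{ref} - x)/x_{ref}} — positive values mean a reduction
#' relative to the reference.
#'
#' @param results named list (>= 2) of \code{\link{hemodynamic_indices}}
#'   sharing one geometry; names identify the conditions.
#' @param reference name of the reference condition; default the first.
#' @return An object of class \code{condition_comparison}: data.frame with
#'   one row per (non-reference condition, landmark, index).
#' @export
compare_conditions <- function(results, reference = NULL) {
  if (!is.list(results) || length(results) < 2L)
    stopf("'results' must be a named list of >= 2 hemodynamic_indices")
  if (is.null(names(results)) || any(names(results) == ""))
    stopf("'results' must be fully named by condition")
  if (!all(vapply(results, inherits, logical(1), "hemodynamic_indices")))
    stopf("all elements of 'results' must be hemodynamic_indices")
  g0 <- results[[1]]$geometry
  for (r in results[-1]) {
    if (!isTRUE(all.equal(r$geometry[c("parent_width", "parent_length", "sac_neck_width", "sac_depth", "sac_shape")],
                          g0[c("parent_width", "parent_length", "sac_neck_width", "sac_depth", "sac_shape")])))
      stopf("conditions do not share a geometry; comparison rejected")
  }
  if (is.null(reference)) reference <- names(results)[1]
  if (!reference %in% names(results)) stopf("reference '%s' not among conditions", reference)
  ref <- results[[reference]]$per_landmark
  idx_cols <- c(max_wss = "max_wss_sac", max_osi = "max_osi_sac",
                sac_mean_velocity = "sac_mean_velocity")
  rows <- list()
  for (nm in setdiff(names(results), reference)) {
    cur <- results[[nm]]$per_landmark
    for (li in seq_len(nrow(ref))) {
      for (k in seq_along(idx_cols)) {
        xr <- ref[[idx_cols[k]]][li]; xc <- cur[[idx_cols[k]]][li]
        rows[[length(rows) + 1L]] <- data.frame(
          condition = nm, reference = reference,
          landmark = ref$landmark[li], index = names(idx_cols)[k],
          value = xc, reference_value = xr,
          percent_change = if (is.finite(xr) && xr != 0) 100 * (xr - xc) / xr else NA_real_)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("condition_comparison", class(out))
  out
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison> percent change vs reference (positive = reduction)\n")
  NextMethod()
  invisible(x)
}
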