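#' Idealized sidewall-aneurysm geometry
#'
#' Parametric 2-D stand-in for a patient internal-carotid-artery (ICA)
#' sidewall aneurysm: a parent vessel of width \code{parent_width} and
#' length \code{parent_length}, optionally bent with constant centerline
#' curvature \code{curvature}, carrying a sac on one wall.  The geometry is
#' described (and solved) in straightened arc-length coordinates: the
#' channel occupies \eqn{[0, L] \times [0, D]} and the sac bulges above the
#' wall \eqn{y = D}; the bend is applied as an isometric mapping for output
#' (see \code{\link{bend_coordinates}}).
#'
#' Sac shapes:
#' \describe{
#'   \item{\code{circular_segment}}{the region of a circle of dome radius
#'     \eqn{r} above the wall line; \eqn{r} follows from neck width \eqn{N}
#'     and depth \eqn{H_s} as \eqn{r = H_s/2 + N^2/(8 H_s)}.  Alternatively
#'     pass \code{dome_radius} and the depth of the major segment
#'     \eqn{H_s = r + \sqrt{r^2 - (N/2)^2}} is derived (requires
#'     \eqn{N \le 2r}).}
#'   \item{\code{elliptical}}{the upper half of an ellipse with semi-axes
#'     \eqn{N/2} (along the wall) and \eqn{H_s} (depth).}
#' }
#' Setting \code{sac_neck_width = 0} (or \code{sac_depth = 0}) degenerates
#' to a plain channel with zero sac area.
#'
#' The coil region occupies the fraction \code{coil_fill_fraction} of the
#' sac area, measured from the dome inward (coils pack the dome first): it
#' is the part of the sac above a horizontal cut chosen so the enclosed
#' area equals \eqn{f_c \times} sac area.
#'
#' @param parent_width channel width \eqn{D}, m. Default 4 mm.
#' @param parent_length channel length \eqn{L}, m. Default 40 mm.
#' @param curvature centerline curvature \eqn{\kappa}, 1/m (0 = straight).
#'   Default 1/(20 mm) = 50.
#' @param sac_neck_width neck width \eqn{N}, m (0 = no sac). Default 4 mm.
#' @param sac_depth sac depth \eqn{H_s}, m; for \code{circular_segment} it
#'   may be omitted when \code{dome_radius} is given.
#' @param dome_radius dome radius \eqn{r}, m (circular_segment only).
#'   Default 3 mm when neither \code{sac_depth} nor \code{dome_radius} is
#'   supplied.
#' @param sac_shape \code{"circular_segment"} or \code{"elliptical"}.
#' @param sac_center_arc arc-length position \eqn{s_0} of the neck centre
#'   along the wall, m. Default \eqn{L/2}.
#' @param coil_fill_fraction \eqn{f_c \in [0, 1]}. Default 0.85: the coil
#'   packs the dome and leaves a thin neck-adjacent layer open, the common
#'   clinical outcome (neck remnant); set 1 for complete packing.
#' @return An object of class \code{vessel_geometry}.
#' @examples
#' g <- build_idealized_aneurysm()
#' sac_area(g)
#' @export
build_idealized_aneurysm <- function(parent_width = 4e-3, parent_length = 40e-3,
                                     curvature = 50,
                                     sac_neck_width = 4e-3, sac_depth = NULL,
                                     dome_radius = NULL,
                                     sac_shape = c("circular_segment", "elliptical"),
                                     sac_center_arc = NULL,
                                     coil_fill_fraction = 0.85) {
  sac_shape <- match.arg(sac_shape)
  check_scalar(parent_width, "parent_width", 0, strict_lower = TRUE)
  check_scalar(parent_length, "parent_length", 0, strict_lower = TRUE)
  check_scalar(curvature, "curvature", 0)
  check_scalar(sac_neck_width, "sac_neck_width", 0)
  check_scalar(coil_fill_fraction, "coil_fill_fraction", 0, 1)
  if (is.null(sac_center_arc)) sac_center_arc <- parent_length / 2
  check_scalar(sac_center_arc, "sac_center_arc", 0, parent_length)
  if (curvature > 0 && curvature * parent_width >= 1)
    stopf("curvature * parent_width = %g >= 1: inner wall radius would be negative",
          curvature * parent_width)

  D <- parent_width; L <- parent_length; N <- sac_neck_width
  no_sac <- (N == 0) || (!is.null(sac_depth) && sac_depth == 0)
  r <- NA_real_
  if (no_sac) {
    N <- 0; Hs <- 0
  } else if (sac_shape == "circular_segment") {
    if (is.null(sac_depth) && is.null(dome_radius)) dome_radius <- 3e-3
    if (!is.null(dome_radius)) {
      check_scalar(dome_radius, "dome_radius", 0, strict_lower = TRUE)
      if (N > 2 * dome_radius)
        stopf("sac_neck_width N = %g m exceeds 2 * dome_radius = %g m: no circular segment has that chord",
              N, 2 * dome_radius)
      r <- dome_radius
      Hs_derived <- r + sqrt(r^2 - (N / 2)^2)
      if (!is.null(sac_depth)) {
        check_scalar(sac_depth, "sac_depth", 0, strict_lower = TRUE)
        if (abs(sac_depth - Hs_derived) > 1e-9 * r)
          stopf("sac_depth = %g m is inconsistent with dome_radius = %g m and N = %g m (implied depth %g m)",
                sac_depth, r, N, Hs_derived)
      }
      Hs <- Hs_derived
    } else {
      check_scalar(sac_depth, "sac_depth", 0, strict_lower = TRUE)
      Hs <- sac_depth
      r <- Hs / 2 + N^2 / (8 * Hs)
    }
  } else {
    if (is.null(sac_depth))
      stopf("sac_depth is required for an elliptical sac")
    check_scalar(sac_depth, "sac_depth", 0, strict_lower = TRUE)
    Hs <- sac_depth
  }
  if (!no_sac) {
    if (sac_center_arc - N / 2 < 0 || sac_center_arc + N / 2 > L)
      stopf("neck [s0 - N/2, s0 + N/2] = [%g, %g] m must lie within the wall [0, %g] m",
            sac_center_arc - N / 2, sac_center_arc + N / 2, L)
  }
  structure(list(parent_width = D, parent_length = L, curvature = curvature,
                 sac_neck_width = N, sac_depth = Hs, dome_radius = r,
                 sac_shape = sac_shape, sac_center_arc = sac_center_arc,
                 coil_fill_fraction = coil_fill_fraction,
                 has_sac = !no_sac),
            class = "vessel_geometry")
}

#' @rdname build_idealized_aneurysm
#' @param ... passed to \code{build_idealized_aneurysm}.
#' @export
vessel_geometry <- function(...) build_idealized_aneurysm(...)

#' @export
print.vessel_geometry <- function(x, ...) {
  cat(sprintf("<vessel_geometry> D = %g mm, L = %g mm, kappa = %g 1/m\n",
              x$parent_width * 1e3, x$parent_length * 1e3, x$curvature))
  if (x$has_sac) {
    cat(sprintf("  sac: %s, N = %g mm, depth = %g mm, area = %.3f mm^2, f_c = %g\n",
                x$sac_shape, x$sac_neck_width * 1e3, x$sac_depth * 1e3,
                sac_area(x) * 1e6, x$coil_fill_fraction))
  } else cat("  no sac (plain channel)\n")
  invisible(x)
}

# area of the sac above the horizontal line y (y >= D), closed form
sac_area_above <- function(geom, y) {
  if (!geom$has_sac) return(0)
  D <- geom$parent_width; Hs <- geom$sac_depth
  y <- min(max(y, D), D + Hs)
  if (geom$sac_shape == "circular_segment") {
    r <- geom$dome_radius
    cy <- D + Hs - r              # circle centre height
    d <- (y - cy) / r             # signed distance above centre, in radii
    d <- min(max(d, -1), 1)
    r^2 * acos(d) - (y - cy) * sqrt(max(r^2 - (y - cy)^2, 0))
  } else {
    a <- geom$sac_neck_width / 2; b <- geom$sac_depth
    u <- min(max((y - D) / b, 0), 1)
    a * b * (acos(u) - u * sqrt(1 - u^2))
  }
}

#' Analytic sac area
#'
#' Closed-form area of the sac region (m^2); zero for a plain channel.
#' @param geom a \code{\link{vessel_geometry}}.
#' @export
sac_area <- function(geom) {
  if (!inherits(geom, "vessel_geometry")) stopf("'geom' must be a vessel_geometry")
  sac_area_above(geom, geom$parent_width)
}

#' @rdname sac_area
#' @return \code{domain_area()}: channel area plus sac area, m^2.
#' @export
domain_area <- function(geom) {
  geom$parent_width * geom$parent_length + sac_area(geom)
}

# height of the horizontal cut bounding the coil region from below:
# area of sac above the cut equals f_c * sac area (dome packs first)
coil_cut_height <- function(geom, f_c = geom$coil_fill_fraction) {
  D <- geom$parent_width
  if (!geom$has_sac || f_c <= 0) return(D + geom$sac_depth)
  if (f_c >= 1) return(D)
  A <- sac_area(geom)
  stats::uniroot(function(y) sac_area_above(geom, y) - f_c * A,
                 lower = D, upper = D + geom$sac_depth, tol = 1e-13)$root
}

# vectorized indicator: is straightened point (x, y) inside the sac region?
sac_contains <- function(geom, x, y) {
  if (!geom$has_sac) return(rep(FALSE, length(x)))
  D <- geom$parent_width; s0 <- geom$sac_center_arc; Hs <- geom$sac_depth
  if (geom$sac_shape == "circular_segment") {
    r <- geom$dome_radius; cy <- D + Hs - r
    y > D & (x - s0)^2 + (y - cy)^2 <= r^2
  } else {
    a <- geom$sac_neck_width / 2
    y > D & ((x - s0) / a)^2 + ((y - D) / Hs)^2 <= 1
  }
}

#' Neck segment of the sac
#'
#' @param geom a \code{\link{vessel_geometry}}.
#' @return Numeric vector \code{c(x_min, x_max)} of the neck chord on the
#'   wall \eqn{y = D} (straightened coordinates), or \code{NULL} if no sac.
#' @export
neck_segment <- function(geom) {
  if (!geom$has_sac) return(NULL)
  geom$sac_center_arc + c(-0.5, 0.5) * geom$sac_neck_width
}

#' Closed boundary polygon of the geometry
#'
#' Polygon tracing the domain boundary counter-clockwise in straightened
#' coordinates, with the sac arc discretized at \code{n_arc} points.  Used
#' for area checks and VTK geometry export.
#'
#' @param geom a \code{\link{vessel_geometry}}.
#' @param n_arc number of points on the sac arc.
#' @return A two-column matrix (x, y), closed (first point repeated last).
#' @export
geometry_boundary <- function(geom, n_arc = 200L) {
  D <- geom$parent_width; L <- geom$parent_length
  if (!geom$has_sac) {
    pts <- rbind(c(0, 0), c(L, 0), c(L, D), c(0, D), c(0, 0))
    return(pts)
  }
  ns <- neck_segment(geom)
  if (geom$sac_shape == "circular_segment") {
    r <- geom$dome_radius; cy <- D + geom$sac_depth - r; s0 <- geom$sac_center_arc
    th1 <- atan2(D - cy, ns[2] - s0)   # right neck corner
    th2 <- atan2(D - cy, ns[1] - s0)   # left neck corner
    if (th2 <= th1) th2 <- th2 + 2 * pi
    th <- seq(th1, th2, length.out = n_arc)
    arc <- cbind(s0 + r * cos(th), cy + r * sin(th))
  } else {
    a <- geom$sac_neck_width / 2; b <- geom$sac_depth; s0 <- geom$sac_center_arc
    th <- seq(0, pi, length.out = n_arc)
    arc <- cbind(s0 + a * cos(th), D + b * sin(th))
  }
  rbind(c(0, 0), c(L, 0), c(L, D), c(ns[2], D), arc, c(ns[1], D), c(0, D), c(0, 0))
}

#' Bend straightened coordinates onto the curved vessel
#'
#' Maps straightened coordinates (arc length \eqn{x}, cross-channel
#' \eqn{y}) isometrically onto a constant-curvature bend: the channel
#' centerline \eqn{y = D/2} becomes a circular arc of radius
#' \eqn{1/\kappa}.  Identity for \eqn{\kappa = 0}.  Applied to geometry and
#' mesh output only; the flow solve lives in straightened coordinates under
#' a small-curvature approximation.
#'
#' @param geom a \code{\link{vessel_geometry}}.
#' @param xy two-column matrix of straightened coordinates, m.
#' @return Two-column matrix of bent coordinates, m.
#' @export
bend_coordinates <- function(geom, xy) {
  xy <- as.matrix(xy)
  if (geom$curvature == 0) return(xy)
  R0 <- 1 / geom$curvature
  Dh <- geom$parent_width / 2
  th <- xy[, 1] / R0
  rad <- R0 - (xy[, 2] - Dh)  # sac (y > D) bulges toward the bend centre
  cbind(R0 - rad * cos(th), rad * sin(th))
}
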