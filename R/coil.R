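#' Endovascular coil packing as a porous medium
#'
#' Coil embolization is modelled continuum-style: the coil-packed part of
#' the sac is a porous medium of porosity \code{porosity} (void fraction
#' \eqn{\varepsilon}) made of wire of diameter \code{wire_diameter}, which
#' exerts a Darcy-Forchheimer momentum sink on the flow (see
#' \code{\link{momentum_sink}}).  Permeability defaults to the
#' Kozeny-Carman closure (\code{\link{permeability_from_porosity}}) and the
#' inertial coefficient to the Ergun closure
#' \eqn{C_2 = 3.5\,(1-\varepsilon)/(d_w \varepsilon^3)}; both can be
#' overridden.
#'
#' @param porosity void fraction \eqn{\varepsilon} in (0, 1).
#' @param wire_diameter coil wire diameter \eqn{d_w}, m. Default 0.25 mm.
#' @param permeability optional override of the permeability \eqn{k}, m^2.
#' @param inertial_coef optional override of \eqn{C_2}, 1/m.
#' @return An object of class \code{coil_properties}.
#' @examples
#' coil_properties(0.79)
#' coil_properties(0.89)
#' @export
coil_properties <- function(porosity, wire_diameter = 2.5e-4,
                            permeability = NULL, inertial_coef = NULL) {
  check_scalar(porosity, "porosity", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(wire_diameter, "wire_diameter", 0, strict_lower = TRUE)
  if (is.null(permeability))
    permeability <- permeability_from_porosity(porosity, wire_diameter)
  if (is.null(inertial_coef))
    inertial_coef <- 3.5 * (1 - porosity) / (wire_diameter * porosity^3)
  check_scalar(permeability, "permeability", 0, strict_lower = TRUE)
  check_scalar(inertial_coef, "inertial_coef", 0)
  structure(list(porosity = porosity, wire_diameter = wire_diameter,
                 permeability = permeability, inertial_coef = inertial_coef),
            class = "coil_properties")
}

#' @export
print.coil_properties <- function(x, ...) {
  cat(sprintf("<coil_properties> eps = %g, d_w = %g m, k = %.4g m^2, C2 = %.4g 1/m\n",
              x$porosity, x$wire_diameter, x$permeability, x$inertial_coef))
  invisible(x)
}

#' Kozeny-Carman permeability of a coil pack
#'
#' \deqn{k = \frac{\varepsilon^3 d_w^2}{180\,(1-\varepsilon)^2}}
#' Strictly increasing in porosity at fixed wire diameter: a more loosely
#' packed coil (higher \eqn{\varepsilon}) is more permeable, so
#' \eqn{\varepsilon \to 1} recovers the open (uncoiled) sac.
#'
#' @param porosity void fraction in (0, 1); vectorized.
#' @param wire_diameter wire diameter, m.
#' @return Permeability in m^2.
#' @examples
#' permeability_from_porosity(c(0.79, 0.89), 2.5e-4)
#' @export
permeability_from_porosity <- function(porosity, wire_diameter) {
  if (any(!is.finite(porosity)) || any(porosity <= 0) || any(porosity >= 1))
    stopf("porosity must lie strictly in (0, 1)")
  check_scalar(wire_diameter, "wire_diameter", 0, strict_lower = TRUE)
  porosity^3 * wire_diameter^2 / (180 * (1 - porosity)^2)
}

#' Darcy-Forchheimer momentum sink
#'
#' Body-force density exerted by the coil pack on the flow:
#' \deqn{\mathbf{S} = -\frac{\mu}{k}\,\mathbf{u}
#'   - \frac{C_2}{2}\,\rho\,|\mathbf{u}|\,\mathbf{u},}
#' applied on the superficial (physical) velocity.  Always dissipative:
#' \eqn{\mathbf{S}\cdot\mathbf{u} \le 0}.
#'
#' @param u_vec velocity, m/s: numeric vector of length 2 or an n x 2 matrix.
#' @param mu local apparent viscosity, Pa s (scalar or length n).
#' @param rho density, kg/m^3.
#' @param props a \code{\link{coil_properties}} object.
#' @return Force density N/m^3, same shape as \code{u_vec}.
#' @examples
#' cp <- coil_properties(0.79)
#' momentum_sink(c(0.1, 0), mu = 0.0035, rho = 1060, props = cp)
#' @export
momentum_sink <- function(u_vec, mu, rho, props) {
  if (!inherits(props, "coil_properties")) stopf("'props' must be coil_properties")
  vec <- is.null(dim(u_vec))
  U <- if (vec) matrix(u_vec, ncol = 2) else as.matrix(u_vec)
  if (ncol(U) != 2L) stopf("u_vec must have 2 components")
  speed <- sqrt(rowSums(U^2))
  fac <- mu / props$permeability + 0.5 * props$inertial_coef * rho * speed
  S <- -U * fac
  if (vec) drop(S) else S
}
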