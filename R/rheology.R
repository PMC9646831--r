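#' Blood properties with a Casson rheology closure
#'
#' Bundles the physical properties of blood used by the solver: density,
#' haematocrit, and the coefficients of the Casson shear-thinning model
#' \deqn{\mu_{app}(\dot\gamma) = \left(\sqrt{\mu_\infty} +
#'   \sqrt{\tau_y/\dot\gamma}\right)^2,}
#' where \eqn{\mu_\infty} is the asymptotic (high-shear) viscosity and
#' \eqn{\tau_y} the yield stress.  Neither coefficient is a universal
#' constant; both rise with haematocrit.  The default closures are
#' \eqn{\mu_\infty(H) = \mu_p (1-H)^{-2.5}} (Einstein-type hindrance of the
#' plasma viscosity \eqn{\mu_p}) and \eqn{\tau_y(H) = A\,(H - H_c)^3} for
#' \eqn{H > H_c} (zero below the critical haematocrit \eqn{H_c}), with
#' defaults chosen so that \eqn{\tau_y(0.40) \approx 5} mPa, a standard
#' literature value for whole blood.  Every coefficient can be overridden.
#'
#' The Casson law is singular at zero shear; the shear rate is clamped from
#' below at \code{gamma_min} (simplest bounded regularization), so the
#' apparent viscosity is finite everywhere, with maximum
#' \eqn{\mu_{app}(\dot\gamma_{min})}.
#'
#' @param hct haematocrit, red-cell volume fraction in (0, 1). Default 0.40.
#' @param density blood density, kg/m^3. Default 1060.
#' @param plasma_viscosity plasma viscosity \eqn{\mu_p}, Pa s. Default 0.00145.
#' @param yield_coef coefficient \eqn{A} of the yield-stress closure, Pa.
#' @param yield_hct_crit critical haematocrit \eqn{H_c} below which the yield
#'   stress vanishes.
#' @param gamma_min regularization shear rate, 1/s. Default 1e-3.
#' @param model \code{"casson"} or \code{"newtonian"}.  A Newtonian fluid has
#'   \eqn{\tau_y = 0} and constant viscosity \code{mu_inf}.
#' @param mu_inf optional direct override of the asymptotic viscosity, Pa s.
#' @param tau_y optional direct override of the yield stress, Pa.
#' @return An object of class \code{blood_properties}.
#' @examples
#' blood_properties(hct = 0.45)
#' blood_properties(model = "newtonian", mu_inf = 0.0035)
#' @export
blood_properties <- function(hct = 0.40, density = 1060,
                             plasma_viscosity = 0.00145,
                             yield_coef = 0.185, yield_hct_crit = 0.10,
                             gamma_min = 1e-3,
                             model = c("casson", "newtonian"),
                             mu_inf = NULL, tau_y = NULL) {
  model <- match.arg(model)
  check_scalar(hct, "hct", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(density, "density", 0, strict_lower = TRUE)
  check_scalar(plasma_viscosity, "plasma_viscosity", 0, strict_lower = TRUE)
  check_scalar(gamma_min, "gamma_min", 0, strict_lower = TRUE)
  if (is.null(mu_inf)) mu_inf <- plasma_viscosity * (1 - hct)^(-2.5)
  check_scalar(mu_inf, "mu_inf", 0, strict_lower = TRUE)
  if (mu_inf < plasma_viscosity)
    stopf("mu_inf (%g) must be >= plasma_viscosity (%g)", mu_inf, plasma_viscosity)
  if (is.null(tau_y))
    tau_y <- if (model == "newtonian") 0 else yield_coef * max(hct - yield_hct_crit, 0)^3
  check_scalar(tau_y, "tau_y", 0)
  if (model == "newtonian" && tau_y != 0)
    stopf("a newtonian model must have tau_y = 0 (got %g)", tau_y)
  structure(list(density = density, hct = hct,
                 plasma_viscosity = plasma_viscosity,
                 mu_inf = mu_inf, tau_y = tau_y,
                 gamma_min = gamma_min, model = model),
            class = "blood_properties")
}

#' @export
print.blood_properties <- function(x, ...) {
  cat(sprintf("<blood_properties> %s, HCT = %.2f\n", x$model, x$hct))
  cat(sprintf("  rho = %g kg/m^3, mu_inf = %.4g Pa.s, tau_y = %.4g Pa, gamma_min = %g 1/s\n",
              x$density, x$mu_inf, x$tau_y, x$gamma_min))
  invisible(x)
}

#' Casson apparent viscosity
#'
#' Apparent viscosity \eqn{\mu_{app} = (\sqrt{\mu_\infty} +
#' \sqrt{\tau_y/\max(\dot\gamma, \dot\gamma_{min})})^2} at shear rate
#' \code{gamma_dot}.  Vectorized over \code{gamma_dot}; finite for all
#' inputs including zero shear thanks to the \code{gamma_min} clamp.
#'
#' @param gamma_dot shear rate(s), 1/s, non-negative.
#' @param props a \code{\link{blood_properties}} object.
#' @return Apparent viscosity in Pa s, same shape as \code{gamma_dot}.
#' @examples
#' bp <- blood_properties(hct = 0.40)
#' casson_viscosity(c(1, 10, 100, 1000), bp)
#' @export
casson_viscosity <- function(gamma_dot, props) {
  if (!inherits(props, "blood_properties")) stopf("'props' must be blood_properties")
  if (any(!is.finite(gamma_dot)) || any(gamma_dot < 0))
    stopf("shear rate must be finite and non-negative")
  if (props$tau_y == 0) {
    out <- gamma_dot; out[] <- props$mu_inf
    return(out)
  }
  g <- pmax(gamma_dot, props$gamma_min)
  (sqrt(props$mu_inf) + sqrt(props$tau_y / g))^2
}
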