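#' Carreau-Yasuda blood rheology parameters
#'
#' Bundles the constants of the four-parameter Carreau-Yasuda
#' shear-thinning law together with the blood density.  Defaults
#' correspond to whole blood at 40 % hematocrit and 37 C.
#'
#' @param mu0 Zero-shear-rate viscosity (Pa s).
#' @param mu_inf Infinite-shear-rate viscosity (Pa s).
#' @param tau Relaxation time (s).
#' @param n_index Power-law index (dimensionless, in (0, 1]).
#' @param a_param Yasuda transition parameter (dimensionless, > 0).
#' @param rho Blood density (kg/m^3).
#' @return An object of class \code{cy_params}.
#' @export
#' @examples
#' p <- cy_params()
#' cy_viscosity(0, p)    # zero-shear plateau, 0.0456 Pa s
#' cy_viscosity(1e6, p)  # approaches mu_inf
cy_params <- function(mu0 = 0.0456, mu_inf = 0.00320, tau = 10.03,
                      n_index = 0.344, a_param = 1.25, rho = 1050) {
  stopifnot(mu0 >= mu_inf, mu_inf > 0, tau > 0,   # equality = Newtonian limit
            n_index > 0, n_index <= 1, a_param > 0, rho > 0)
  structure(list(mu0 = mu0, mu_inf = mu_inf, tau = tau,
                 n_index = n_index, a_param = a_param, rho = rho),
            class = "cy_params")
}

#' Carreau-Yasuda viscosity
#'
#' mu(gdot) = mu_inf + (mu0 - mu_inf) * [1 + (tau gdot)^a]^((n-1)/a).
#' Strictly decreasing in the shear rate, bounded in (mu_inf, mu0].
#'
#' @param gamma_dot Shear rate (1/s), non-negative; vectorized.
#' @param p A \code{cy_params} object.
#' @return Dynamic viscosity (Pa s).
#' @export
cy_viscosity <- function(gamma_dot, p = cy_params()) {
  if (any(gamma_dot < 0)) stop("shear rate must be non-negative")
  p$mu_inf + (p$mu0 - p$mu_inf) *
    (1 + (p$tau * gamma_dot)^p$a_param)^((p$n_index - 1) / p$a_param)
}

#' Shear rate from a velocity-gradient tensor
#'
#' The scalar shear rate is the second invariant of the
#' rate-of-deformation tensor eps = (G + G^T)/2:
#' gdot = sqrt(2 eps : eps).  The antisymmetric (rotational) part of the
#' gradient does not contribute.
#'
#' @param grad_u A 2x2 or 3x3 velocity-gradient matrix (du_i/dx_j, 1/s).
#' @return Shear rate (1/s), non-negative.
#' @export
shear_rate <- function(grad_u) {
  stopifnot(is.matrix(grad_u), nrow(grad_u) == ncol(grad_u),
            nrow(grad_u) %in% c(2L, 3L), all(is.finite(grad_u)))
  eps <- (grad_u + t(grad_u)) / 2
  sqrt(2 * sum(eps * eps))
}

#' Local wall shear stress with Weissenberg-Rabinowitsch correction
#'
#' WSS = (3n + 1) / (4n) * mu * gdot * delta_sac, where delta_sac masks
#' positions outside the aneurysm sac.  The prefactor corrects the
#' Newtonian wall-shear estimate for shear-thinning; it is exactly 1 for
#' n = 1.  The result is reported in dyne/cm^2 (1 Pa = 10 dyne/cm^2).
#'
#' @param gamma_dot Wall shear rate (1/s); vectorized.
#' @param mu Local viscosity (Pa s); recycled against \code{gamma_dot}.
#' @param in_sac Logical mask: TRUE on intra-saccular wall positions.
#' @param p A \code{cy_params} object (supplies the power-law index).
#' @return Wall shear stress (dyne/cm^2).
#' @export
wss_local <- function(gamma_dot, mu, in_sac = TRUE, p = cy_params()) {
  if (any(gamma_dot < 0)) stop("shear rate must be non-negative")
  n <- p$n_index
  pref <- (3 * n + 1) / (4 * n)
  10 * pref * mu * gamma_dot * as.numeric(in_sac)
}
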