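#' Toroidal stent envelope
#'
#' The braided stent is generated on a toroidal envelope inscribed in the
#' parent artery.  The surface is parametrized by the azimuthal angle
#' \code{theta} and the centerline arc length \code{s}:
#' \deqn{((r(s)\cos\theta + R)\cos(s/R),\ (r(s)\cos\theta + R)\sin(s/R),\
#'        r(s)\sin\theta)}
#' with a slowly varying minor radius
#' \eqn{r(s) = r_{prox}(1 - s/l) + r_{dist}\, s/l}.
#'
#' The winding factor \code{k} of a design advances the wire azimuth as
#' \eqn{\theta(s) = \theta_0 \pm 2\pi k s / L_{ref}} where the reference
#' pitch length \code{L_ref} is a single calibration constant.  By default
#' it is fixed so that \code{k = 25} yields a 75-degree braiding angle on
#' the default envelope (minor radius 1.75 mm), which places the
#' \code{k in \{20..35\}} family in the nominal 65-95 degree range.
#'
#' @param r_prox Proximal minor radius (mm).
#' @param r_dist Distal minor radius (mm).
#' @param R Major (centerline curvature) radius (mm).
#' @param l Centerline length (mm).
#' @param reference_pitch_length Calibration constant \code{L_ref} (mm);
#'   \code{NULL} calibrates it so that winding factor 25 gives a
#'   75-degree braiding angle at the mean minor radius.
#' @return An object of class \code{envelope_spec}.
#' @export
#' @examples
#' env <- make_envelope(1.75, 1.75, 20, 20)
#' envelope_point(env, theta = 0, s = 0)  # (r_prox + R, 0, 0)
make_envelope <- function(r_prox = 1.75, r_dist = 1.75, R = 20, l = 20,
                          reference_pitch_length = NULL) {
  if (any(c(r_prox, r_dist, R, l) <= 0))
    stop("invalid geometry: all envelope lengths must be positive")
  if (r_prox >= R || r_dist >= R)
    stop("invalid geometry: minor radii must be smaller than the major radius")
  rbar <- (r_prox + r_dist) / 2
  if (abs(r_prox - r_dist) / rbar > 0.5)
    stop("minor radii violate the slowly varying envelope assumption")
  if (is.null(reference_pitch_length))
    reference_pitch_length <- calibrate_pitch(rbar)
  stopifnot(reference_pitch_length > 0)
  structure(list(r_prox = r_prox, r_dist = r_dist, R = R, l = l,
                 reference_pitch_length = reference_pitch_length),
            class = "envelope_spec")
}

#' Reference pitch length for a target braiding angle
#'
#' Solves \eqn{2\arctan(2\pi k\, r / L_{ref}) = \beta} for \code{L_ref}.
#'
#' @param r Minor radius used for calibration (mm).
#' @param k Winding factor at which the target angle is attained.
#' @param angle_deg Target braiding angle (degrees).
#' @return Calibrated pitch length (mm).
#' @export
calibrate_pitch <- function(r = 1.75, k = 25, angle_deg = 75) {
  stopifnot(r > 0, k > 0, angle_deg > 0, angle_deg < 180)
  2 * pi * k * r / tan(angle_deg * pi / 360)
}

#' Minor radius at arc length s
#' @param env An \code{envelope_spec}.
#' @param s Arc length along the centerline (mm), in [0, l].
#' @return Minor radius (mm).
#' @export
envelope_radius <- function(env, s) {
  env$r_prox * (1 - s / env$l) + env$r_dist * s / env$l
}

#' Envelope surface point
#' @param env An \code{envelope_spec}.
#' @param theta Azimuthal angle (radians); vectorized with \code{s}.
#' @param s Arc length (mm).
#' @return A matrix with columns x, y, z (mm).
#' @export
envelope_point <- function(env, theta, s) {
  r <- envelope_radius(env, s)
  w <- r * cos(theta) + env$R
  cbind(x = w * cos(s / env$R), y = w * sin(s / env$R), z = r * sin(theta))
}

#' Distance of points from the envelope surface
#'
#' Used to verify that generated wire centerlines lie on the envelope.
#' @param env An \code{envelope_spec}.
#' @param pts An n x 3 matrix of points (mm).
#' @return Absolute radial deviation from the surface (mm).
#' @export
envelope_surface_error <- function(env, pts) {
  phi <- atan2(pts[, 2], pts[, 1])
  s <- phi * env$R
  s <- pmin(pmax(s, 0), env$l)
  w <- sqrt(pts[, 1]^2 + pts[, 2]^2) - env$R
  abs(sqrt(w^2 + pts[, 3]^2) - envelope_radius(env, s))
}
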