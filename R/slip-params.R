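#' Parameters of the augmented bipedal SLIP walker
#'
#' Constructs the parameter set for a three-dimensional bipedal spring-loaded
#' inverted pendulum (SLIP) augmented with leg dampers and sagittal- and
#' frontal-plane rotary spring-dampers.  Each leg carries seven mechanism
#' constants plus fixed touchdown angles; the body is a point mass.
#'
#' World axes are fixed as (anterior-posterior, vertical, mediolateral), with
#' the mediolateral axis positive to the walker's left and the ground plane at
#' height 0.
#'
#' @param M body mass (kg).
#' @param g gravitational acceleration magnitude (m/s^2).
#' @param L_bio biological leg length (m), used for normalization.
#' @param k_L leg stiffness (N/m); scalar (both legs) or named vector
#'   `c(R = , L = )`.
#' @param L_0 leg resting length (m); scalar or per-leg.
#' @param c_L leg damping (N s/m); scalar or per-leg.
#' @param k_s,c_s sagittal-plane rotary stiffness (N m/rad) and damping
#'   (N m s/rad); scalar or per-leg.
#' @param k_f,c_f frontal-plane rotary stiffness and damping; scalar or
#'   per-leg.
#' @param theta_td sagittal touchdown angle of the swing leg from vertical
#'   (rad, positive forward).
#' @param phi_td frontal touchdown angle from vertical (rad, positive lateral,
#'   i.e. the foot lands outside the CoM for both legs).
#' @param speed nominal forward (belt) speed (m/s); metadata used when
#'   constructing initial conditions.
#' @param k_sag,k_lat foot-placement feedback gains (s/m-scaled direction
#'   adjustments per unit CoM-velocity error) in the sagittal and frontal
#'   planes.  Zero gives a strictly fixed touchdown angle; small nonzero
#'   values implement the standard discrete foot-placement stabilization of
#'   walking SLIP models.  Placement feedback changes where the feet land,
#'   never the stance force law.
#' @param vx_ref,vz_ref reference CoM velocities at touchdown (m/s) for the
#'   placement feedback; `vz_ref` is mirrored between legs.
#' @param rotary_mode direction convention for the rotary force terms:
#'   `"as_printed"` applies them along the leg vector scaled by the inverse
#'   squared planar projection; `"transverse"` applies them perpendicular to
#'   the in-plane leg projection.  The default matches the regression library.
#'
#' @return An object of class `slip_params`: a list with scalars `M`, `g`,
#'   `L_bio`, `theta_td`, `phi_td`, `speed`, `rotary_mode` and a `legs` list
#'   with per-leg mechanism constants.
#' @export
#' @examples
#' p <- slip_params(M = 70, k_L = 12000, L_0 = 0.98)
#' p$legs$R$k_L
slip_params <- function(M = 70, g = 9.81, L_bio = 1.0,
                        k_L = 12000, L_0 = 0.98, c_L = 0,
                        k_s = 0, c_s = 0, k_f = 0, c_f = 0,
                        theta_td = 0.36, phi_td = 0.06,
                        speed = 1.2,
                        k_sag = 0, k_lat = 0, vx_ref = speed, vz_ref = 0,
                        rotary_mode = c("as_printed", "transverse")) {
  rotary_mode <- match.arg(rotary_mode)
  stopifnot(M > 0, g > 0, L_bio > 0)
  per_leg <- function(x, nm) {
    if (length(x) == 1L) x <- c(R = unname(x), L = unname(x))
    if (!all(c("R", "L") %in% names(x)))
      stop("per-leg parameter '", nm, "' must be scalar or named c(R=,L=)")
    x[c("R", "L")]
  }
  k_L <- per_leg(k_L, "k_L"); L_0 <- per_leg(L_0, "L_0")
  c_L <- per_leg(c_L, "c_L"); k_s <- per_leg(k_s, "k_s")
  c_s <- per_leg(c_s, "c_s"); k_f <- per_leg(k_f, "k_f")
  c_f <- per_leg(c_f, "c_f")
  if (any(k_L <= 0)) stop("k_L must be > 0")
  if (any(L_0 <= 0) || any(L_0 > 1.2 * L_bio))
    stop("L_0 must satisfy 0 < L_0 <= 1.2 * L_bio")
  if (any(c(c_L, c_s, c_f) < 0)) stop("damping values must be >= 0")
  legs <- lapply(c(R = "R", L = "L"), function(j) {
    list(k_L = k_L[[j]], L_0 = L_0[[j]], c_L = c_L[[j]],
         k_s = k_s[[j]], c_s = c_s[[j]], k_f = k_f[[j]], c_f = c_f[[j]])
  })
  structure(list(M = M, g = g, L_bio = L_bio, legs = legs,
                 theta_td = theta_td, phi_td = phi_td, speed = speed,
                 placement = list(k_sag = k_sag, k_lat = k_lat,
                                  vx_ref = vx_ref, vz_ref = vz_ref),
                 rotary_mode = rotary_mode),
            class = "slip_params")
}

#' @export
print.slip_params <- function(x, ...) {
  cat("Augmented bipedal SLIP parameters\n")
  cat(sprintf("  M = %.3g kg, g = %.4g m/s^2, L_bio = %.3g m\n",
              x$M, x$g, x$L_bio))
  for (j in c("R", "L")) {
    l <- x$legs[[j]]
    cat(sprintf("  leg %s: k_L=%.4g  L_0=%.4g  c_L=%.3g  k_s=%.3g  c_s=%.3g  k_f=%.3g  c_f=%.3g\n",
                j, l$k_L, l$L_0, l$c_L, l$k_s, l$c_s, l$k_f, l$c_f))
  }
  cat(sprintf("  touchdown angles: theta_td=%.4g rad, phi_td=%.4g rad; speed=%.3g m/s\n",
              x$theta_td, x$phi_td, x$speed))
  invisible(x)
}

# mediolateral mirror sign per leg: frontal leg angle is measured positive
# toward the contralateral side, so the two legs use opposite ML signs.
.ml_sign <- c(R = 1, L = -1)

#' Dimensionless (normalized) view of a SLIP parameter set
#'
#' Converts the raw mechanism constants of a [slip_params()] object into the
#' normalized coefficients used for reporting: dimensionless leg stiffness
#' `kappa_L = k_L * L_bio / (M g)`, normalized resting length
#' `L0_tilde = L_0 / L_bio`, damping ratios and dimensionless rotary
#' stiffnesses.
#'
#' @param params a `slip_params` object.
#' @return A data frame with one row per (leg, coefficient).
#' @seealso [normalize_mechanisms()] for the scalar transformation.
#' @export
ground_truth_signature <- function(params) {
  out <- lapply(c("R", "L"), function(j) {
    l <- params$legs[[j]]
    nn <- normalize_mechanisms(k_L = l$k_L, L_0 = l$L_0, c_L = l$c_L,
                               k_s = l$k_s, c_s = l$c_s,
                               k_f = l$k_f, c_f = l$c_f,
                               M = params$M, g = params$g,
                               L_bio = params$L_bio)
    data.frame(leg = j, coefficient = names(nn), value = unname(unlist(nn)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
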