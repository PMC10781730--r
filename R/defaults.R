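# Canonical ground-truth gait fixture.
#
# A conservative pure bipedal SLIP (leg springs only) at human-scale
# dimensionless values (kappa_L = 16.7, L0_tilde = 0.97), with the initial
# state sitting on a Newton-converged periodic orbit of the stride map and
# small discrete foot-placement feedback keeping the laterally neutral gait
# bounded over 100+ strides.  All constants below are frozen so that every
# test and example exercises the same deterministic gait.

.FP_STATE <- list(
  vel = c(1.11678470564158583, -0.37837850368130849, -0.03563883780141069),
  com = c(-0.34170600627683723, 0.90652452522222537, 0.04847979419255798),
  foot_L = c(-0.47587341330232000, 0, 0.08846155290965410)
)

#' Canonical ground-truth SLIP parameter set
#'
#' The default synthetic walker: a conservative bipedal SLIP (no dampers, no
#' rotary mechanisms) with dimensionless leg stiffness `kappa_L = 16.7` and
#' normalized resting length `L0_tilde = 0.97` -- the average human values the
#' identification pipeline should recover -- walking at about 1.1 m/s with a
#' 0.86 s stride period.  Foot-placement feedback gains are set about the
#' periodic orbit so the gait stays bounded for at least 100 strides.
#'
#' @return A [slip_params()] object.
#' @export
#' @examples
#' p <- default_gait_params()
#' ground_truth_signature(p)
default_gait_params <- function() {
  slip_params(M = 70, g = 9.81, L_bio = 1.0,
              k_L = 16.7 * 70 * 9.81, L_0 = 0.97, c_L = 0,
              k_s = 0, c_s = 0, k_f = 0, c_f = 0,
              theta_td = 0.36, phi_td = 0.05, speed = 1.2,
              k_sag = 0.2, k_lat = 0.4,
              vx_ref = .FP_STATE$vel[1], vz_ref = .FP_STATE$vel[3])
}

#' Periodic initial state of the canonical gait
#'
#' The walker state at a right-leg touchdown on the periodic orbit of
#' [default_gait_params()]: the right foot has just been placed at the
#' touchdown angles, the left (trailing) leg is still loaded.
#'
#' @return An initial-state list accepted by [simulate_slip()].
#' @export
default_gait_state <- function() {
  list(com = .FP_STATE$com, vel = .FP_STATE$vel,
       feet = list(R = c(0, 0, 0), L = .FP_STATE$foot_L),
       trailing = "L")
}

#' Simulate the canonical synthetic walking trial
#'
#' Convenience wrapper: simulates the frozen ground-truth gait for a given
#' number of strides and optionally adds measurement noise.
#'
#' @param n_strides strides to record (default 40, about 35 s at 120 Hz).
#' @param sd_pos position noise standard deviation (m); 0 for a noise-free
#'   trial.
#' @param seed noise seed (ignored when `sd_pos = 0`).
#' @param dt sampling interval (s).
#' @return A [trial] object.
#' @export
#' @examples
#' \donttest{
#' tr <- canonical_trial(n_strides = 5)
#' tr
#' }
canonical_trial <- function(n_strides = 40, sd_pos = 0, seed = 1, dt = 1 / 120) {
  p <- default_gait_params()
  tr <- simulate_slip(p, default_gait_state(), n_strides = n_strides, dt = dt)
  if (sd_pos > 0) tr <- add_noise(tr, sd_pos = sd_pos, seed = seed)
  tr
}
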