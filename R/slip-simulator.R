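# Forward simulation of the augmented bipedal SLIP walker.
#
# The walker is a hybrid system: single-limb support (one spring leg loaded),
# double-limb support (both loaded), with touchdown and liftoff events.  Legs
# are massless, so swing-leg motion does not feed back on the CoM; recorded
# swing-foot trajectories are reconstructed after integration.

.G_DIR <- c(0, -1, 0)  # gravity direction in (AP, vertical, ML) axes

# force exerted on the CoM by one loaded leg (world frame)
.leg_force <- function(q, v, lp, s, rotary_mode) {
  L2 <- sum(q * q)
  if (L2 < 1e-12) stop("leg vector has zero length")
  L <- sqrt(L2)
  Ldot <- sum(q * v) / L
  f <- -(lp$k_L * (L - lp$L_0) + lp$c_L * Ldot) * q / L
  if (lp$k_s != 0 || lp$c_s != 0) {
    Ls2 <- q[1]^2 + q[2]^2
    if (Ls2 < 1e-12) stop("sagittal leg projection vanishes with nonzero rotary gains")
    theta <- atan2(q[1], q[2])
    thetadot <- (v[1] * q[2] - q[1] * v[2]) / Ls2
    mag <- lp$k_s * theta + lp$c_s * thetadot
    dir <- if (rotary_mode == "as_printed") q else c(q[2], -q[1], 0)
    f <- f - mag * dir / Ls2
  }
  if (lp$k_f != 0 || lp$c_f != 0) {
    Lf2 <- q[3]^2 + q[2]^2
    if (Lf2 < 1e-12) stop("frontal leg projection vanishes with nonzero rotary gains")
    phi <- atan2(s * q[3], q[2])
    phidot <- s * (v[3] * q[2] - q[3] * v[2]) / Lf2
    mag <- lp$k_f * phi + lp$c_f * phidot
    dir <- if (rotary_mode == "as_printed") q else c(0, -s * q[3], s * q[2])
    f <- f - mag * dir / Lf2
  }
  f
}

#' CoM acceleration of the augmented bipedal SLIP
#'
#' Evaluates the instantaneous center-of-mass acceleration produced by the
#' loaded legs of the augmented SLIP model: for every leg in contact, a radial
#' spring-damper along the leg plus sagittal- and frontal-plane rotary
#' spring-damper terms, divided by body mass, plus gravity.  Legs not in
#' contact contribute no force.
#'
#' @param com_rel named list (`R`, `L`) of CoM-minus-foot 3-vectors (m) in
#'   (AP, vertical, ML) axes; entries for inactive legs may be `NULL`.
#' @param vel_rel named list of CoM-velocity-minus-foot-velocity 3-vectors
#'   (m/s); for stance feet this is just the CoM velocity.
#' @param active_legs character subset of `c("R", "L")`: legs in contact.
#' @param params a [slip_params()] object.
#' @return CoM acceleration 3-vector (m/s^2).
#' @export
#' @examples
#' p <- slip_params(M = 70, k_L = 10000, L_0 = 1, c_L = 0)
#' # unloaded vertical leg at rest length: pure gravity
#' slip_acceleration(list(R = c(0, 1, 0)), list(R = c(0, 0, 0)), "R", p)
slip_acceleration <- function(com_rel, vel_rel, active_legs, params) {
  stopifnot(all(active_legs %in% c("R", "L")))
  f <- c(0, 0, 0)
  for (j in active_legs) {
    f <- f + .leg_force(com_rel[[j]], vel_rel[[j]], params$legs[[j]],
                        .ml_sign[[j]], params$rotary_mode)
  }
  params$g * .G_DIR + f / params$M
}

# unit vector from CoM to the virtual landing point of leg j.  With nonzero
# placement gains the nominal touchdown angles are adjusted by the CoM
# velocity error (discrete foot-placement stabilization); at the reference
# velocities the direction reduces to the fixed touchdown angles.
.touchdown_dir <- function(params, j, vel = NULL) {
  sx <- sin(params$theta_td)
  sz <- sin(params$phi_td)
  cy <- sqrt(1 - sx^2 - sz^2)
  u <- c(sx, -cy, -.ml_sign[[j]] * sz)
  pl <- params$placement
  if (!is.null(vel) && !is.null(pl) && (pl$k_sag != 0 || pl$k_lat != 0)) {
    u[1] <- u[1] + pl$k_sag * (vel[1] - pl$vx_ref)
    u[3] <- u[3] + pl$k_lat * (vel[3] - .ml_sign[[j]] * pl$vz_ref)
    u <- u / sqrt(sum(u * u))
  }
  u
}

#' Construct the mid-single-support initial state of the walker
#'
#' @param params a [slip_params()] object.
#' @param com,vel CoM position and velocity 3-vectors; defaults place the CoM
#'   nearly over a right foot at the origin, moving forward at `params$speed`.
#' @param stance_leg which leg is initially loaded.
#' @return A list with `com`, `vel`, `foot`, `stance_leg`.
#' @export
slip_initial_state <- function(params, com = NULL, vel = NULL,
                               stance_leg = "R") {
  if (is.null(com)) com <- c(0, 0.97 * params$legs[[stance_leg]]$L_0,
                             .ml_sign[[stance_leg]] * 0.02)
  if (is.null(vel)) vel <- c(params$speed, 0, 0)
  list(com = com, vel = vel, foot = c(0, 0, 0), stance_leg = stance_leg)
}

.gait_failure <- function(msg, trial = NULL) {
  stop(errorCondition(msg, trial = trial,
                      class = c("templatesig_gait_failure", "error")))
}

#' Simulate walking of the augmented bipedal SLIP
#'
#' Integrates the hybrid walker with adaptive Runge-Kutta/Adams integration
#' (`deSolve::lsodar`) and root-based event handling: the swing leg touches
#' down when its virtual landing point -- placed at the fixed touchdown angles
#' with length `L_0` from the CoM -- reaches ground height, and a trailing
#' stance leg lifts off when its spring returns to rest length.  Foot
#' positions are fixed while in stance; swing-foot trajectories are filled in
#' afterwards with a smooth minimum-jerk path between liftoff and touchdown
#' points (legs are massless, so this is bookkeeping, not dynamics).
#'
#' If the center of mass drops below `fall_frac * L_bio`, or the stance leg
#' unloads with no other foot on the ground (a flight phase), the gait has
#' failed and an error of class `"templatesig_gait_failure"` is signalled; the
#' partial trajectory is attached to the condition as `$trial`.
#'
#' @param params a [slip_params()] object.
#' @param initial_state from [slip_initial_state()]; `NULL` uses its defaults.
#' @param n_strides number of complete strides (right touchdown to right
#'   touchdown) to record.
#' @param dt sampling interval of the recorded trial (s); default 1/120 s,
#'   a standard motion-capture rate.
#' @param fall_frac fall threshold as a fraction of `L_bio`.
#' @param rtol,atol relative/absolute integration tolerances.
#' @return A [trial] object (see [new_trial()]) with simulated CoM and foot
#'   trajectories, contact flags, and the exact event table in
#'   `$events`.  CoM velocities from the integrator are kept in `$com_vel`.
#' @export
simulate_slip <- function(params, initial_state = NULL, n_strides = 110,
                          dt = 1 / 120, fall_frac = 0.4,
                          rtol = 1e-9, atol = 1e-10) {
  if (dt <= 0) stop("dt must be positive")
  if (is.null(initial_state)) initial_state <- slip_initial_state(params)
  mode_horizon <- 3.0  # s; no gait event within this long is a failure
  fall_y <- fall_frac * params$L_bio

  deriv <- function(t, y, parms, stance_feet) {
    com <- y[1:3]; vel <- y[4:6]
    qs <- lapply(stance_feet, function(fp) com - fp)
    vs <- lapply(stance_feet, function(fp) vel)
    acc <- slip_acceleration(qs, vs, names(stance_feet), params)
    list(c(vel, acc))
  }

  # roots: [1] fall, [2] touchdown of swing leg (if any), [3] liftoff of
  # trailing leg (if any)
  make_root <- function(stance_feet, swing_leg, trailing_leg) {
    function(t, y, parms, ...) {
      com <- y[1:3]
      r <- com[2] - fall_y
      r2 <- if (!is.null(swing_leg)) {
        u <- .touchdown_dir(params, swing_leg, y[4:6])
        com[2] + params$legs[[swing_leg]]$L_0 * u[2]
      } else 1
      r3 <- if (!is.null(trailing_leg)) {
        q <- com - stance_feet[[trailing_leg]]
        sqrt(sum(q * q)) - params$legs[[trailing_leg]]$L_0
      } else -1
      c(r, r2, r3)
    }
  }

  # state of the loop; initial_state may describe single support (fields
  # `foot`, `stance_leg`) or double support (`feet` named list + `trailing`)
  t_cur <- 0
  y_cur <- c(initial_state$com, initial_state$vel)
  if (!is.null(initial_state$feet)) {
    stance_feet <- initial_state$feet
    trailing_leg <- initial_state$trailing
    swing_leg <- NULL
  } else {
    stance_feet <- stats::setNames(list(initial_state$foot),
                                   initial_state$stance_leg)
    swing_leg <- setdiff(c("R", "L"), initial_state$stance_leg)
    trailing_leg <- NULL          # only set in double support
  }
  stride_count <- 0
  events <- list()
  rec_t <- numeric(0); rec_y <- NULL
  rec_cR <- logical(0); rec_cL <- logical(0)
  rec_fR <- NULL; rec_fL <- NULL  # stance-foot rows; NA while swinging
  grid_next <- 0                  # next sample time to record

  record_segment <- function(out, t_stop) {
    # out: lsodar matrix; keep grid rows in (t_cur, t_stop]
    on_grid <- abs(out[, 1] / dt - round(out[, 1] / dt)) < 1e-6
    keep <- on_grid & out[, 1] >= grid_next - 1e-9 & out[, 1] <= t_stop + 1e-9
    rows <- out[keep, , drop = FALSE]
    if (nrow(rows) == 0) return(invisible())
    fR <- if ("R" %in% names(stance_feet))
      matrix(stance_feet$R, nrow(rows), 3, byrow = TRUE) else
      matrix(NA_real_, nrow(rows), 3)
    fL <- if ("L" %in% names(stance_feet))
      matrix(stance_feet$L, nrow(rows), 3, byrow = TRUE) else
      matrix(NA_real_, nrow(rows), 3)
    rec_t <<- c(rec_t, rows[, 1])
    rec_y <<- rbind(rec_y, rows[, 2:7, drop = FALSE])
    rec_cR <<- c(rec_cR, rep("R" %in% names(stance_feet), nrow(rows)))
    rec_cL <<- c(rec_cL, rep("L" %in% names(stance_feet), nrow(rows)))
    rec_fR <<- rbind(rec_fR, fR)
    rec_fL <<- rbind(rec_fL, fL)
    grid_next <<- (floor(max(rows[, 1]) / dt + 0.5) + 1) * dt
  }

  partial_trial <- function() {
    if (length(rec_t) < 2) return(NULL)
    .assemble_trial(rec_t, rec_y, rec_fR, rec_fL, rec_cR, rec_cL,
                    events, params, stride_count, dt)
  }

  repeat {
    times <- c(t_cur, seq(grid_next, t_cur + mode_horizon, by = dt))
    times <- times[!duplicated(signif(times, 12))]
    rootf <- make_root(stance_feet, swing_leg, trailing_leg)
    out <- deSolve::lsodar(y = y_cur, times = times,
                           func = deriv, parms = NULL,
                           stance_feet = stance_feet,
                           rootfunc = rootf, rtol = rtol, atol = atol)
    troot <- attr(out, "troot")
    iroot <- which(attr(out, "iroot") == 1L)
    if (is.null(troot) || length(troot) == 0)
      .gait_failure(sprintf("gait failed at stride %d: no gait event within %.1f s",
                            stride_count, mode_horizon), partial_trial())
    t_ev <- troot[1]
    record_segment(out, t_ev)
    y_ev <- as.numeric(out[nrow(out), 2:7])
    t_cur <- t_ev; y_cur <- y_ev

    if (1 %in% iroot)
      .gait_failure(sprintf("gait failed at stride %d: CoM fell below %.2f m",
                            stride_count, fall_y), partial_trial())

    if (!is.null(swing_leg) && 2 %in% iroot && y_cur[5] > 0) {
      # virtual landing point crossed ground height while the CoM was rising
      # (mid-vault): not a touchdown.  Nudge past the root and continue.
      nudge <- deSolve::lsoda(y = y_cur, times = c(t_cur, t_cur + 1e-7),
                              func = deriv, parms = NULL,
                              stance_feet = stance_feet,
                              rtol = rtol, atol = atol)
      t_cur <- nudge[nrow(nudge), 1]
      y_cur <- as.numeric(nudge[nrow(nudge), 2:7])
      next
    }

    if (!is.null(swing_leg) && 2 %in% iroot) {
      # touchdown: place the swing foot, enter double support
      com <- y_cur[1:3]
      u <- .touchdown_dir(params, swing_leg, y_cur[4:6])
      foot_new <- com + params$legs[[swing_leg]]$L_0 * u
      foot_new[2] <- 0
      events[[length(events) + 1]] <-
        data.frame(time = t_cur, leg = swing_leg, type = "touchdown",
                   com_x = com[1], com_y = com[2], com_z = com[3],
                   vel_x = y_cur[4], vel_y = y_cur[5], vel_z = y_cur[6])
      if (swing_leg == "R") {
        stride_count <- stride_count + 1
        if (stride_count >= n_strides) {
          trial <- partial_trial()
          if (is.null(trial))
            .gait_failure("trial too short to assemble", NULL)
          return(trial)
        }
      }
      trailing_leg <- names(stance_feet)[1]
      stance_feet[[swing_leg]] <- foot_new
      swing_leg <- NULL
    } else if (!is.null(trailing_leg) && 3 %in% iroot) {
      # liftoff of the trailing leg: back to single support
      events[[length(events) + 1]] <-
        data.frame(time = t_cur, leg = trailing_leg, type = "liftoff",
                   com_x = y_cur[1], com_y = y_cur[2], com_z = y_cur[3],
                   vel_x = y_cur[4], vel_y = y_cur[5], vel_z = y_cur[6])
      stance_feet[[trailing_leg]] <- NULL
      swing_leg <- trailing_leg
      trailing_leg <- NULL
    } else if (3 %in% iroot && is.null(trailing_leg)) {
      .gait_failure(sprintf(
        "gait failed at stride %d: stance leg unloaded in single support (flight)",
        stride_count), partial_trial())
    }
  }
}

# build a trial object from raw recorded segments; fills swing-foot paths
.assemble_trial <- function(rec_t, rec_y, rec_fR, rec_fL, rec_cR, rec_cL,
                            events, params, stride_count, dt) {
  ord <- order(rec_t)
  t <- rec_t[ord]
  com <- rec_y[ord, 1:3, drop = FALSE]
  vel <- rec_y[ord, 4:6, drop = FALSE]
  fR <- rec_fR[ord, , drop = FALSE]; fL <- rec_fL[ord, , drop = FALSE]
  cR <- rec_cR[ord]; cL <- rec_cL[ord]
  fR <- .fill_swing_foot(t, com, fR, cR, params, "R")
  fL <- .fill_swing_foot(t, com, fL, cL, params, "L")
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(time = numeric(0), leg = character(0), type = character(0),
               com_x = numeric(0), com_y = numeric(0), com_z = numeric(0),
               vel_x = numeric(0), vel_y = numeric(0), vel_z = numeric(0))
  new_trial(t = t, com = com, foot_R = fR, foot_L = fL,
            contact_R = cR, contact_L = cL,
            M = params$M, L_bio = params$L_bio, g = params$g,
            provenance = "synthetic",
            com_vel = vel, events = ev, params = params,
            n_strides = stride_count)
}

# swing path between liftoff and touchdown points: a symmetric sigmoid with
# steep ends (feet leave and meet the ground briskly, as at toe-off and heel
# strike) plus a vertical clearance bump; open-ended swings track the
# virtual landing point
.fill_swing_foot <- function(t, com, foot, contact, params, j) {
  n <- length(t)
  clearance <- 0.06 * params$L_bio
  u <- .touchdown_dir(params, j)
  L0 <- params$legs[[j]]$L_0
  virt <- function(i) {
    p <- com[i, ] + L0 * u
    p
  }
  i <- 1
  while (i <= n) {
    if (!contact[i]) {
      i0 <- i
      while (i <= n && !contact[i]) i <- i + 1
      i1 <- i - 1                      # swing block [i0, i1]
      has_prev <- i0 > 1
      has_next <- i1 < n
      p0 <- if (has_prev) foot[i0 - 1, ] else NULL
      p1 <- if (has_next) foot[i1 + 1, ] else NULL
      for (s in i0:i1) {
        if (has_prev && has_next) {
          tau <- (t[s] - t[i0 - 1]) / (t[i1 + 1] - t[i0 - 1])
          w <- tau^3 * (10 - 15 * tau + 6 * tau^2)
          p <- p0 + w * (p1 - p0)
          # sqrt-sine profile: the foot clears the ground within the first
          # sample after toe-off, as a briskly lifted heel does
          p[2] <- p[2] + clearance * sqrt(sin(pi * tau))
          foot[s, ] <- p
        } else {
          foot[s, ] <- virt(s)         # trial edge: virtual landing point
        }
      }
    } else i <- i + 1
  }
  foot
}

#' Walking trial container
#'
#' A synchronized recording of CoM and foot trajectories with contact flags
#' and subject constants -- either simulated ([simulate_slip()]) or read from
#' measured data ([read_trial()]).  Axes are (anterior-posterior, vertical,
#' mediolateral); positions in metres on a uniform time base.
#'
#' @param t time vector (s), uniformly spaced.
#' @param com,foot_R,foot_L m x 3 position matrices.
#' @param contact_R,contact_L logical contact flags (may be `NULL` for
#'   measured data without contact information).
#' @param M,L_bio,g subject constants (kg, m, m/s^2).
#' @param provenance `"synthetic"` or `"measured"`.
#' @param com_vel optional m x 3 CoM velocities (simulator output only).
#' @param events optional event table (`time`, `leg`, `type`).
#' @param params optional generating [slip_params()].
#' @param n_strides optional stride count.
#' @param noise_seed seed used by [add_noise()], if any.
#' @return An object of class `trial`.
#' @export
new_trial <- function(t, com, foot_R, foot_L, contact_R = NULL,
                      contact_L = NULL, M, L_bio, g = 9.81,
                      provenance = "measured", com_vel = NULL,
                      events = NULL, params = NULL, n_strides = NA,
                      noise_seed = NULL) {
  m <- length(t)
  t <- unname(as.numeric(t))
  com <- unname(as.matrix(com)); foot_R <- unname(as.matrix(foot_R))
  foot_L <- unname(as.matrix(foot_L))
  stopifnot(nrow(com) == m, nrow(foot_R) == m, nrow(foot_L) == m,
            ncol(com) == 3, M > 0, L_bio > 0, g > 0)
  if (m >= 2) {
    dts <- diff(t)
    if (max(abs(dts - dts[1])) > 1e-6 * dts[1])
      stop("trial time base must be uniform")
  }
  if (!is.null(contact_R)) {
    stopifnot(length(contact_R) == m, length(contact_L) == m)
    if (any(!contact_R & !contact_L))
      stop("walking trial must have at least one foot in contact at every sample")
  }
  colnames(com) <- colnames(foot_R) <- colnames(foot_L) <- c("x", "y", "z")
  structure(list(t = t, com = com, foot_R = foot_R, foot_L = foot_L,
                 contact_R = contact_R, contact_L = contact_L,
                 M = M, L_bio = L_bio, g = g, provenance = provenance,
                 com_vel = com_vel, events = events, params = params,
                 n_strides = n_strides, noise_seed = noise_seed,
                 dt = if (m >= 2) t[2] - t[1] else NA_real_),
            class = "trial")
}

#' @export
print.trial <- function(x, ...) {
  cat(sprintf("Walking trial (%s): %d samples at %.1f Hz (%.1f s)",
              x$provenance, length(x$t), 1 / x$dt, diff(range(x$t))))
  if (!is.na(x$n_strides)) cat(sprintf(", %d strides", x$n_strides))
  cat(sprintf("\n  M = %.3g kg, L_bio = %.3g m\n", x$M, x$L_bio))
  invisible(x)
}

#' Add measurement noise to a trial
#'
#' Adds i.i.d. zero-mean Gaussian noise to the CoM and foot positions,
#' emulating marker-based motion-capture error.  Contact flags, time base and
#' subject constants are unchanged.  Deterministic for a fixed seed; the
#' caller's RNG state is restored on exit.
#'
#' @param trial a [trial] object.
#' @param sd_pos noise standard deviation (m); default 1 mm.
#' @param seed integer seed.
#' @return A new `trial` with perturbed positions and `noise_seed` recorded.
#' @export
add_noise <- function(trial, sd_pos = 0.001, seed = 1) {
  stopifnot(sd_pos >= 0)
  if (sd_pos == 0) return(trial)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- length(trial$t)
  jitter <- function(x) x + matrix(stats::rnorm(3 * m, 0, sd_pos), m, 3)
  out <- trial
  out$com <- jitter(trial$com)
  out$foot_R <- jitter(trial$foot_R)
  out$foot_L <- jitter(trial$foot_L)
  out$noise_seed <- seed
  out
}

#' Total mechanical energy along a simulated trajectory
#'
#' Kinetic plus gravitational plus elastic leg-spring energy at every sample
#' of a noise-free simulated trial.  For a conservative parameter set (all
#' damping and rotary gains zero) this is constant to integration tolerance.
#' Rotary-term energy is not included: in the `"as_printed"` force convention
#' the rotary terms are non-conservative by construction.
#'
#' @param trial a simulated [trial] with `com_vel` present.
#' @param params the generating [slip_params()]; defaults to `trial$params`.
#' @return Numeric vector of energies (J), one per sample.
#' @export
slip_energy <- function(trial, params = trial$params) {
  if (is.null(trial$com_vel)) stop("trial lacks com_vel (not simulator output?)")
  v2 <- rowSums(trial$com_vel^2)
  E <- 0.5 * params$M * v2 + params$M * params$g * trial$com[, 2]
  for (j in c("R", "L")) {
    contact <- if (j == "R") trial$contact_R else trial$contact_L
    foot <- if (j == "R") trial$foot_R else trial$foot_L
    q <- trial$com - foot
    L <- sqrt(rowSums(q^2))
    lp <- params$legs[[j]]
    E <- E + ifelse(contact, 0.5 * lp$k_L * (L - lp$L_0)^2, 0)
  }
  E
}
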