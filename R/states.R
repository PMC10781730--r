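# Template state computation: per-leg lengths, angles and velocities, CoM
# accelerations, continuous gait phase and hybrid gait-phase labels.
#
# Hybrid gait is only piecewise smooth: leg forces switch at touchdown and
# liftoff, so accelerations have corners (jerk discontinuities) at contact
# transitions.  The default differentiation scheme is therefore a degree-6
# regression spline whose knots carry multiplicity 4 at every contact event
# — the spline is C2 there, exactly the smoothness class of the true motion
# — fitted by least squares and differentiated analytically.  To keep the
# noise in the regression library independent of the noise in the
# acceleration target, the spline is cross-fitted: states are evaluated from
# a fit to the odd-indexed samples and accelerations from a fit to the
# even-indexed samples.  A Savitzky-Golay filter is available as an
# alternative for data without hybrid structure.

.PHASE_LEVELS <- c("DS1", "SS_R", "DS2", "SS_L")

#' Smoothing / differentiation settings
#'
#' @param method `"spline"` (default): event-knot regression spline with
#'   analytic derivatives, cross-fitted on interleaved sample halves;
#'   `"sgolay"`: global Savitzky-Golay smoothing differentiation.
#' @param window odd filter window length (samples; `sgolay` only).
#' @param polyorder local polynomial order (`sgolay` only).
#' @param spline_ord B-spline order for `"spline"` (7 = degree 6).
#' @param cross_fit fit states and accelerations on disjoint interleaved
#'   sample halves so their noise is independent (`"spline"` only).
#' @return List of class `smoothing_config`.
#' @export
smoothing_config <- function(method = c("spline", "sgolay"),
                             window = 31, polyorder = 3,
                             spline_ord = 7, cross_fit = TRUE) {
  method <- match.arg(method)
  stopifnot(window %% 2 == 1, polyorder < window, spline_ord >= 5)
  structure(list(method = method, window = window, polyorder = polyorder,
                 spline_ord = spline_ord, cross_fit = cross_fit),
            class = "smoothing_config")
}

.sg_deriv <- function(x, dt, m, cfg) {
  signal::sgolayfilt(x, p = cfg$polyorder, n = cfg$window, m = m, ts = dt)
}

# B-spline design with full knot multiplicity at interior event times: the
# basis is an independent degree-(ord-1) polynomial on every contact
# segment.  Hybrid dynamics are only piecewise smooth, and the per-phase
# force balance holds segment by segment, so estimation never couples
# across an event.  Sparse: rows have at most `ord` nonzeros.
.event_basis <- function(t, event_t, ord, derivs = 0) {
  ev <- event_t[event_t > t[1] + 1e-9 & event_t < t[length(t)] - 1e-9]
  knots <- sort(c(rep(range(t), ord), rep(ev, ord)))
  splines::splineDesign(knots, t, ord = ord, derivs = derivs, sparse = TRUE)
}

# design matrices (value, first, second derivative) shared across all series
# of a trial
.spline_bases <- function(t, event_t, ord) {
  lapply(0:2, function(d) .event_basis(t, event_t, ord, d))
}

# least-squares spline fit on the samples in fit_idx; returns d0/d1/d2 at
# every sample for each column of X, plus the fitted coefficients
.spline_derivs <- function(X, bases, fit_idx) {
  X <- cbind(X)
  Af <- bases[[1]][fit_idx, , drop = FALSE]
  G <- Matrix::crossprod(Af)
  # tiny ridge guards segments with fewer fitting samples than coefficients
  G <- G + Matrix::Diagonal(ncol(G), 1e-9 * mean(Matrix::diag(G)))
  cf <- as.matrix(Matrix::solve(G, Matrix::crossprod(Af,
                                X[fit_idx, , drop = FALSE])))
  list(d0 = as.matrix(bases[[1]] %*% cf),
       d1 = as.matrix(bases[[2]] %*% cf),
       d2 = as.matrix(bases[[3]] %*% cf),
       cf = cf)
}

#' Compute template states from a walking trial
#'
#' Converts CoM and foot trajectories into the candidate template-signature
#' states: for each leg, the leg length `L` (CoM-to-foot distance), the
#' sagittal-plane leg angle from vertical `theta` (positive with the CoM
#' anterior to the foot), the frontal-plane leg angle `phi` (positive toward
#' the contralateral side, mirrored between legs), their time derivatives,
#' the planar projection lengths `L_s` and `L_f`, plus the CoM acceleration,
#' the continuous gait phase `psi` and categorical gait-phase labels.
#'
#' Angles are planar-projection angles: `theta` in the AP-vertical plane,
#' `phi` in the ML-vertical plane.
#'
#' @param trial a [trial] object.
#' @param smoothing a [smoothing_config()].
#' @param reference_leg leg whose phase portrait defines `psi`.
#' @return An object of class `template_states`; `$seg` holds the contact
#'   segment id of every sample.
#' @export
compute_states <- function(trial, smoothing = smoothing_config(),
                           reference_leg = "R") {
  m <- length(trial$t)
  if (m < 4 * smoothing$window)
    stop("trial too short for state computation")
  if (anyNA(trial$com) || anyNA(trial$foot_R) || anyNA(trial$foot_L))
    stop("NaN/NA in trial positions")
  dt <- trial$dt

  contact_R <- trial$contact_R
  contact_L <- trial$contact_L
  if (is.null(contact_R)) {
    cc <- detect_contacts(trial, smoothing = smoothing)
    contact_R <- cc$contact_R; contact_L <- cc$contact_L
  }
  seg <- cumsum(c(TRUE, diff(contact_R) != 0 | diff(contact_L) != 0))

  if (smoothing$method == "spline") {
    bnd <- which(diff(seg) != 0)
    event_t <- (trial$t[bnd] + trial$t[bnd + 1]) / 2
    bases <- .spline_bases(trial$t, event_t, smoothing$spline_ord)
    idx_states <- if (smoothing$cross_fit) seq(1, m, 2) else seq_len(m)
    idx_acc <- if (smoothing$cross_fit) seq(2, m, 2) else seq_len(m)
    sd_acc <- .spline_derivs(trial$com, bases, idx_acc)
    com_acc <- sd_acc$d2
    sd_com <- .spline_derivs(trial$com, bases, idx_states)
    com_s <- sd_com$d0
    spline_cf <- list(com_states = sd_com$cf, com_acc = sd_acc$cf)
    legs <- lapply(c(R = "R", L = "L"), function(j) {
      foot_raw <- if (j == "R") trial$foot_R else trial$foot_L
      sd_foot <- .spline_derivs(foot_raw, bases, idx_states)
      foot <- sd_foot$d0
      q <- com_s - foot
      L <- sqrt(rowSums(q^2))
      theta <- atan2(q[, 1], q[, 2])
      phi <- atan2(.ml_sign[[j]] * q[, 3], q[, 2])
      sd_leg <- .spline_derivs(cbind(L, theta, phi), bases, idx_states)
      spline_cf[[paste0("foot_", j)]] <<- sd_foot$cf
      spline_cf[[paste0("leg_", j)]] <<- sd_leg$cf
      d1 <- sd_leg$d1
      list(q_rel = q, L = L,
           Ls = sqrt(q[, 1]^2 + q[, 2]^2), Lf = sqrt(q[, 3]^2 + q[, 2]^2),
           theta = theta, phi = phi,
           Ldot = d1[, 1], thetadot = d1[, 2], phidot = d1[, 3])
    })
    spline_info <- list(event_t = event_t, ord = smoothing$spline_ord,
                        idx_acc = idx_acc, cf = spline_cf)
  } else {
    spline_info <- NULL
    legs <- lapply(c(R = "R", L = "L"), function(j) {
      foot <- if (j == "R") trial$foot_R else trial$foot_L
      q <- trial$com - foot
      L <- sqrt(rowSums(q^2))
      theta <- atan2(q[, 1], q[, 2])
      phi <- atan2(.ml_sign[[j]] * q[, 3], q[, 2])
      list(q_rel = q, L = L,
           Ls = sqrt(q[, 1]^2 + q[, 2]^2), Lf = sqrt(q[, 3]^2 + q[, 2]^2),
           theta = theta, phi = phi,
           Ldot = .sg_deriv(L, dt, 1, smoothing),
           thetadot = .sg_deriv(theta, dt, 1, smoothing),
           phidot = .sg_deriv(phi, dt, 1, smoothing))
    })
    com_acc <- apply(trial$com, 2, .sg_deriv, dt = dt, m = 2, cfg = smoothing)
  }
  colnames(com_acc) <- c("x", "y", "z")

  st <- structure(list(t = trial$t, dt = dt, n = m, legs = legs,
                       com_acc = com_acc, seg = seg, spline = spline_info,
                       contact_R = contact_R, contact_L = contact_L,
                       gait_phase = label_gait_phases(contact_R, contact_L),
                       M = trial$M, L_bio = trial$L_bio, g = trial$g,
                       reference_leg = reference_leg,
                       smoothing = smoothing),
                  class = "template_states")
  st$psi <- compute_phase(st, reference_leg)
  st
}

#' @export
print.template_states <- function(x, ...) {
  cat(sprintf("Template states: %d samples at %.1f Hz (%s differentiation)\n",
              x$n, 1 / x$dt, x$smoothing$method))
  print(table(x$gait_phase))
  invisible(x)
}

#' Samples with trustworthy derivative estimates
#'
#' Returns the sample indices at least `edge_trim` samples away from the
#' boundary of their contact segment (and from the trial's ends), where the
#' spline/filter derivative estimates are most reliable.  The pipeline
#' restricts the regression system to these samples.
#'
#' @param states a `template_states` object.
#' @param edge_trim samples discarded at each end of every contact segment.
#' @return Integer vector of retained sample indices.
#' @export
state_sample_mask <- function(states, edge_trim = 2) {
  unlist(lapply(split(seq_len(states$n), states$seg), function(s) {
    if (length(s) > 2 * edge_trim)
      s[(edge_trim + 1):(length(s) - edge_trim)] else integer(0)
  }), use.names = FALSE)
}

#' Continuous gait phase from the reference leg's phase portrait
#'
#' The phase variable `psi` (percent of stride, in \[0, 100)) is the wrapped
#' angle of the point (theta, thetadot) in the reference leg's normalized
#' phase portrait: each coordinate is centered and scaled to unit amplitude,
#' and the angle is shifted so `psi = 0` at the reference leg's heel strike
#' (rising contact edge).  `psi` is used both as the clustering distance and
#' to normalize stride progression.
#'
#' @param states a `template_states` object.
#' @param reference_leg `"R"` or `"L"`.
#' @return Numeric vector of phases in percent.
#' @export
compute_phase <- function(states, reference_leg = "R") {
  th <- states$legs[[reference_leg]]$theta
  thd <- states$legs[[reference_leg]]$thetadot
  amp_th <- (max(th) - min(th)) / 2
  amp_thd <- (max(thd) - min(thd)) / 2
  if (amp_th < 1e-8 || amp_thd < 1e-8)
    stop("phase undefined: reference leg angle has no oscillation")
  th_h <- (th - (max(th) + min(th)) / 2) / amp_th
  thd_h <- (thd - (max(thd) + min(thd)) / 2) / amp_thd
  alpha <- atan2(-thd_h, th_h)
  psi <- (alpha / (2 * pi) * 100) %% 100

  contact <- if (reference_leg == "R") states$contact_R else states$contact_L
  hs <- which(diff(c(FALSE, contact)) == 1)
  if (length(hs) > 0) {
    a <- psi[hs] / 100 * 2 * pi
    shift <- atan2(mean(sin(a)), mean(cos(a))) / (2 * pi) * 100
    psi <- (psi - shift) %% 100
  }
  psi
}

#' Label hybrid gait phases from contact flags
#'
#' Gait phases are the hybrid regimes of walking defined by foot contact:
#' both feet down following a right heel strike is first double support
#' (`DS1`), right-only is right single support (`SS_R`), both down following
#' a left heel strike is second double support (`DS2`), left-only is `SS_L`.
#'
#' @param contact_R,contact_L logical contact flags.
#' @return Factor with levels `DS1`, `SS_R`, `DS2`, `SS_L`.
#' @export
#' @examples
#' label_gait_phases(c(TRUE, TRUE, FALSE, FALSE), c(FALSE, TRUE, TRUE, TRUE))
label_gait_phases <- function(contact_R, contact_L) {
  m <- length(contact_R)
  stopifnot(length(contact_L) == m)
  if (any(!contact_R & !contact_L))
    stop("neither foot in contact: not walking data")
  # last heel strike at each sample (carry rising edges forward); a trial
  # beginning in double support is ambiguous at sample 1 and resolved by the
  # backfill below (the leg still down at the first liftoff struck last)
  last_hs <- rep(NA_character_, m)
  last_hs[which(diff(contact_R) == 1) + 1L] <- "R"
  last_hs[which(diff(contact_L) == 1) + 1L] <- "L"
  if (contact_R[1] && !contact_L[1]) last_hs[1] <- "R"
  if (contact_L[1] && !contact_R[1]) last_hs[1] <- "L"
  for (i in seq_len(m)[-1]) if (is.na(last_hs[i])) last_hs[i] <- last_hs[i - 1]
  # leading samples still NA: the trial starts in double support; the leg
  # that keeps contact at the first liftoff is the one that struck last
  if (anyNA(last_hs)) {
    first_ss <- which(xor(contact_R, contact_L))[1]
    if (is.na(first_ss)) stop("cannot label gait phases: no single support")
    fill <- if (contact_R[first_ss]) "R" else "L"
    # the inferred leg struck before the window; only backfill the leading
    # stretch, everything later is covered by observed edges
    last_hs[seq_len(which(!is.na(last_hs))[1] - 1L)] <- fill
  }
  lab <- ifelse(contact_R & contact_L,
                ifelse(last_hs == "R", "DS1", "DS2"),
                ifelse(contact_R, "SS_R", "SS_L"))
  factor(lab, levels = .PHASE_LEVELS)
}

#' Detect foot contact from foot kinematics
#'
#' Fallback for trials without contact flags: a foot is in contact when its
#' vertical position is below a height threshold and its speed is below a
#' velocity threshold.  Samples where neither foot qualifies are assigned to
#' the lower foot so the walking assumption holds.
#'
#' @param trial a [trial] object.
#' @param height_frac height threshold as a fraction of `L_bio`.
#' @param speed_max speed threshold (m/s).
#' @param smoothing a [smoothing_config()]; its Savitzky-Golay settings are
#'   used for the foot-velocity estimate.
#' @return List with logical `contact_R`, `contact_L`.
#' @export
detect_contacts <- function(trial, height_frac = 0.02, speed_max = 0.2,
                            smoothing = smoothing_config()) {
  dt <- trial$dt
  one <- function(foot) {
    # one-sided speeds, combined by min(): a sample is "slow" if it is
    # stationary on either side, so stance samples bordering a swing are not
    # contaminated by the neighboring swing motion
    step <- sqrt(rowSums(diff(foot)^2)) / dt  # speed of step i -> i+1
    speed <- pmin(c(step, Inf), c(Inf, step))
    foot[, 2] < height_frac * trial$L_bio & speed < speed_max
  }
  cR <- one(trial$foot_R); cL <- one(trial$foot_L)
  none <- !cR & !cL
  if (any(none)) {
    lower_R <- trial$foot_R[, 2] <= trial$foot_L[, 2]
    cR[none & lower_R] <- TRUE
    cL[none & !lower_R] <- TRUE
  }
  list(contact_R = cR, contact_L = cL)
}
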