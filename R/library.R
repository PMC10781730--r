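# The mechanism function library.
#
# Fourteen columns (7 per leg), constructed so that each column multiplies
# exactly one dimensionless target coefficient: the radial spring is split
# into a -q/L_bio part (coefficient kappa_L) and a +q/L part (coefficient
# kappa_L * L0_tilde); the radial damper and both rotary spring-dampers each
# contribute one column on a linear dimensionless scale.  The regression
# target is (qdd - g)/g, i.e. the specific leg force in units of body weight,
# so fitted coefficients are directly the normalized signature quantities
# (damping surrogates are converted to ratios afterwards).

.MECH_NAMES <- c("kappa_L", "kappa_L_L0", "c_L_tilde", "kappa_s", "c_s_tilde",
                 "kappa_f", "c_f_tilde")

# 4th-order cumulative integration on a uniform grid; when `seg` is given,
# stencils never cross segment boundaries (the integrand has corners there)
# and the single boundary-crossing step falls back to the trapezoid rule
.cumint4 <- function(f, dt, seg = NULL) {
  n <- length(f)
  inc <- rep(NA_real_, n - 1)
  blocks <- if (is.null(seg)) list(seq_len(n)) else split(seq_len(n), seg)
  for (s in blocks) {
    ns <- length(s)
    if (ns < 2) next
    if (ns < 4) {
      inc[s[-ns]] <- dt * (f[s[-ns]] + f[s[-1]]) / 2
      next
    }
    ii <- 2:(ns - 2)
    inc[s[ii]] <- dt * (-f[s[ii - 1]] + 13 * f[s[ii]] + 13 * f[s[ii + 1]] -
                          f[s[ii + 2]]) / 24
    inc[s[1]] <- dt * (9 * f[s[1]] + 19 * f[s[2]] - 5 * f[s[3]] + f[s[4]]) / 24
    inc[s[ns - 1]] <- dt * (9 * f[s[ns]] + 19 * f[s[ns - 1]] -
                              5 * f[s[ns - 2]] + f[s[ns - 3]]) / 24
  }
  miss <- which(is.na(inc))
  if (length(miss)) inc[miss] <- dt * (f[miss] + f[miss + 1]) / 2
  c(0, cumsum(inc))
}

# integral-form columns: evaluate the mechanism columns from the state
# splines on an `up`-times refined grid, double-integrate, fit with the same
# event-knot spline as the positions (on the acceleration fit samples) and
# differentiate twice.  Columns and target then pass through the identical
# linear observation operator, so the true coefficient vector satisfies the
# regression system to quadrature accuracy.
.projected_columns <- function(states, rotary_mode, up) {
  sp <- states$spline
  t <- states$t; m <- states$n; dt <- states$dt
  dtf <- dt / up
  n_f <- (m - 1L) * up + 1L
  tf <- t[1] + (0:(n_f - 1L)) * dtf
  tf[n_f] <- t[m]
  A0f <- .event_basis(tf, sp$event_t, sp$ord, 0)
  A1f <- .event_basis(tf, sp$event_t, sp$ord, 1)
  seg_f <- findInterval(tf, sp$event_t) + 1L

  com_f <- as.matrix(A0f %*% sp$cf$com_states)
  fine_cols <- matrix(0, n_f, 42)  # 2 legs x 7 mechanisms x 3 directions
  for (jn in 1:2) {
    j <- c("R", "L")[jn]
    foot_f <- as.matrix(A0f %*% sp$cf[[paste0("foot_", j)]])
    st_f <- as.matrix(A0f %*% sp$cf[[paste0("leg_", j)]])
    d1_f <- as.matrix(A1f %*% sp$cf[[paste0("leg_", j)]])
    q_f <- com_f - foot_f
    cols <- .leg_columns(q_f, st_f[, 1], q_f[, 1]^2 + q_f[, 2]^2,
                         q_f[, 3]^2 + q_f[, 2]^2, st_f[, 2], st_f[, 3],
                         d1_f[, 1], d1_f[, 2], d1_f[, 3], .ml_sign[[j]],
                         states$L_bio, states$g, rotary_mode)
    for (c_i in 1:7) for (d in 1:3)
      fine_cols[, (jn - 1L) * 21 + (c_i - 1L) * 3 + d] <- cols[[c_i]][, d]
  }

  ds_rows <- seq(1L, n_f, by = up)        # fine index of each sample
  I2 <- apply(fine_cols, 2, function(f)
    .cumint4(.cumint4(f, dtf, seg_f), dtf)[ds_rows])

  bases <- .spline_bases(t, sp$event_t, sp$ord)
  Af <- bases[[1]][sp$idx_acc, , drop = FALSE]
  G <- Matrix::crossprod(Af)
  G <- G + Matrix::Diagonal(ncol(G), 1e-9 * mean(Matrix::diag(G)))
  cf <- Matrix::solve(G, Matrix::crossprod(Af, I2[sp$idx_acc, , drop = FALSE]))
  proj <- as.matrix(bases[[3]] %*% cf)     # m x 42

  out <- list(R = vector("list", 7), L = vector("list", 7))
  for (jn in 1:2) for (c_i in 1:7)
    out[[jn]][[c_i]] <- proj[, (jn - 1L) * 21 + (c_i - 1L) * 3 + (1:3),
                             drop = FALSE]
  out
}

# per-leg pointwise column block (m x 3 per mechanism) from state series
.leg_columns <- function(q, L, Ls2, Lf2, th, ph, Ld, thd, phd, s,
                         L_bio, g, rotary_mode) {
  dir_s <- if (rotary_mode == "as_printed") q else cbind(q[, 2], -q[, 1], 0)
  dir_f <- if (rotary_mode == "as_printed") q else
    cbind(0, -s * q[, 3], s * q[, 2])
  list(
    -q / L_bio,                                   # kappa_L
    q / L,                                        # kappa_L * L0_tilde
    -(Ld / sqrt(g * L_bio)) * q / L,              # c_L_tilde
    -th * L_bio * dir_s / Ls2,                    # kappa_s
    -thd * L_bio * sqrt(L_bio / g) * dir_s / Ls2, # c_s_tilde
    -ph * L_bio * dir_f / Lf2,                    # kappa_f
    -phd * L_bio * sqrt(L_bio / g) * dir_f / Lf2) # c_f_tilde
}

#' Build the mechanism library and regression target
#'
#' Assembles the stacked regression system `theta %*% xi = target` over the
#' retained samples: for every sample the three spatial directions (AP,
#' vertical, ML) contribute three consecutive rows.  Gravity is moved to the
#' target side; no library column represents it.
#'
#' Both legs' columns are always present -- regimes where a leg swings are
#' not masked out; sparsity decides which mechanisms act.
#'
#' @param states a [compute_states()] result.
#' @param sample_mask optional logical or integer vector of samples to
#'   retain (default: all).
#' @param rotary_mode direction convention for the rotary columns; the
#'   default `"as_printed"` applies them along the leg vector scaled by the
#'   inverse squared planar projection, matching [slip_acceleration()];
#'   `"transverse"` applies them perpendicular to the in-plane projection.
#' @param form `"projected"` (default with spline differentiation): the
#'   integral-form library — each mechanism column is double-integrated in
#'   time on a refined grid, fitted with the same event-knot spline as the
#'   positions, and differentiated twice, so columns and target pass through
#'   the identical linear observation operator and the spline reconstruction
#'   error cancels from the regression residual instead of acting as a
#'   spurious fittable signal.  `"pointwise"`: the plain sampled columns.
#' @param upsample grid refinement factor for the integral form.
#' @return Object of class `library_matrix`: list with `theta` (3m' x 14),
#'   `target` (3m'), `columns` (metadata data frame), `samples` (retained
#'   sample indices), `row_sample`, `row_dir` (row maps), and subject
#'   constants `M`, `L_bio`, `g`.
#' @export
build_library <- function(states, sample_mask = NULL,
                          rotary_mode = c("as_printed", "transverse"),
                          form = c("projected", "pointwise"),
                          upsample = 8) {
  rotary_mode <- match.arg(rotary_mode)
  form <- match.arg(form)
  if (is.null(states$spline)) form <- "pointwise"
  idx <- if (is.null(sample_mask)) seq_len(states$n)
         else if (is.logical(sample_mask)) which(sample_mask)
         else as.integer(sample_mask)
  m <- length(idx)
  L_bio <- states$L_bio; g <- states$g

  for (j in c("R", "L")) {
    lg <- states$legs[[j]]
    bad <- which(lg$Ls[idx] < 1e-6 * L_bio | lg$Lf[idx] < 1e-6 * L_bio)
    if (length(bad))
      stop("degenerate planar leg projection at samples ",
           paste(utils::head(idx[bad], 5), collapse = ", "),
           if (length(bad) > 5) " ..." else "")
  }

  col_series <- if (form == "projected")
    .projected_columns(states, rotary_mode, upsample)
  else {
    lapply(c(R = "R", L = "L"), function(j) {
      lg <- states$legs[[j]]
      .leg_columns(lg$q_rel, lg$L, lg$Ls^2, lg$Lf^2, lg$theta, lg$phi,
                   lg$Ldot, lg$thetadot, lg$phidot, .ml_sign[[j]],
                   L_bio, g, rotary_mode)
    })
  }

  theta <- matrix(0, 3 * m, 14)
  for (jn in 1:2) {
    j <- c("R", "L")[jn]
    for (c_i in 1:7) {
      col3 <- col_series[[j]][[c_i]][idx, , drop = FALSE]
      theta[, (jn - 1) * 7 + c_i] <- as.vector(t(col3))  # rows: x,y,z per sample
    }
  }
  acc <- states$com_acc[idx, , drop = FALSE]
  gvec <- matrix(rep(c(0, -g, 0), m), m, 3, byrow = TRUE)
  target <- as.vector(t((acc - gvec) / g))

  columns <- data.frame(
    column = 1:14,
    leg = rep(c("R", "L"), each = 7),
    mechanism = rep(.MECH_NAMES, 2),
    stringsAsFactors = FALSE)
  colnames(theta) <- paste(columns$leg, columns$mechanism, sep = ".")

  structure(list(theta = theta, target = target, columns = columns,
                 samples = idx, form = form,
                 row_sample = rep(idx, each = 3),
                 row_dir = rep(c("x", "y", "z"), m),
                 M = states$M, L_bio = L_bio, g = g),
            class = "library_matrix")
}

#' @export
print.library_matrix <- function(x, ...) {
  cat(sprintf("Mechanism library: %d samples x 3 directions = %d rows, 14 columns\n",
              length(x$samples), nrow(x$theta)))
  invisible(x)
}

# rows of the stacked system belonging to the given sample indices
.lib_rows <- function(lib, sample_idx) {
  pos <- match(sample_idx, lib$samples)
  if (anyNA(pos)) stop("sample indices outside the library mask")
  as.vector(t(outer(pos - 1, 1:3, function(p, d) 3 * p + d)))
}

#' Ground-truth library-scale coefficients of a SLIP parameter set
#'
#' The 14-vector of coefficients that, multiplied with the library of
#' [build_library()] (in `"as_printed"` mode), reproduces the simulated leg
#' forces exactly: per leg `(kappa_L, kappa_L * L0_tilde, c_L_tilde, kappa_s,
#' c_s_tilde, kappa_f, c_f_tilde)`.
#'
#' @param params a [slip_params()] object.
#' @return Named numeric 14-vector.
#' @export
true_coefficients <- function(params) {
  M <- params$M; g <- params$g; L_bio <- params$L_bio
  one <- function(l) {
    kappa_L <- l$k_L * L_bio / (M * g)
    c(kappa_L,
      kappa_L * l$L_0 / L_bio,
      l$c_L * sqrt(L_bio / g) / M,
      l$k_s / (M * g * L_bio),
      l$c_s / (M * sqrt(g * L_bio^3)),
      l$k_f / (M * g * L_bio),
      l$c_f / (M * sqrt(g * L_bio^3)))
  }
  out <- c(one(params$legs$R), one(params$legs$L))
  names(out) <- paste(rep(c("R", "L"), each = 7), rep(.MECH_NAMES, 2), sep = ".")
  out
}

#' Restrict ground-truth coefficients to the legs actually loaded
#'
#' In a gait phase where a leg swings it exerts no force; the ground-truth
#' coefficient vector for that phase has zeros in the swing leg's columns.
#'
#' @param params a [slip_params()] object.
#' @param loaded character vector of loaded legs.
#' @return Named numeric 14-vector.
#' @export
true_coefficients_phase <- function(params, loaded = c("R", "L")) {
  xi <- true_coefficients(params)
  if (!"R" %in% loaded) xi[1:7] <- 0
  if (!"L" %in% loaded) xi[8:14] <- 0
  xi
}
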