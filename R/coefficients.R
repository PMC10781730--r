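# Normalization of mechanism constants and bootstrap coefficient estimation.
#
# Reported template-signature coefficients are dimensionless: stiffnesses are
# scaled by body weight and leg length, the resting length by leg length, and
# damping constants are converted to damping ratios.  Internally the
# regression estimates damping on a linear dimensionless scale (see
# build_library()); the ratio conversion happens here because the damping
# ratios are nonlinear in the estimated stiffnesses.

.COEF_NAMES <- c("kappa_L", "L0_tilde", "zeta_L", "kappa_s", "zeta_s",
                 "kappa_f", "zeta_f")

#' Normalize raw mechanism constants
#'
#' Converts raw per-leg mechanism constants into the dimensionless reporting
#' form: `kappa_L = k_L L_bio / (M g)`, `L0_tilde = L_0 / L_bio`,
#' `zeta_L = c_L / (2 sqrt(k_L M))`, `kappa_s = k_s / (M g L_bio)`,
#' `zeta_s = c_s / sqrt(kappa_s M L_bio^2)` and the frontal-plane analogues.
#' Note that the rotary damping ratios intentionally use the *normalized*
#' stiffness inside the radical; this convention is kept for comparability
#' even though it mixes normalized and raw symbols.
#'
#' A damping ratio whose associated stiffness is zero (or negative) is
#' undefined and reported as `NA`, never as 0 or infinity.
#'
#' @param k_L,L_0,c_L,k_s,c_s,k_f,c_f raw mechanism constants (SI units).
#' @param M body mass (kg); @param g gravity (m/s^2); @param L_bio leg
#'   length (m).
#' @return Named list with `kappa_L`, `L0_tilde`, `zeta_L`, `kappa_s`,
#'   `zeta_s`, `kappa_f`, `zeta_f`.
#' @seealso [denormalize_mechanisms()] for the exact inverse.
#' @export
#' @examples
#' normalize_mechanisms(k_L = 10000, L_0 = 0.9, c_L = 100, k_s = 50, c_s = 5,
#'                      k_f = 0, c_f = 0, M = 70, g = 9.81, L_bio = 0.9)
normalize_mechanisms <- function(k_L, L_0, c_L = 0, k_s = 0, c_s = 0,
                                 k_f = 0, c_f = 0, M, g, L_bio) {
  stopifnot(M > 0, g > 0, L_bio > 0)
  kappa_L <- k_L * L_bio / (M * g)
  kappa_s <- k_s / (M * g * L_bio)
  kappa_f <- k_f / (M * g * L_bio)
  zeta_L <- if (k_L > 0) c_L / (2 * sqrt(k_L * M)) else NA_real_
  zeta_s <- if (kappa_s > 0) c_s / sqrt(kappa_s * M * L_bio^2) else NA_real_
  zeta_f <- if (kappa_f > 0) c_f / sqrt(kappa_f * M * L_bio^2) else NA_real_
  list(kappa_L = kappa_L, L0_tilde = L_0 / L_bio, zeta_L = zeta_L,
       kappa_s = kappa_s, zeta_s = zeta_s, kappa_f = kappa_f, zeta_f = zeta_f)
}

#' Invert the mechanism normalization
#'
#' Exact inverse of [normalize_mechanisms()]; `NA` damping ratios map to zero
#' damping constants.
#'
#' @param kappa_L,L0_tilde,zeta_L,kappa_s,zeta_s,kappa_f,zeta_f normalized
#'   coefficients.
#' @inheritParams normalize_mechanisms
#' @return Named list of raw constants `k_L`, `L_0`, `c_L`, `k_s`, `c_s`,
#'   `k_f`, `c_f`.
#' @export
denormalize_mechanisms <- function(kappa_L, L0_tilde, zeta_L = NA,
                                   kappa_s = 0, zeta_s = NA,
                                   kappa_f = 0, zeta_f = NA, M, g, L_bio) {
  k_L <- kappa_L * M * g / L_bio
  c_L <- if (is.na(zeta_L)) 0 else zeta_L * 2 * sqrt(k_L * M)
  k_s <- kappa_s * M * g * L_bio
  c_s <- if (is.na(zeta_s)) 0 else zeta_s * sqrt(kappa_s * M * L_bio^2)
  k_f <- kappa_f * M * g * L_bio
  c_f <- if (is.na(zeta_f)) 0 else zeta_f * sqrt(kappa_f * M * L_bio^2)
  list(k_L = k_L, L_0 = L0_tilde * L_bio, c_L = c_L,
       k_s = k_s, c_s = c_s, k_f = k_f, c_f = c_f)
}

# convert one leg's 7 library-scale regression coefficients
# (kappa_L, kappa_L*L0_tilde, c_L_tilde, kappa_s, c_s_tilde, kappa_f,
#  c_f_tilde) to the normalized reporting form.  L0_tilde is recovered as the
# ratio of the product term to kappa_L; without a leg spring a resting length
# is meaningless and reported NA.
.lib_to_normalized <- function(xi, M, g, L_bio) {
  kappa_L <- xi[1]
  L0_tilde <- if (kappa_L != 0) xi[2] / kappa_L else NA_real_
  zeta_L <- if (kappa_L > 0) xi[3] / (2 * sqrt(kappa_L)) else NA_real_
  kappa_s <- xi[4]
  zeta_s <- if (kappa_s > 0) {
    c_s <- xi[5] * M * sqrt(g * L_bio^3)
    c_s / sqrt(kappa_s * M * L_bio^2)
  } else NA_real_
  kappa_f <- xi[6]
  zeta_f <- if (kappa_f > 0) {
    c_f <- xi[7] * M * sqrt(g * L_bio^3)
    c_f / sqrt(kappa_f * M * L_bio^2)
  } else NA_real_
  c(kappa_L = unname(kappa_L), L0_tilde = unname(L0_tilde),
    zeta_L = unname(zeta_L), kappa_s = unname(kappa_s),
    zeta_s = unname(zeta_s), kappa_f = unname(kappa_f),
    zeta_f = unname(zeta_f))
}

#' Bootstrap coefficient estimates for a fixed signature structure
#'
#' Quantifies the robustness of template-signature coefficients to
#' stride-to-stride variability and noise: each iteration draws samples with
#' replacement from the gait phase's training pool, refits the coefficients
#' on the fixed support by least squares, and converts them to normalized
#' form.  The final coefficient is the bootstrap mean; reliability is
#' summarized by the coefficient of variation CV = sd / |mean|.
#'
#' Rank-deficient resamples are redrawn (with a logged count); more than 10%
#' redraws is an error.
#'
#' @param lib a [build_library()] object.
#' @param sample_idx training-sample indices of the gait phase pool.
#' @param support logical 14-vector: the fixed signature structure.
#' @param n_boot bootstrap iterations (default 200).
#' @param resample_size samples drawn per iteration with replacement;
#'   `NULL` uses the pool size (the conventional bootstrap).
#' @param seed integer seed; required for reproducibility.
#' @return Object of class `bootstrap_result`: list with `draws` (n_boot x 14
#'   library-scale coefficients), `normalized` (n_boot x 14 per-leg normalized
#'   draws), `mean`, `sd`, `cv` (named per leg/coefficient), `n_redraws`,
#'   `seed`.
#' @export
bootstrap_signature <- function(lib, sample_idx, support, n_boot = 200,
                                resample_size = 3600, seed) {
  if (missing(seed)) stop("a seed is required for bootstrap_signature()")
  stopifnot(length(support) == ncol(lib$theta))
  pool <- sample_idx
  if (is.null(resample_size)) resample_size <- length(pool)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  draws <- matrix(0, n_boot, ncol(lib$theta))
  n_redraws <- 0
  b <- 1
  while (b <= n_boot) {
    take <- sample(pool, resample_size, replace = TRUE)
    rows <- .lib_rows(lib, take)
    fit <- tryCatch(
      .ols_support(lib$theta[rows, , drop = FALSE], lib$target[rows], support),
      templatesig_rank_deficient = function(e) NULL)
    if (is.null(fit)) {
      n_redraws <- n_redraws + 1
      if (n_redraws > 0.1 * n_boot)
        stop("more than 10% of bootstrap resamples were rank-deficient")
      next
    }
    draws[b, ] <- fit
    b <- b + 1
  }
  colnames(draws) <- colnames(lib$theta)

  norm_draws <- t(apply(draws, 1, function(xi) {
    c(.lib_to_normalized(xi[1:7], lib$M, lib$g, lib$L_bio),
      .lib_to_normalized(xi[8:14], lib$M, lib$g, lib$L_bio))
  }))
  colnames(norm_draws) <- c(paste0("R.", .COEF_NAMES), paste0("L.", .COEF_NAMES))
  mu <- colMeans(norm_draws)
  sdv <- apply(norm_draws, 2, stats::sd)
  cv <- ifelse(abs(mu) > 0, sdv / abs(mu), NA_real_)
  structure(list(draws = draws, normalized = norm_draws,
                 mean = mu, sd = sdv, cv = cv,
                 n_boot = n_boot, resample_size = resample_size,
                 n_redraws = n_redraws, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Bootstrap result: %d draws of %d samples (%d redraws)\n",
              x$n_boot, x$resample_size, x$n_redraws))
  sel <- !is.na(x$cv) & abs(x$mean) > 1e-10
  if (any(sel)) {
    df <- data.frame(mean = x$mean[sel], sd = x$sd[sel], cv = x$cv[sel])
    print(round(df, 4))
  }
  invisible(x)
}

#' Refit a fixed signature structure on another condition's data
#'
#' Holds a template-signature structure (the support) fixed and re-estimates
#' its coefficients by least squares on a different condition's training
#' data, then scores the refit on that condition's held-out data with AICc --
#' the cross-condition comparison used to ask whether a baseline structure
#' remains plausible under a new walking condition.
#'
#' @param support logical 14-vector defining the structure.
#' @param lib a [build_library()] for the new condition.
#' @param train_idx,test_idx sample indices (within the library's retained
#'   samples) used for fitting and for AICc scoring.
#' @return List with `coefficients` (library scale), `normalized`, `k`,
#'   `rho`, `rss`, `aic`, `aicc`.
#' @export
constrained_refit <- function(support, lib, train_idx, test_idx) {
  xi <- .ols_support(lib$theta[.lib_rows(lib, train_idx), , drop = FALSE],
                     lib$target[.lib_rows(lib, train_idx)], support)
  rows_te <- .lib_rows(lib, test_idx)
  res <- lib$theta[rows_te, , drop = FALSE] %*% xi - lib$target[rows_te]
  rss <- sum(res^2)
  k <- sum(support)
  rho <- length(test_idx)
  sc <- aicc_score(k, rho, rss)
  list(coefficients = xi,
       normalized = c(.lib_to_normalized(xi[1:7], lib$M, lib$g, lib$L_bio),
                      .lib_to_normalized(xi[8:14], lib$M, lib$g, lib$L_bio)),
       k = k, rho = rho, rss = rss, aic = sc["aic"], aicc = sc["aicc"])
}
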