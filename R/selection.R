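# Held-out evaluation, AICc scoring, plausibility filtering and Akaike-weight
# multi-model averaging: one template signature per gait phase.

#' AIC and small-sample-corrected AICc from residuals
#'
#' Under i.i.d. normal residuals, `AIC = 2k + rho * ln(rss / rho)` where `k`
#' is the number of free parameters, `rho` the number of evaluation samples
#' and `rss` the residual sum of squares pooled over the three output
#' directions.  The finite-sample correction is
#' `AICc = AIC + 2(k+1)(k+2)/(rho - k - 2)`, which vanishes as `rho` grows.
#'
#' @param k free parameters (support size).
#' @param rho evaluation samples.
#' @param rss residual sum of squares (> 0).
#' @return Named vector `c(aic = , aicc = )`.
#' @export
#' @examples
#' aicc_score(k = 3, rho = 100, rss = 100)  # aic 6, aicc 6.4211
aicc_score <- function(k, rho, rss) {
  if (rho <= k + 2) stop("AICc undefined: rho must exceed k + 2")
  if (rss <= 0) stop("rss must be positive")
  aic <- 2 * k + rho * log(rss / rho)
  c(aic = aic, aicc = aic + 2 * (k + 1) * (k + 2) / (rho - k - 2))
}

#' Relative AICc and plausibility
#'
#' `delta_aicc = AICc - min(AICc)`; signatures with `delta_aicc <= threshold`
#' (default 3) are deemed plausible.
#'
#' @param aicc numeric vector of AICc scores.
#' @param threshold plausibility cutoff.
#' @return Data frame with `aicc`, `delta_aicc`, `plausible`.
#' @export
rank_and_filter <- function(aicc, threshold = 3) {
  stopifnot(length(aicc) >= 1)
  delta <- aicc - min(aicc)
  data.frame(aicc = aicc, delta_aicc = delta,
             plausible = delta <= threshold)
}

#' Akaike weights
#'
#' Normalized relative likelihoods `w_j = exp(-delta_j / 2) / sum_r
#' exp(-delta_r / 2)` over the models being averaged.
#'
#' @param delta_aicc relative AICc scores.
#' @return Weights summing to 1.
#' @export
#' @examples
#' akaike_weights(c(0, 2))  # 0.7311, 0.2689
akaike_weights <- function(delta_aicc) {
  stopifnot(length(delta_aicc) >= 1)
  w <- exp(-delta_aicc / 2)
  w / sum(w)
}

#' Weighted-average signature over the plausible set
#'
#' Coefficient-wise weighted mean of the plausible models, with terms absent
#' from a model contributing zero.  The averaged support is the union
#' support; each term's effective weight (the summed weight of the models
#' containing it) is recorded.
#'
#' @param coef_matrix models x coefficients matrix (zeros off-support).
#' @param weights Akaike weights of exactly these models.
#' @return List with `coefficients`, `support` (union), `term_weight`.
#' @export
multimodel_average <- function(coef_matrix, weights) {
  coef_matrix <- rbind(coef_matrix)
  stopifnot(nrow(coef_matrix) == length(weights))
  avg <- drop(weights %*% coef_matrix)
  support <- colSums(coef_matrix != 0) > 0
  tw <- drop(weights %*% (coef_matrix != 0))
  list(coefficients = avg, support = support, term_weight = tw)
}

#' Reconstruction error over the gait cycle
#'
#' Mean absolute reconstruction error of a signature on held-out samples,
#' binned by the continuous phase `psi` (default 100 bins of 1% stride),
#' per direction and pooled.  Empty bins are reported as `NA`, not zero.
#'
#' @param coefficients library-scale 14-vector.
#' @param lib a [build_library()] over (at least) the evaluation samples.
#' @param sample_idx evaluation sample indices.
#' @param psi phase of every trial sample (percent).
#' @param n_bins phase bins.
#' @return Data frame with `bin` (left edge, percent), `x`, `y`, `z`,
#'   `pooled` mean absolute errors.
#' @export
heldout_error_curve <- function(coefficients, lib, sample_idx, psi,
                                n_bins = 100) {
  rows <- .lib_rows(lib, sample_idx)
  res <- abs(lib$theta[rows, , drop = FALSE] %*% coefficients -
               lib$target[rows])
  res <- matrix(res, ncol = 3, byrow = TRUE)  # per sample: x, y, z
  bin <- floor(psi[sample_idx] / (100 / n_bins))
  bin <- pmin(bin, n_bins - 1L)
  agg <- function(v) {
    out <- rep(NA_real_, n_bins)
    s <- tapply(v, bin, mean)
    out[as.integer(names(s)) + 1L] <- s
    out
  }
  data.frame(bin = (0:(n_bins - 1)) * (100 / n_bins),
             x = agg(res[, 1]), y = agg(res[, 2]), z = agg(res[, 3]),
             pooled = agg(rowMeans(res)))
}

# score every candidate within one gait phase and average the plausible set.
# `score` chooses the residual convention: "refit" evaluates the phase-refit
# coefficients on the held-out samples; "cluster" scores a structure by the
# best held-out RSS among the coefficient vectors fitted in its source
# clusters.  The coefficients carried into multi-model averaging are always
# the per-phase refits.
.select_phase <- function(candidates, lib, train_idx, test_idx,
                          aicc_threshold = 3, score = "refit") {
  rho <- length(test_idx)
  rows_tr <- .lib_rows(lib, train_idx)
  rows_te <- .lib_rows(lib, test_idx)
  A_tr <- lib$theta[rows_tr, , drop = FALSE]; b_tr <- lib$target[rows_tr]
  A_te <- lib$theta[rows_te, , drop = FALSE]; b_te <- lib$target[rows_te]

  keep <- vapply(candidates, function(cd) sum(cd$support) < rho - 2, TRUE)
  candidates <- candidates[keep]
  if (!length(candidates))
    stop("no scorable candidates in this gait phase")

  coefs <- matrix(0, length(candidates), ncol(lib$theta),
                  dimnames = list(NULL, colnames(lib$theta)))
  k <- integer(length(candidates)); rss <- numeric(length(candidates))
  aic <- numeric(length(candidates)); aicc <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    xi <- withCallingHandlers(
      .ols_support(A_tr, b_tr, cd$support, strict = FALSE),
      templatesig_rank_deficient = function(w) invokeRestart("muffleWarning"))
    coefs[i, ] <- xi
    k[i] <- sum(cd$support)
    rss[i] <- if (score == "cluster" && length(cd$cluster_coefs)) {
      # median over source clusters: robust to lucky draws among the many
      # noisy evaluations of a frequent structure
      stats::median(vapply(cd$cluster_coefs,
                           function(cc) sum((A_te %*% cc - b_te)^2), 0))
    } else sum((A_te %*% xi - b_te)^2)
    sc <- aicc_score(k[i], rho, rss[i])
    aic[i] <- sc["aic"]; aicc[i] <- sc["aicc"]
  }
  rk <- rank_and_filter(aicc, aicc_threshold)
  w <- rep(0, length(candidates))
  w[rk$plausible] <- akaike_weights(rk$delta_aicc[rk$plausible])
  avg <- multimodel_average(coefs[rk$plausible, , drop = FALSE],
                            w[rk$plausible])
  table <- data.frame(
    support = vapply(candidates, function(cd)
      paste(colnames(lib$theta)[cd$support], collapse = "+"), ""),
    frequency = vapply(candidates, function(cd) cd$frequency, 0),
    k = k, rho = rho, rss = rss, aic = aic, aicc = aicc,
    delta_aicc = rk$delta_aicc, plausible = rk$plausible, weight = w,
    stringsAsFactors = FALSE)
  list(table = table[order(table$delta_aicc), ],
       coefficients = avg$coefficients,
       support = avg$support, term_weight = avg$term_weight,
       refit_coefs = coefs, rho = rho)
}
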