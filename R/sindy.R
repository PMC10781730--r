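# Sparse regression core: sequential thresholded least squares (STLSQ),
# the sparsity sweep, phase-based nearest-neighbor clustering, and the
# candidate-signature pool.

# minimum-norm least squares via SVD; used wherever the active set may be
# rank deficient (e.g. a mediolateral direction with no lateral motion)
.lstsq_minnorm <- function(A, b, tol = 1e-10) {
  sv <- svd(A)
  keep <- sv$d > tol * sv$d[1]
  if (!all(keep)) {
    warning(warningCondition("rank-deficient least-squares system",
                             class = "templatesig_rank_deficient"))
  }
  d_inv <- ifelse(keep, 1 / sv$d, 0)
  drop(sv$v %*% (d_inv * crossprod(sv$u, b)))
}

# OLS restricted to a support, full-length coefficient vector returned;
# signals a templatesig_rank_deficient error condition when strict = TRUE
.ols_support <- function(theta, target, support, strict = TRUE) {
  p <- ncol(theta)
  xi <- numeric(p)
  act <- which(support)
  if (!length(act)) return(stats::setNames(xi, colnames(theta)))
  A <- theta[, act, drop = FALSE]
  qrA <- qr(A)
  if (qrA$rank < length(act)) {
    if (strict)
      stop(errorCondition("rank-deficient support",
                          class = "templatesig_rank_deficient"))
    xi[act] <- .lstsq_minnorm(A, target)
  } else {
    xi[act] <- qr.coef(qrA, target)
  }
  stats::setNames(xi, colnames(theta))
}

#' Sequential thresholded least squares
#'
#' The sparsifying regression at the heart of the pipeline: iterate
#' \{least-squares fit on the active set; zero every coefficient with
#' magnitude below `lambda`; repeat\} until the active set is stable.
#' `lambda = 0` returns ordinary least squares; a `lambda` above the largest
#' OLS coefficient magnitude returns the all-zero model.
#'
#' Rank-deficient active sets are solved by the smallest-norm solution with
#' a warning.
#'
#' @param theta regressor matrix (rows >= columns on the active set).
#' @param target response vector.
#' @param lambda hard threshold (>= 0) on coefficient magnitude.
#' @param max_iter iteration cap (the active set shrinks monotonically, so
#'   convergence needs at most `ncol(theta)` passes).
#' @return Full-length coefficient vector; zeros off the final support.
#' @export
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(300), 100, 3)
#' y <- 2 * X[, 1]
#' stlsq(X, y, lambda = 0.5)
stlsq <- function(theta, target, lambda, max_iter = ncol(theta) + 1L) {
  stopifnot(lambda >= 0)
  p <- ncol(theta)
  active <- rep(TRUE, p)
  xi <- numeric(p)
  for (it in seq_len(max_iter)) {
    if (!any(active)) break
    xi <- withCallingHandlers(
      .ols_support(theta, target, active, strict = FALSE),
      templatesig_rank_deficient = function(w) invokeRestart("muffleWarning"))
    new_active <- abs(xi) >= lambda & active
    xi[!new_active] <- 0
    if (identical(new_active, active)) break
    active <- new_active
  }
  stats::setNames(xi, colnames(theta))
}

# STLSQ via a precomputed Gram system (G = t(X) X, c = t(X) y): the sweep
# refits the same cluster thousands of times, so normal equations pay off.
# A small relative ridge keeps near-collinear active sets (the library's
# columns are all parallel to the leg vector pointwise) from producing huge
# mutually-cancelling coefficients that would distort the threshold grid.
.stlsq_gram <- function(G, cvec, lambda, ridge = 0.01) {
  p <- ncol(G)
  eps <- ridge * mean(diag(G))
  active <- rep(TRUE, p)
  xi <- numeric(p)
  for (it in seq_len(p + 1L)) {
    if (!any(active)) break
    a <- which(active)
    Ga <- G[a, a, drop = FALSE] + diag(eps, length(a))
    sol <- tryCatch(solve(Ga, cvec[a]), error = function(e) NULL)
    if (is.null(sol)) {
      sv <- svd(Ga)
      keep <- sv$d > 1e-12 * sv$d[1]
      sol <- drop(sv$v %*% (ifelse(keep, 1 / sv$d, 0) *
                              crossprod(sv$u, cvec[a])))
    }
    xi[] <- 0; xi[a] <- sol
    new_active <- abs(xi) >= lambda & active
    xi[!new_active] <- 0
    if (identical(new_active, active)) break
    active <- new_active
  }
  xi
}

#' Sweep the sparsity threshold over one cluster's system
#'
#' Runs STLSQ at `n_lambda` logarithmically spaced thresholds from
#' `range[1]` to `range[2]` times the largest-magnitude coefficient of the
#' cluster's unthresholded (full-dimensional) fit, and deduplicates the
#' resulting supports.
#'
#' @param theta,target the cluster's regression system.
#' @param n_lambda grid size (default 40).
#' @param range relative threshold range (default 1%-100% of the largest
#'   full-model coefficient).
#' @param ridge relative ridge regularization of the cluster fits (see
#'   Details).
#' @details The cluster systems are strongly collinear (every mechanism
#'   column is the leg vector scaled by a state-dependent factor), so the
#'   unthresholded fits are ridge-stabilized; the threshold grid then spans
#'   physically scaled coefficients rather than collinear cancellation
#'   artifacts.
#' @return List with `supports` (list of logical vectors), `lambdas` (list
#'   of the thresholds that produced each support), `c_max`.
#' @export
sweep_sparsity <- function(theta, target, n_lambda = 40,
                           range = c(0.01, 1), ridge = 0.01) {
  G <- crossprod(theta)
  cvec <- crossprod(theta, target)
  xi_full <- .stlsq_gram(G, cvec, 0, ridge)
  c_max <- max(abs(xi_full))
  if (c_max == 0)
    return(list(supports = list(rep(FALSE, ncol(theta))),
                lambdas = list(0), coefs = list(xi_full), c_max = 0))
  grid <- exp(seq(log(range[1] * c_max), log(range[2] * c_max),
                  length.out = n_lambda))
  supports <- list(); lambdas <- list(); coefs <- list()
  for (lam in grid) {
    xi <- .stlsq_gram(G, cvec, lam, ridge)
    key <- paste(which(xi != 0), collapse = ",")
    pos <- match(key, vapply(supports, function(s)
      paste(which(s), collapse = ","), ""))
    if (is.na(pos)) {
      supports[[length(supports) + 1]] <- xi != 0
      lambdas[[length(lambdas) + 1]] <- lam
      coefs[[length(coefs) + 1]] <- xi
    } else {
      lambdas[[pos]] <- c(lambdas[[pos]], lam)
    }
  }
  list(supports = supports, lambdas = lambdas, coefs = coefs, c_max = c_max)
}

#' Split a trial's samples into a clustering pool and a held-out set
#'
#' The last `n_test` samples are withheld for model evaluation and
#' selection; the remainder forms the clustering (training) pool.
#'
#' @param states a `template_states` object, an integer sample count, or an
#'   integer vector of usable sample indices (e.g. [state_sample_mask()]).
#' @param n_test held-out samples (default 3600, i.e. 30 s at 120 Hz).
#' @param min_train minimum training-pool size accepted.
#' @return List with integer vectors `train` and `test` (trial sample
#'   indices).
#' @export
split_train_test <- function(states, n_test = 3600, min_train = n_test) {
  idx <- if (inherits(states, "template_states")) seq_len(states$n)
         else if (length(states) == 1L) seq_len(states)
         else as.integer(states)
  m <- length(idx)
  if (m < n_test + min_train)
    stop(sprintf("trial too short: %d usable samples, need at least %d",
                 m, n_test + min_train))
  list(train = idx[seq_len(m - n_test)], test = idx[(m - n_test + 1L):m])
}

#' Cluster training samples by continuous gait phase
#'
#' For each of the first `n_centroids` training samples (the seeds), collects
#' its `k` nearest neighbors in the training pool under the circular phase
#' distance `min(|dpsi|, 100 - |dpsi|)`.  Distance ties break by sample
#' index, so clustering is fully deterministic.  Each cluster's centroid
#' phase is the circular mean of its members' phases, and its gait-phase
#' label is the members' majority label.
#'
#' @param psi phase of every training-pool sample (percent).
#' @param gait_phase factor of gait-phase labels for the pool.
#' @param pool integer indices of the pool samples (into the trial).
#' @param n_centroids number of cluster seeds (first samples of the pool).
#' @param k neighbors per cluster.
#' @return Object of class `cluster_set`: list with `members` (list of
#'   integer vectors of trial sample indices, sorted by distance),
#'   `centroid_psi`, `centroid_phase`, `seeds`, `k`, `coverage` (percent of
#'   the pool spanned by one cluster).
#' @export
cluster_by_phase <- function(psi, gait_phase, pool, n_centroids, k) {
  n <- length(pool)
  if (k > n) stop("k exceeds the clustering pool size")
  if (n_centroids > n) stop("more centroids than pool samples")
  psi_pool <- psi[pool]
  members <- vector("list", n_centroids)
  centroid_psi <- numeric(n_centroids)
  centroid_phase <- character(n_centroids)
  chunk <- max(1L, floor(2e6 / n))
  for (start in seq(1L, n_centroids, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_centroids)
    d <- abs(outer(psi_pool[idx], psi_pool, "-"))
    d <- pmin(d, 100 - d)
    for (ii in seq_along(idx)) {
      ord <- order(d[ii, ], seq_len(n))[seq_len(k)]
      mem <- pool[ord]
      members[[idx[ii]]] <- mem
      a <- psi_pool[ord] / 100 * 2 * pi
      centroid_psi[idx[ii]] <-
        (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi) * 100) %% 100
      tab <- table(gait_phase[mem])
      centroid_phase[idx[ii]] <- names(tab)[which.max(tab)]
    }
  }
  structure(list(members = members, centroid_psi = centroid_psi,
                 centroid_phase = factor(centroid_phase,
                                         levels = levels(gait_phase)),
                 seeds = pool[seq_len(n_centroids)], k = k,
                 coverage = cluster_coverage(k, n)),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("Cluster set: %d clusters of %d neighbors (%.1f%% pool coverage)\n",
              length(x$members), x$k, x$coverage))
  print(table(x$centroid_phase))
  invisible(x)
}

#' Fraction of the training pool spanned by one cluster
#'
#' @param k cluster size; @param pool_size training-pool size.
#' @return Coverage in percent.
#' @export
#' @examples
#' cluster_coverage(800, 10800)  # 7.4
cluster_coverage <- function(k, pool_size) 100 * k / pool_size

#' Collect candidate signatures across clusters
#'
#' Pools the supports found by [sweep_sparsity()] over all clusters, keyed by
#' support set, and discards supports identified in less than `min_freq` of
#' the clusters (strictly less than: a support at exactly the threshold is
#' retained).  Each surviving support is assigned the gait phase(s) of the
#' centroids of the clusters in which it appeared.
#'
#' @param sweeps list (one per cluster) of [sweep_sparsity()] results.
#' @param clusters the [cluster_by_phase()] object.
#' @param min_freq frequency threshold (default 0.01).
#' @return List of candidate signatures: each has `support`, `frequency`,
#'   `source` (cluster ids), `phases` (factor levels observed at the source
#'   centroids), `lambda_values`.
#' @export
collect_candidates <- function(sweeps, clusters, min_freq = 0.01) {
  n_clusters <- length(sweeps)
  pool <- new.env(parent = emptyenv())
  for (ci in seq_len(n_clusters)) {
    sw <- sweeps[[ci]]
    seen <- character(0)
    for (si in seq_along(sw$supports)) {
      s <- sw$supports[[si]]
      if (!any(s)) next          # the empty model is never pooled
      key <- paste(which(s), collapse = ",")
      if (key %in% seen) next   # count each support once per cluster
      seen <- c(seen, key)
      rec <- if (!is.null(pool[[key]])) pool[[key]] else
        list(support = s, source = integer(0), lambda_values = numeric(0),
             cluster_coefs = list())
      rec$source <- c(rec$source, ci)
      rec$lambda_values <- c(rec$lambda_values, sw$lambdas[[si]])
      rec$cluster_coefs[[length(rec$cluster_coefs) + 1]] <- sw$coefs[[si]]
      pool[[key]] <- rec
    }
  }
  keys <- ls(pool)
  out <- list()
  for (key in keys) {
    rec <- pool[[key]]
    freq <- length(rec$source) / n_clusters
    if (freq < min_freq) next
    if (!any(rec$support)) next  # the empty model is never a candidate
    rec$frequency <- freq
    rec$phases <- unique(clusters$centroid_phase[rec$source])
    out[[length(out) + 1]] <- rec
  }
  if (!length(out)) stop("no frequent signatures survived the filter")
  out[order(vapply(out, function(r) -r$frequency, 0))]
}
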