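# Sparse regression core: STLSQ against an independent reference, the
# sparsity sweep, the train/test split, phase clustering and the candidate
# pool.

test_that("STLSQ limits: OLS at lambda 0, empty model above max coefficient", {
  set.seed(11)
  X <- matrix(rnorm(300), 100, 3)
  y <- drop(X %*% c(2, -1, 0.5)) + rnorm(100, 0, 0.01)
  expect_equal(unname(stlsq(X, y, 0)), unname(qr.solve(X, y)), tolerance = 1e-10)
  xi_ols <- qr.solve(X, y)
  expect_equal(unname(stlsq(X, y, max(abs(xi_ols)) * 1.01)), c(0, 0, 0))
})

test_that("STLSQ recovers an exactly sparse model", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  y <- 2 * X[, 1]
  expect_equal(unname(stlsq(X, y, 0.5)), c(2, 0, 0), tolerance = 1e-12)
})

test_that("STLSQ matches the independent reference on random systems", {
  set.seed(99)
  for (rep in 1:200) {
    p <- sample(4:6, 1)
    n <- 50
    X <- matrix(rnorm(n * p), n, p)
    beta <- ifelse(runif(p) < 0.5, 0, rnorm(p, 0, 2))
    y <- drop(X %*% beta) + rnorm(n, 0, 0.1)
    lambda <- runif(1, 0.05, 1.5)
    a <- unname(stlsq(X, y, lambda))
    b <- stlsq_reference(X, y, lambda)
    expect_equal(a, b, tolerance = 1e-8)
    # the returned support is a fixed point of the thresholding iteration
    act <- a != 0
    if (any(act)) {
      refit <- qr.solve(X[, act, drop = FALSE], y)
      expect_true(all(abs(refit) >= lambda))
    }
  }
})

test_that("the sparsity sweep spans 1-100% of the largest coefficient", {
  set.seed(5)
  X <- matrix(rnorm(600), 200, 3)
  y <- drop(X %*% c(3, 1, 0)) + rnorm(200, 0, 0.05)
  sw <- sweep_sparsity(X, y, n_lambda = 40, ridge = 1e-9)
  lam <- sort(unlist(sw$lambdas))
  expect_equal(min(lam), 0.01 * sw$c_max, tolerance = 1e-9)
  expect_equal(max(lam), sw$c_max, tolerance = 1e-9)
  # consecutive grid ratios are constant (log spacing)
  ratios <- diff(log(lam))
  expect_lt(max(ratios) - min(ratios), 1e-8)
  # at the top threshold at most one term survives
  top <- sw$supports[[length(sw$supports)]]
  expect_lte(sum(top), 1)
})

test_that("the true structure appears in stance-cluster sweeps", {
  res <- fix_result40()
  has_true <- vapply(res$candidates, function(cd)
    all(which(cd$support)[1:2] == c(1, 2)) && cd$support[1] && cd$support[2],
    TRUE)
  truth_present <- vapply(res$candidates, function(cd)
    identical(which(cd$support), c(1L, 2L)) ||
      identical(which(cd$support), c(8L, 9L)), TRUE)
  expect_true(any(truth_present))
})

test_that("the split reserves the last samples for evaluation", {
  sp <- split_train_test(14400)
  expect_length(sp$train, 10800)
  expect_length(sp$test, 3600)
  expect_equal(max(sp$train) + 1L, min(sp$test))
  expect_equal(cluster_coverage(800, length(sp$train)), 7.4, tolerance = 0.01)
  expect_error(split_train_test(7199), "too short")
})

test_that("phase clustering selects circular nearest neighbors", {
  # brute-force oracle on a small instance
  set.seed(21)
  n <- 200
  psi <- runif(n, 0, 100)
  gp <- factor(ifelse(psi < 50, "SS_R", "SS_L"),
               levels = c("DS1", "SS_R", "DS2", "SS_L"))
  cl <- cluster_by_phase(psi, gp, seq_len(n), n_centroids = 30, k = 20)
  for (i in 1:30) {
    d <- abs(psi - psi[i]); d <- pmin(d, 100 - d)
    oracle <- order(d, seq_len(n))[1:20]
    expect_setequal(cl$members[[i]], oracle)
    # members occupy a contiguous arc of the circular ordering
    ord <- order(psi)
    pos <- sort(match(cl$members[[i]], ord))
    gaps <- diff(c(pos, pos[1] + n))
    expect_equal(sum(gaps > 1), if (max(gaps) > 1) 1 else 0)
  }
})

test_that("clustering wraps around the stride boundary", {
  psi <- c(99.5, 0.2, 99.9, 0.4, 50, 51, 52, 53)
  gp <- factor(rep("SS_R", 8), levels = c("DS1", "SS_R", "DS2", "SS_L"))
  cl <- cluster_by_phase(psi, gp, 1:8, n_centroids = 1, k = 4)
  expect_setequal(cl$members[[1]], 1:4)
})

test_that("degenerate phase yields a valid circular mean", {
  psi <- rep(25, 10)
  gp <- factor(rep("SS_R", 10), levels = c("DS1", "SS_R", "DS2", "SS_L"))
  cl <- cluster_by_phase(psi, gp, 1:10, n_centroids = 2, k = 5)
  expect_equal(cl$centroid_psi[1], 25, tolerance = 1e-9)
})

test_that("candidate frequency filtering keeps the 1% boundary", {
  mk_sweep <- function(support) list(supports = list(support),
                                     lambdas = list(1),
                                     coefs = list(as.numeric(support)))
  common <- c(rep(TRUE, 2), rep(FALSE, 12))
  rare <- c(rep(FALSE, 12), rep(TRUE, 2))
  n_cl <- 3600
  sweeps <- c(replicate(36, mk_sweep(rare), simplify = FALSE),
              replicate(n_cl - 36, mk_sweep(common), simplify = FALSE))
  clusters <- list(centroid_phase = factor(rep("SS_R", n_cl),
                                           levels = c("DS1", "SS_R", "DS2", "SS_L")))
  out <- collect_candidates(sweeps, clusters, min_freq = 0.01)
  expect_length(out, 2)  # 36/3600 = exactly 1%: retained
  sweeps35 <- c(replicate(35, mk_sweep(rare), simplify = FALSE),
                replicate(n_cl - 35, mk_sweep(common), simplify = FALSE))
  out35 <- collect_candidates(sweeps35, clusters, min_freq = 0.01)
  expect_length(out35, 1)  # 35/3600 < 1%: discarded
  expect_gte(sum(vapply(out, function(cd) cd$frequency, 0)), 1)
})
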