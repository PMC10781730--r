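# AICc scoring, plausibility filtering, Akaike weights, model averaging and
# held-out error curves.

test_that("AIC and AICc match hand-computed values", {
  sc <- aicc_score(k = 3, rho = 100, rss = 100)
  expect_equal(unname(sc["aic"]), 6)  # 2*3 + 100*ln(1)
  expect_equal(unname(sc["aicc"]), 6 + 2 * 4 * 5 / 95, tolerance = 1e-12)
  expect_equal(round(unname(sc["aicc"]), 4), 6.4211)
  expect_error(aicc_score(10, 12, 1), "rho")
  expect_error(aicc_score(1, 100, 0), "rss")
})

test_that("the finite-sample correction vanishes with sample size", {
  corr <- function(rho) {
    sc <- aicc_score(3, rho, rho)  # rss/rho = 1 keeps the aic flat at 2k
    unname(sc["aicc"] - sc["aic"])
  }
  expect_gt(corr(20), corr(200))
  expect_lt(corr(1e6), 1e-4)
})

test_that("halving the residual lowers AIC by rho ln 2", {
  a1 <- aicc_score(4, 500, 10)["aic"]
  a2 <- aicc_score(4, 500, 5)["aic"]
  expect_equal(unname(a1 - a2), 500 * log(2), tolerance = 1e-10)
})

test_that("relative AICc and the plausibility threshold behave as defined", {
  rk <- rank_and_filter(c(100, 102.9, 107.1))
  expect_equal(rk$delta_aicc, c(0, 2.9, 7.1))
  expect_equal(rk$plausible, c(TRUE, TRUE, FALSE))
  expect_equal(rank_and_filter(42)$delta_aicc, 0)
  expect_true(rank_and_filter(42)$plausible)
  # shift invariance
  expect_equal(rank_and_filter(c(100, 102.9, 107.1) + 55)$delta_aicc,
               rk$delta_aicc)
})

test_that("Akaike weights are normalized relative likelihoods", {
  expect_equal(akaike_weights(c(0, 0)), c(0.5, 0.5))
  w <- akaike_weights(c(0, 2))
  expect_equal(w, c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(w, 4), c(0.7311, 0.2689))
  set.seed(8)
  expect_equal(sum(akaike_weights(runif(7, 0, 20))), 1)
})

test_that("multi-model averaging zero-pads absent terms", {
  cm <- rbind(c(1, 4, 0), c(3, 0, 0))
  one <- multimodel_average(cm[1, , drop = FALSE], 1)
  expect_equal(one$coefficients, c(1, 4, 0))
  eq <- multimodel_average(cm, c(0.5, 0.5))
  expect_equal(eq$coefficients[1], 2)          # shared term: mean
  expect_equal(eq$coefficients[2], 2)          # absent term contributes zero
  expect_equal(eq$support, c(TRUE, TRUE, FALSE))
  qtr <- multimodel_average(rbind(c(0, 4, 0), c(1, 0, 0)), c(0.25, 0.75))
  expect_equal(qtr$coefficients[2], 1)         # 0.25 * 4
  expect_equal(qtr$term_weight[2], 0.25)
})

test_that("held-out error is near zero for the exact model and flat for none", {
  st <- fix_states40()
  lib <- fix_lib40()
  mask <- fix_mask40()
  p <- fix_trial40()$params
  idx <- mask[st$gait_phase[mask] == "SS_R"]
  xi <- true_coefficients_phase(p, "R")
  curve <- heldout_error_curve(xi, lib, idx, st$psi, n_bins = 50)
  expect_lt(max(curve$pooled, na.rm = TRUE), 1e-3)
  # null model: binned error equals the binned mean |target|
  curve0 <- heldout_error_curve(numeric(14), lib, idx, st$psi, n_bins = 50)
  rows <- lib_rows(lib, idx)
  expect_equal(mean(curve0$pooled, na.rm = TRUE),
               mean(tapply(abs(lib$target[rows]),
                           pmin(floor(st$psi[rep(idx, each = 3)] / 2), 49),
                           mean)),
               tolerance = 1e-6)
  # empty bins are missing, not zero
  expect_true(anyNA(curve$pooled))
})

test_that("a stance signature fits its own phase better than the rest", {
  st <- fix_states40()
  lib <- fix_lib40()
  mask <- fix_mask40()
  p <- fix_trial40()$params
  xi <- true_coefficients_phase(p, "R")  # right-stance-only model
  own <- mask[st$gait_phase[mask] == "SS_R"]
  other <- mask[st$gait_phase[mask] == "DS1"]
  e_own <- mean(abs(lib$theta[lib_rows(lib, own), ] %*% xi -
                      lib$target[lib_rows(lib, own)]))
  e_other <- mean(abs(lib$theta[lib_rows(lib, other), ] %*% xi -
                        lib$target[lib_rows(lib, other)]))
  expect_lt(e_own * 10, e_other)
})
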