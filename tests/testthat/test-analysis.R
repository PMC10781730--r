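# Comparison layer: r^2, structure-plausibility testing, Holm-Sidak
# correction and percent differences.

test_that("r^2 has the standard limits", {
  set.seed(2)
  m <- cbind(rnorm(50), rnorm(50), rnorm(50))
  expect_equal(r_squared(m, m)$average, 1)
  pred_mean <- matrix(rep(colMeans(m), each = 50), 50, 3)
  expect_equal(r_squared(pred_mean, m)$average, 0, tolerance = 1e-12)
  flat <- m; flat[, 2] <- 1
  expect_warning(r_squared(flat, flat), "zero-variance")
})

test_that("one-sample right-tailed plausibility test matches the textbook t", {
  out <- structure_plausibility_test(c(10, 12, 14, 16))
  expect_equal(out$t, (13 - 3) / (stats::sd(c(10, 12, 14, 16)) / 2),
               tolerance = 1e-12)
  expect_equal(round(out$t, 2), 7.75)
  expect_true(out$reject)
  # boundary: all differences exactly at the threshold
  b <- structure_plausibility_test(c(3, 3, 3))
  expect_equal(b$t, 0)
  expect_equal(b$p, 0.5)
  expect_false(b$reject)
  expect_false(structure_plausibility_test(c(-5, -4, -6))$reject)
})

test_that("Holm-Sidak critical levels reproduce the 56-test family values", {
  set.seed(1)
  p <- runif(56)
  hs <- holm_sidak(p, alpha = 0.05)
  expect_equal(signif(min(hs$alpha_sidak), 2), 9.2e-4)        # rank 1
  expect_equal(signif(sort(hs$alpha_sidak)[2], 2), 9.3e-4)    # rank 2
  expect_equal(holm_sidak(0.02)$alpha_sidak, 0.05)            # single test
})

test_that("Holm-Sidak never rejects more than uncorrected testing", {
  set.seed(31)
  for (i in 1:20) {
    p <- runif(15)^2
    hs <- holm_sidak(p, 0.05)
    expect_lte(sum(hs$reject), sum(p <= 0.05))
    # step-down monotonicity: rejections form a prefix of the sorted order
    rej_sorted <- hs$reject[order(hs$p)]
    if (any(!rej_sorted)) expect_false(any(rej_sorted[which(!rej_sorted)[1]:length(p)]))
  }
})

test_that("percent differences use an explicit reference", {
  expect_equal(round(percent_difference(11.0, 10.4)), 6)
  expect_equal(percent_difference(11.0, 10.4), 100 * 0.6 / 10.4)
  expect_equal(percent_difference(5, 5), 0)
  expect_equal(percent_difference(1.5, 1.0), 50)
  expect_warning(out <- percent_difference(1, 0), "zero reference")
  expect_true(is.na(out))
})

test_that("condition comparison pairs legs within subjects and corrects", {
  set.seed(4)
  subj <- rep(1:8, each = 2)
  mk <- function(shift) {
    do.call(rbind, lapply(seq_along(subj), function(i)
      data.frame(subject = subj[i], leg = c("R", "L")[1 + (i - 1) %% 2],
                 gait_phase = "SS_R", role = "single_support",
                 coefficient = c("kappa_L", "L0_tilde"),
                 boot_mean = c(16 + rnorm(1, 0, 0.2) + shift,
                               0.97 + rnorm(1, 0, 0.002)))))
  }
  a <- mk(0); b <- mk(1.5)
  out <- compare_conditions(a, b, family_size = 8)
  expect_equal(attr(out, "family_size"), 8)
  row_k <- out[out$coefficient == "kappa_L", ]
  expect_lt(row_k$mean_diff, 0)
  expect_true(row_k$p < 0.01)
})
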