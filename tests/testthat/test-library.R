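# Mechanism library: column structure, dimensional scaling, completeness on
# ground-truth data, and the normalization round trip.

# hand-built static states: both legs vertical at rest, zero velocities
static_states <- function(m = 5, L = 1, M = 70, g = 9.81) {
  leg <- list(q_rel = matrix(rep(c(0, L, 0), each = m), m, 3),
              L = rep(L, m), Ls = rep(L, m), Lf = rep(L, m),
              theta = rep(0, m), phi = rep(0, m),
              Ldot = rep(0, m), thetadot = rep(0, m), phidot = rep(0, m))
  structure(list(n = m, legs = list(R = leg, L = leg),
                 com_acc = matrix(0, m, 3), M = M, L_bio = L, g = g,
                 spline = NULL),
            class = "template_states")
}

test_that("velocity columns vanish in static stance", {
  lib <- build_library(static_states())
  vel_cols <- grepl("c_L_tilde|c_s_tilde|c_f_tilde", colnames(lib$theta))
  expect_true(all(lib$theta[, vel_cols] == 0))
  # and the angle columns vanish for a vertical leg
  expect_true(all(lib$theta[, grepl("kappa_s|kappa_f", colnames(lib$theta))] == 0))
})

test_that("degenerate planar projections are reported by sample", {
  st <- static_states()
  st$legs$R$Ls <- rep(1e-9, st$n)
  expect_error(build_library(st), "degenerate planar leg projection")
})

test_that("the library reproduces ground-truth dynamics (completeness)", {
  st <- fix_states40()
  lib <- fix_lib40()
  mask <- fix_mask40()
  p <- fix_trial40()$params
  for (g in c("SS_R", "SS_L", "DS1", "DS2")) {
    legs <- switch(g, SS_R = "R", SS_L = "L", c("R", "L"))
    idx <- mask[st$gait_phase[mask] == g]
    rows <- lib_rows(lib, idx)
    xi <- true_coefficients_phase(p, legs)
    res <- lib$theta[rows, ] %*% xi - lib$target[rows]
    expect_lt(sqrt(mean(res^2)), 2e-3)
  }
})

test_that("stance least squares recovers the dimensionless leg spring", {
  st <- fix_states40()
  lib <- fix_lib40()
  mask <- fix_mask40()
  idx <- mask[st$gait_phase[mask] == "SS_R"]
  rows <- lib_rows(lib, idx)
  fit <- qr.solve(lib$theta[rows, 1:2], lib$target[rows])
  expect_rel_error(fit[1], 16.7, 0.01)            # kappa_L
  expect_rel_error(fit[2] / fit[1], 0.97, 0.01)   # L0_tilde
})

test_that("normalization follows the dimensionless definitions", {
  n <- normalize_mechanisms(k_L = 10000, L_0 = 0.9, c_L = 0, M = 70,
                            g = 9.81, L_bio = 0.9)
  expect_equal(n$kappa_L, 9000 / (70 * 9.81), tolerance = 1e-12)
  expect_equal(round(n$kappa_L, 1), 13.1)
  expect_equal(n$L0_tilde, 1)
  expect_true(is.na(normalize_mechanisms(k_L = 1, L_0 = 1, c_L = 0, k_s = 0,
                                         c_s = 5, M = 70, g = 9.81,
                                         L_bio = 1)$zeta_s))
})

test_that("normalize and denormalize are exact inverses", {
  set.seed(3)
  for (i in 1:20) {
    raw <- list(k_L = runif(1, 1e3, 2e4), L_0 = runif(1, 0.8, 1.1),
                c_L = runif(1, 0, 100), k_s = runif(1, 1, 500),
                c_s = runif(1, 0, 50), k_f = runif(1, 1, 500),
                c_f = runif(1, 0, 50))
    M <- runif(1, 50, 90); g <- 9.81; L_bio <- runif(1, 0.8, 1.05)
    nn <- do.call(normalize_mechanisms, c(raw, list(M = M, g = g, L_bio = L_bio)))
    back <- do.call(denormalize_mechanisms, c(nn, list(M = M, g = g, L_bio = L_bio)))
    expect_equal(back[names(raw)], raw, tolerance = 1e-10)
  }
})

test_that("dimensionless stiffness scales inversely with body mass", {
  p1 <- slip_params(M = 70, k_L = 10000, L_0 = 1)
  p2 <- slip_params(M = 140, k_L = 10000, L_0 = 1)
  expect_equal(true_coefficients(p2)[1], true_coefficients(p1)[1] / 2)
})
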