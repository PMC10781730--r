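# Template-state computation: leg geometry, the continuous phase variable,
# gait-phase labeling, contact fallback.

# a fabricated single-support-on-R "gait" with analytically known geometry:
# the CoM sways sinusoidally over a fixed right foot
sway_trial <- function(m = 1200, dt = 1 / 120, A = 0.1) {
  t <- (seq_len(m) - 1) * dt
  omega <- 2 * pi * 1.0
  com <- cbind(A * sin(omega * t), 1 + 0 * t, 0 * t)
  foot_R <- matrix(0, m, 3)
  foot_L <- cbind(0 * t, 0.05 + 0.04 * cos(omega * t), 0.2 + 0 * t)
  # brief left-foot contacts create contact segments without ever breaking
  # the walking assumption (the right foot stays down throughout)
  cL <- sin(omega * t) < -0.9
  new_trial(t = t, com = com, foot_R = foot_R, foot_L = foot_L,
            contact_R = rep(TRUE, m), contact_L = cL,
            M = 70, L_bio = 1, provenance = "synthetic")
}

test_that("leg lengths and planar angles follow hand trigonometry", {
  st <- compute_states(sway_trial(), reference_leg = "R")
  # at the sway peak the CoM is at (0.1, 1, 0) over the right foot
  i <- which.max(st$legs$R$q_rel[, 1])
  expect_equal(st$legs$R$L[i], sqrt(1.01), tolerance = 1e-4)
  expect_equal(st$legs$R$theta[i], atan2(0.1, 1), tolerance = 1e-3)
  expect_equal(st$legs$R$phi[i], 0, tolerance = 1e-3)
  # vertical leg at the zero crossing
  j <- which.min(abs(st$legs$R$q_rel[, 1]))
  expect_equal(st$legs$R$L[j], 1, tolerance = 1e-4)
  expect_equal(st$legs$R$theta[j], 0, tolerance = 1e-2)
})

test_that("the phase of a harmonic leg angle advances linearly", {
  st <- compute_states(sway_trial(), reference_leg = "R")
  psi <- st$psi
  inc <- diff(psi) %% 100
  inner <- 100:1000
  # 1 Hz oscillation at 120 Hz sampling: 100/120 percent per sample
  expect_lt(max(abs(inc[inner] - 100 / 120)), 0.15)
})

test_that("phase is invariant to cropping by whole strides", {
  st <- fix_states40()
  tr <- fix_trial40()
  hs <- which(diff(c(FALSE, tr$contact_R)) == 1)
  crop <- hs[3]:length(tr$t)  # drop the first two strides
  tr2 <- new_trial(t = tr$t[crop] - tr$t[crop[1]], com = tr$com[crop, ],
                   foot_R = tr$foot_R[crop, ], foot_L = tr$foot_L[crop, ],
                   contact_R = tr$contact_R[crop], contact_L = tr$contact_L[crop],
                   M = tr$M, L_bio = tr$L_bio, provenance = "synthetic")
  st2 <- compute_states(tr2)
  common <- 200:3000
  d <- (st$psi[crop][common] - st2$psi[common]) %% 100
  d <- pmin(d, 100 - d)
  expect_lt(stats::median(d), 1)
})

test_that("phase is anchored at right heel strike", {
  st <- fix_states40()
  hs <- which(diff(c(FALSE, st$contact_R)) == 1)
  d <- st$psi[hs] %% 100
  d <- pmin(d, 100 - d)  # circular distance to 0
  expect_lt(stats::median(d), 1)
  expect_lt(max(d), 3)
})

test_that("a constant leg angle has no defined phase", {
  tr <- sway_trial(A = 0)
  expect_error(compute_states(tr), "phase undefined")
})

test_that("gait phases follow the contact configuration", {
  # alternating pattern R -> RL -> L -> LR
  cR <- c(TRUE, TRUE, FALSE, TRUE)
  cL <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(as.character(label_gait_phases(cR, cL)),
               c("SS_R", "DS2", "SS_L", "DS1"))
  expect_error(label_gait_phases(c(TRUE, FALSE), c(TRUE, FALSE)),
               "neither foot")
})

test_that("kinematic contact fallback reproduces the simulator flags", {
  tr <- fix_trial40()
  cc <- detect_contacts(tr)
  agree <- mean(cc$contact_R == tr$contact_R & cc$contact_L == tr$contact_L)
  expect_gt(agree, 0.98)
})

test_that("angles are odd under spatial reflection, lengths invariant", {
  tr <- fix_trial40()
  mir <- function(m) { m[, 3] <- -m[, 3]; m }
  tr2 <- new_trial(t = tr$t, com = mir(tr$com), foot_R = mir(tr$foot_L),
                   foot_L = mir(tr$foot_R), contact_R = tr$contact_L,
                   contact_L = tr$contact_R, M = tr$M, L_bio = tr$L_bio,
                   provenance = "synthetic")
  st <- fix_states40()
  st2 <- compute_states(tr2, reference_leg = "L")
  expect_equal(st2$legs$L$L, st$legs$R$L, tolerance = 1e-9)
  expect_equal(st2$legs$L$theta, st$legs$R$theta, tolerance = 1e-9)
  expect_equal(st2$legs$L$phi, st$legs$R$phi, tolerance = 1e-9)
})
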