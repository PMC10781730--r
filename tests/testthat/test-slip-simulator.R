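# Augmented bipedal SLIP simulator: point dynamics, hybrid event handling,
# conservation laws and noise injection.

test_that("leg forces reduce to known limits", {
  p0 <- slip_params(M = 70, k_L = 1e-8 + 0, L_0 = 1)  # k_L must be > 0
  p0$legs$R$k_L <- 0; p0$legs$L$k_L <- 0
  a <- slip_acceleration(list(R = c(0.2, 0.9, 0.1)),
                         list(R = c(1, -0.3, 0)), "R", p0)
  expect_equal(a, c(0, -9.81, 0))  # all gains zero: ballistic

  p <- slip_params(M = 70, k_L = 10000, L_0 = 1)
  a <- slip_acceleration(list(R = c(0, 1, 0)), list(R = c(0, 0, 0)), "R", p)
  expect_equal(a, c(0, -9.81, 0))  # unloaded spring at rest length

  # compressed vertical leg: a_y = k dL / M - g
  a <- slip_acceleration(list(R = c(0, 0.95, 0)), list(R = c(0, 0, 0)), "R", p)
  expect_equal(a[2], 10000 * 0.05 / 70 - 9.81, tolerance = 1e-10)
  expect_equal(a[c(1, 3)], c(0, 0))
})

test_that("degenerate leg geometry is rejected", {
  p <- slip_params(M = 70, k_L = 10000, L_0 = 1)
  expect_error(
    slip_acceleration(list(R = c(0, 0, 0)), list(R = c(0, 0, 0)), "R", p),
    "zero length")
  ps <- slip_params(M = 70, k_L = 10000, L_0 = 1, k_s = 100)
  expect_error(
    slip_acceleration(list(R = c(0, 0, 0.5)), list(R = c(0, 0, 0)), "R", ps),
    "projection")
})

test_that("canonical gait walks with the expected hybrid structure", {
  tr <- fix_trial40()
  expect_s3_class(tr, "trial")
  expect_equal(tr$n_strides, 40)
  expect_true(all(tr$contact_R | tr$contact_L))

  # the contact cycle is DS1 -> SS_R -> DS2 -> SS_L, repeating
  ph <- label_gait_phases(tr$contact_R, tr$contact_L)
  runs <- rle(as.character(ph))$values
  cyc <- c(DS1 = "SS_R", SS_R = "DS2", DS2 = "SS_L", SS_L = "DS1")
  expect_true(all(runs[-1] == cyc[runs[-length(runs)]]))

  # each double-support phase occupies a plausible fraction of the stride
  for (g in c("DS1", "DS2")) {
    frac <- mean(ph == g)
    expect_gt(frac, 0.05)
    expect_lt(frac, 0.30)
  }
})

test_that("feet do not move while in contact", {
  tr <- fix_trial40()
  for (leg in c("R", "L")) {
    contact <- if (leg == "R") tr$contact_R else tr$contact_L
    foot <- if (leg == "R") tr$foot_R else tr$foot_L
    for (s in split(seq_along(contact), cumsum(c(TRUE, diff(contact) != 0)))) {
      if (!contact[s[1]] || length(s) < 2) next
      disp <- max(abs(sweep(foot[s, , drop = FALSE], 2, foot[s[1], ])))
      expect_equal(disp, 0)
    }
  }
})

test_that("the conservative canonical gait conserves mechanical energy", {
  tr <- fix_trial40()
  E <- slip_energy(tr)
  expect_lt((max(E) - min(E)) / abs(mean(E)), 1e-5)
})

test_that("recorded accelerations match the force law", {
  # second central difference of the CoM equals slip_acceleration to O(dt^2)
  tr <- fix_trial40()
  ph <- label_gait_phases(tr$contact_R, tr$contact_L)
  seg <- cumsum(c(TRUE, diff(tr$contact_R) != 0 | diff(tr$contact_L) != 0))
  interior <- unlist(lapply(split(seq_along(seg), seg), function(s)
    if (length(s) > 6) s[4:(length(s) - 3)] else integer(0)))
  set.seed(42)
  idx <- sample(interior, 200)  # spot check
  dt <- tr$dt
  for (i in idx) {
    fd <- (tr$com[i + 1, ] - 2 * tr$com[i, ] + tr$com[i - 1, ]) / dt^2
    active <- c("R", "L")[c(tr$contact_R[i], tr$contact_L[i])]
    qs <- list(R = tr$com[i, ] - tr$foot_R[i, ],
               L = tr$com[i, ] - tr$foot_L[i, ])
    vs <- list(R = tr$com_vel[i, ], L = tr$com_vel[i, ])
    a <- slip_acceleration(qs, vs, active, tr$params)
    expect_lt(max(abs(fd - a)), 0.05)
  }
})

test_that("mirroring the initial state mirrors the trajectory", {
  p <- default_gait_params()
  st <- default_gait_state()
  mir <- function(v) c(v[1], v[2], -v[3])
  st_m <- list(com = mir(st$com), vel = mir(st$vel),
               feet = list(R = mir(st$feet$L), L = mir(st$feet$R)),
               trailing = "R")
  a <- simulate_slip(p, st, n_strides = 5)
  # the mirrored walker leads with the other leg; compare over common time
  b <- simulate_slip(p, st_m, n_strides = 5)
  n <- min(length(a$t), length(b$t))
  expect_equal(a$com[1:n, 1:2], b$com[1:n, 1:2], tolerance = 1e-6)
  expect_equal(a$com[1:n, 3], -b$com[1:n, 3], tolerance = 1e-6)
  expect_equal(a$foot_R[1:n, 3], -b$foot_L[1:n, 3], tolerance = 1e-6)
})

test_that("non-walking parameter sets fail gracefully", {
  p <- slip_params(M = 70, g = 9.81, L_bio = 1, k_L = 3000, L_0 = 0.97,
                   theta_td = 0.36, phi_td = 0.05, speed = 1.2)
  err <- tryCatch(simulate_slip(p, default_gait_state(), n_strides = 30),
                  templatesig_gait_failure = function(e) e)
  expect_s3_class(err, "templatesig_gait_failure")
  expect_match(conditionMessage(err), "gait failed at stride")
  expect_true(is.null(err$trial) || inherits(err$trial, "trial"))
})

test_that("measurement noise injection is controlled and reproducible", {
  tr <- fix_trial40()
  expect_identical(add_noise(tr, sd_pos = 0), tr)
  n1 <- add_noise(tr, sd_pos = 0.001, seed = 7)
  n2 <- add_noise(tr, sd_pos = 0.001, seed = 7)
  expect_identical(n1$com, n2$com)
  expect_identical(n1$contact_R, tr$contact_R)
  # realized noise level (law of large numbers over ~37k draws)
  dev <- c(n1$com - tr$com, n1$foot_R - tr$foot_R, n1$foot_L - tr$foot_L)
  expect_rel_error(stats::sd(dev), 0.001, 0.05)
})
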