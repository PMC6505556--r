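kin_flap <- kinematics_spec(rotation_rate = 0)
kin_rot <- kinematics_spec(rotation_rate = 10)

test_that("start-up ramp is a clamped C2 smoothstep", {
  tr <- 0.05
  expect_equal(ramp_factor(0, tr), 0)
  expect_equal(ramp_factor(tr, tr), 1)
  expect_equal(ramp_factor(tr / 2, tr), 0.5)
  expect_equal(ramp_factor(10 * tr, tr), 1)
  t <- seq(0, 2 * tr, by = 1e-4)
  r <- ramp_factor(t, tr)
  expect_true(all(diff(r) >= 0))
  # analytic derivatives agree with finite differences
  d1 <- ramp_factor(t, tr, 1L)
  fd <- (ramp_factor(t + 1e-6, tr) - ramp_factor(t - 1e-6, tr)) / 2e-6
  expect_equal(d1, fd, tolerance = 1e-4)
})

test_that("stroke state: amplitude, derivatives, rest at t = 0", {
  expect_equal(stroke_state(0, kin_flap)[1, ], c(phi = 0, dphi = 0, ddphi = 0))
  t <- seq(kin_flap$t_ramp, kin_flap$duration, by = 1e-5)
  st <- stroke_state(t, kin_flap)
  expect_equal(max(abs(st[, "phi"])), pi / 2, tolerance = 1e-6)
  expect_equal(max(abs(st[, "dphi"])), pi / 2 * 2 * pi * 40, tolerance = 1e-6)
  # analytic dphi matches numerical differentiation of phi through the ramp
  tt <- seq(0.001, 0.2, by = 1e-3)
  fd <- (stroke_state(tt + 5e-7, kin_flap)[, "phi"] -
           stroke_state(tt - 5e-7, kin_flap)[, "phi"]) / 1e-6
  expect_equal(stroke_state(tt, kin_flap)[, "dphi"], fd, tolerance = 1e-5)
})

test_that("frame state composes flapping and body rotation", {
  t <- seq(0.06, 0.2, by = 1e-3)  # post-ramp
  fr0 <- frame_state(t, kin_flap)
  # flapping only: omega parallel to the local y' axis
  expect_equal(fr0$omega[, 1], rep(0, length(t)))
  expect_equal(fr0$omega[, 3], rep(0, length(t)))
  fr <- frame_state(t, kin_rot)
  # |omega|^2 = dphi^2 + dtheta^2 (the two axes are orthogonal)
  st <- stroke_state(t, kin_rot)
  expect_equal(rowSums(fr$omega^2), st[, "dphi"]^2 + 100, tolerance = 1e-10)
  # omega from finite differences of the rotation matrix Rz(theta) Ry(phi)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  Rot <- function(tt) {
    s <- stroke_state(tt, kin_rot)[1, "phi"]
    b <- body_state(tt, kin_rot)[1, "theta"]
    Rz(b) %*% Ry(s)
  }
  for (tt in c(0.08, 0.1234, 0.19)) {
    h <- 1e-7
    Rdot <- (Rot(tt + h) - Rot(tt - h)) / (2 * h)
    W <- t(Rot(tt)) %*% Rdot  # skew(omega_local)
    om_fd <- c(W[3, 2], W[1, 3], W[2, 1])
    om <- frame_state(tt, kin_rot)$omega[1, ]
    expect_equal(unname(om), om_fd, tolerance = 1e-5)
  }
})

test_that("rigid acceleration matches numerical differentiation of positions", {
  r <- c(5e-3, 2e-4, -1e-4)
  Rz <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3)
  Ry <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3)
  pos <- function(tt) {
    s <- stroke_state(tt, kin_rot)[1, "phi"]
    b <- body_state(tt, kin_rot)[1, "theta"]
    Rz(b) %*% Ry(s) %*% r
  }
  for (tt in c(0.03, 0.09, 0.151)) {
    h <- 2e-6
    acc_global <- (pos(tt + h) - 2 * pos(tt) + pos(tt - h)) / h^2
    s <- stroke_state(tt, kin_rot)[1, "phi"]
    b <- body_state(tt, kin_rot)[1, "theta"]
    acc_local <- drop(t(Rz(b) %*% Ry(s)) %*% acc_global)
    a <- rigid_acceleration(r, tt, kin_rot)$total[1, ]
    expect_equal(unname(a), acc_local, tolerance = 1e-4)
  }
})

test_that("acceleration decomposition: zero omega, Euler + centrifugal sum", {
  a0 <- rigid_acceleration(c(5e-3, 0, 0), 0, kin_rot)
  expect_equal(a0$total[1, ], c(0, 0, 0))
  t <- seq(0.06, 0.2, by = 1e-3)
  a <- rigid_acceleration(c(5e-3, 0, 0), t, kin_rot)
  expect_equal(a$total, a$euler + a$centrifugal)
})

test_that("out-of-plane loading is linear in the rotation rate and flips sign", {
  t <- seq(0.06, 0.2, by = 5e-4)
  ay <- function(Om) {
    k <- kinematics_spec(rotation_rate = Om)
    rigid_acceleration(c(5e-3, 0, 0), t, k)$total[, 2]
  }
  base <- ay(1)
  for (Om in c(5, 10, 20)) {
    expect_equal(ay(Om), Om * base, tolerance = 1e-9)
  }
  expect_equal(ay(-10), -ay(10), tolerance = 1e-12)
})

test_that("for small rotation the out-of-plane load is dominated by a 2f line", {
  k <- kinematics_spec(rotation_rate = 1)
  t <- time_grid(k)
  a <- rigid_acceleration(c(5e-3, 0, 0), t, k)$total[, 2]
  win <- analysis_window(k)
  expect_equal(dominant_frequency(t, a, win), 80, tolerance = 0.01)
})

test_that("nodal loads vanish without motion and respect planar symmetry", {
  model <- haltere_model(annulus_section(150, 50))
  F0 <- distributed_loads(model, 0, kin_rot)
  expect_equal(F0, rep(0, 6 * 32))
  # flapping only, symmetric sphere: y' force and x'/z' moment rows are zero
  Fh <- load_history(model, kin_flap, t = seq(0, 0.1, by = 1e-3))
  uy_rows <- 6 * (0:31) + 2
  expect_equal(max(abs(Fh[uy_rows, ])), 0)
  # laterally offset bulb under pure flapping: the centrifugal tension
  # acting through the y' offset produces a moment that bends the stalk
  # out of plane at 2f (plus a constant lateral torque offset)
  modoff <- haltere_model(annulus_section(150, 50),
                          bulb = bulb_spec("sphere", radius = 500,
                                           offset = c(150, 0)))
  k2 <- kinematics_spec(rotation_rate = 0)
  tt <- time_grid(k2)
  Fo <- load_history(modoff, k2, t = tt)
  mz_tip <- Fo[6 * 31 + 6, ]
  expect_gt(max(abs(mz_tip)), 0)
  expect_equal(dominant_frequency(tt, mz_tip, analysis_window(k2)), 80,
               tolerance = 0.01)
})

test_that("kinematics specification validates its invariants", {
  expect_error(kinematics_spec(dt = 1e-3), "too coarse")
  expect_error(kinematics_spec(total_periods = 3), "at least 4")
  expect_error(kinematics_spec(analysis_periods = 9), "ramp")
  expect_error(kinematics_spec(amplitude = 4))
})
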