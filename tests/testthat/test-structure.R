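model_cs <- haltere_model(annulus_section(150, 50))
sys_cs <- build_beam(model_cs)
ndof <- 6 * length(model_cs$nodes)
tip <- 6 * (length(model_cs$nodes) - 1)

test_that("static cantilever and uniform-torsion closed forms are reproduced", {
  EI <- model_cs$material$E * model_cs$section$I_y * 1e-24
  GJ <- model_cs$material$G * model_cs$section$J * 1e-24
  L <- model_cs$x_d
  f <- numeric(ndof); f[tip + 3] <- 1e-4
  u <- static_solve(sys_cs, f)
  expect_equal(u[tip + 3], 1e-4 * L^3 / (3 * EI), tolerance = 1e-9)
  f <- numeric(ndof); f[tip + 4] <- 1e-9
  u <- static_solve(sys_cs, f)
  expect_equal(u[tip + 4], 1e-9 * L / GJ, tolerance = 1e-9)
  expect_equal(static_solve(sys_cs, numeric(ndof)), numeric(ndof))
})

test_that("mass, stiffness and damping operators have the required structure", {
  expect_equal(sys_cs$K, t(sys_cs$K))
  expect_equal(sys_cs$M, t(sys_cs$M))
  expect_equal(sys_cs$C, 1e-5 * sys_cs$K)
  ev <- eigen(sys_cs$K[sys_cs$free, sys_cs$free], symmetric = TRUE,
              only.values = TRUE)$values
  expect_true(all(ev > 0))
  evM <- eigen(sys_cs$M[sys_cs$free, sys_cs$free], symmetric = TRUE,
               only.values = TRUE)$values
  expect_true(all(evM > 0))
})

test_that("first bending frequency is far above the flapping frequency", {
  f <- modal_frequencies(sys_cs, 4)
  expect_true(all(diff(f) >= -1e-9))
  expect_gt(f[1], 500)
  expect_lt(f[1], 800)
  # Rayleigh quotient with a static tip-force shape brackets f1 from below
  EI <- model_cs$material$E * model_cs$section$I_y * 1e-24
  L <- model_cs$x_d
  m_b <- bulb_properties(model_cs$bulb)$mass
  m_s <- model_cs$material$rho * model_cs$section$A * 1e-12 * L
  k_tip <- 3 * EI / L^3
  f_rq <- sqrt(k_tip / (m_b + 33 / 140 * m_s)) / (2 * pi)
  expect_equal(f[1], f_rq, tolerance = 0.02)
})

test_that("mesh refinement leaves the first frequency nearly unchanged", {
  f31 <- modal_frequencies(sys_cs, 1)
  f62 <- modal_frequencies(build_beam(model_cs, n_elements = 62), 1)
  expect_equal(f31, f62, tolerance = 0.01)
})

test_that("Newmark integration reproduces the static limit and stays at rest", {
  # zero load, zero initial conditions: identically zero
  z <- newmark_simulate(sys_cs, matrix(0, ndof, 101), dt = 1e-4, duration = 1e-2)
  expect_equal(max(abs(z$U)), 0)
  # slowly ramped constant tip load converges to the static solution
  f <- numeric(ndof); f[tip + 3] <- 1e-4
  nt <- 2001
  tgrid <- seq(0, 0.2, length.out = nt)
  ramp <- ramp_factor(tgrid, 0.05)
  F <- f %o% ramp
  sim <- newmark_simulate(sys_cs, F, dt = tgrid[2], duration = 0.2)
  u_stat <- static_solve(sys_cs, f)
  expect_equal(sim$U[tip + 3, nt], u_stat[tip + 3], tolerance = 1e-3)
})

test_that("free decay follows the Rayleigh damping ratio of the first mode", {
  # initial condition on the first bending mode; zeta_1 = alpha_k * omega_1 / 2
  Mf <- sys_cs$M[sys_cs$free, sys_cs$free]
  Kf <- sys_cs$K[sys_cs$free, sys_cs$free]
  L <- t(chol(Mf))
  A <- forwardsolve(L, t(forwardsolve(L, Kf)))
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  i1 <- which.min(eg$values)
  om1 <- sqrt(eg$values[i1])
  shape <- backsolve(t(L), eg$vectors[, i1])
  u0 <- numeric(ndof); u0[sys_cs$free] <- shape / max(abs(shape)) * 1e-5
  period <- 2 * pi / om1
  sim <- newmark_simulate(sys_cs, matrix(0, ndof, 4105), dt = period / 80,
                          duration = 50 * period, u0 = u0)
  x <- sim$U[tip + 3, ]
  # amplitude after n periods: exp(-zeta * omega * n * T)
  pk <- which(diff(sign(diff(x))) == -2) + 1
  pk <- pk[x[pk] > 0]
  n_cycles <- 20
  ratio <- x[pk[1 + n_cycles]] / x[pk[1]]
  zeta <- 1e-5 * om1 / 2
  expect_equal(ratio, exp(-zeta * om1 * n_cycles * period), tolerance = 0.02)
})

test_that("total mechanical energy of the damped free system never increases", {
  u0 <- numeric(ndof)
  u0[sys_cs$free] <- static_solve(sys_cs, {
    f <- numeric(ndof); f[tip + 3] <- 1e-4; f
  })[sys_cs$free]
  sim <- newmark_simulate(sys_cs, matrix(0, ndof, 2001), dt = 2e-5,
                          duration = 0.04, u0 = u0)
  Mf <- sys_cs$M[sys_cs$free, sys_cs$free]
  Kf <- sys_cs$K[sys_cs$free, sys_cs$free]
  U <- sim$U[sys_cs$free, ]
  V <- sim$V[sys_cs$free, ]
  E <- 0.5 * colSums(U * (Kf %*% U)) + 0.5 * colSums(V * (Mf %*% V))
  expect_true(all(diff(E) <= 1e-9 * E[1]))
})

test_that("divergent integrations are reported with a step number", {
  F <- matrix(0, ndof, 2001)
  F[tip + 3, ] <- 1e-4
  F[tip + 3, 1500] <- NaN
  expect_error(
    suppressWarnings(newmark_simulate(sys_cs, F, dt = 1e-5, duration = 0.02)),
    "diverged")
})

test_that("deformation angles vanish out of plane for symmetric flapping", {
  run <- cached_run("cs_flap", short = TRUE)
  win <- analysis_window(run$kin)
  sel <- run$angles$t >= win[1]
  expect_lt(max(abs(run$angles$dtheta[sel])), 1e-6)
  expect_lt(max(abs(run$angles$dgamma[sel])), 1e-6)
  expect_gt(peak_to_peak(run$angles$t, run$angles$dphi, win), 5e-3)
  # arctan vs plain ratio indistinguishable at these amplitudes
  expect_equal(max(abs(run$angles$dphi)), tan(max(abs(run$angles$dphi))),
               tolerance = 1e-4)
})

test_that("out-of-plane bending amplitude is linear in the rotation rate and signed", {
  p2p <- vapply(c(1, 5, 10, 20), function(Om) {
    r <- cached_run("cs_rot", rotation_rate = Om, short = TRUE)
    peak_to_peak(r$angles$t, r$angles$dtheta, analysis_window(r$kin))
  }, numeric(1))
  fit <- stats::lm(p2p ~ c(1, 5, 10, 20))
  expect_gt(summary(fit)$r.squared, 0.999)
  # reversing the rotation reverses the out-of-plane response
  rp <- cached_run("cs_rot", rotation_rate = 10, short = TRUE)
  rn <- cached_run("cs_rot", rotation_rate = -10, short = TRUE)
  win <- analysis_window(rp$kin)
  sel <- rp$angles$t >= win[1]
  expect_equal(rn$angles$dtheta[sel], -rp$angles$dtheta[sel], tolerance = 1e-8)
})

test_that("strain recovery is consistent with imposed bending and tension", {
  # static tip force in z': strain at alpha = pi/2 (neutral axis) has no
  # bending part; alpha = 0 matches -c * kappa with kappa = M(x)/EI
  f <- numeric(ndof); f[tip + 3] <- 1e-4
  u <- static_solve(sys_cs, f)
  sim <- list(t = 0, U = matrix(u, ncol = 1), model = model_cs)
  class(sim) <- "haltere_sim"
  eps <- strain_at(sim, 300, c(0, pi / 2, pi))
  EI <- model_cs$material$E * model_cs$section$I_y * 1e-24
  kappa <- 1e-4 * (model_cs$x_d - 300e-6) / EI
  cc <- model_cs$section$c * 1e-6
  expect_equal(as.numeric(eps[1, 1]), -cc * kappa, tolerance = 1e-6)
  expect_lt(abs(eps[1, 2]), 1e-12)
  expect_equal(as.numeric(eps[1, 3]), cc * kappa, tolerance = 1e-6)
  # static axial force: uniform tensile strain at every alpha
  f <- numeric(ndof); f[tip + 1] <- 1e-3
  ua <- static_solve(sys_cs, f)
  sim$U <- matrix(ua, ncol = 1)
  epsa <- strain_at(sim, 300, c(0, pi / 3, pi / 2))
  EA <- model_cs$material$E * model_cs$section$A * 1e-12
  expect_equal(as.numeric(epsa), rep(1e-3 / EA, 3), tolerance = 1e-9)
  expect_error(strain_at(sim, 6000, 0), "inside")
})

test_that("flapping strains share the centrifugal tension across the circumference", {
  run <- cached_run("cs_flap", short = TRUE)
  win <- analysis_window(run$kin)
  t <- attr(run$strains, "t")
  sel <- t >= win[1] & t < win[2]  # integer number of periods
  means <- colMeans(run$strains[sel, ])
  # mean strain (tension) is positive and identical at all alpha
  expect_true(all(means > 0))
  expect_lt(max(means) - min(means), 0.01 * mean(means))
})
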