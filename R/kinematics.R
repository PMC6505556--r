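#' Flapping and body-rotation kinematics specification
#'
#' Defines the prescribed motion of the haltere base frame: sinusoidal
#' flapping \eqn{\phi(t) = A_f \sin(2\pi f_\phi t)} about the base-plate Y
#' axis, and a constant-rate body rotation \eqn{\dot\theta = \Omega} about
#' the global Z axis. Both motions are ramped from rest with the same
#' C2-continuous sigmoidal ramp (quintic smoothstep) over `ramp_periods`
#' flapping periods.
#'
#' @param amplitude Flapping amplitude \eqn{A_f} (rad), in (0, pi].
#' @param frequency Flapping frequency \eqn{f_\phi} (Hz).
#' @param rotation_rate Body rotation rate \eqn{\Omega} (rad s^-1) about
#'   global Z; 0 means flapping only.
#' @param ramp_periods Ramp duration in flapping periods.
#' @param total_periods Total simulated duration in flapping periods.
#' @param analysis_periods Length of the post-transient analysis window, in
#'   flapping periods (taken from the end of the run).
#' @param dt Time step (s); must resolve the flapping with at least 50
#'   steps per period.
#' @return Object of class `kinematics_spec`.
#' @export
kinematics_spec <- function(amplitude = pi / 2, frequency = 40,
                            rotation_rate = 0, ramp_periods = 2,
                            total_periods = 10, analysis_periods = 5,
                            dt = 1e-5) {
  stopifnot(amplitude > 0, amplitude <= pi, frequency > 0, dt > 0,
            ramp_periods > 0, analysis_periods > 0)
  if (dt >= 1 / (50 * frequency)) {
    stop("dt = ", dt, " s is too coarse: need dt < 1/(50 f) = ",
         signif(1 / (50 * frequency), 3), " s")
  }
  if (total_periods < ramp_periods + 4) {
    stop("total_periods must allow at least 4 flapping periods after the ramp")
  }
  if (analysis_periods > total_periods - ramp_periods) {
    stop("analysis window overlaps the start-up ramp")
  }
  spec <- list(
    amplitude = amplitude, frequency = frequency,
    rotation_rate = rotation_rate,
    t_ramp = ramp_periods / frequency,
    duration = total_periods / frequency,
    analysis_periods = analysis_periods,
    dt = dt
  )
  class(spec) <- "kinematics_spec"
  spec
}

#' Time grid of a kinematics specification
#' @param spec A [kinematics_spec()].
#' @return Numeric vector of sample times from 0 to the total duration.
#' @export
time_grid <- function(spec) {
  seq(0, spec$duration, by = spec$dt)
}

#' Start and end of the post-transient analysis window
#' @param spec A [kinematics_spec()].
#' @return Length-2 numeric vector `c(start, end)` in seconds.
#' @export
analysis_window <- function(spec) {
  c(spec$duration - spec$analysis_periods / spec$frequency, spec$duration)
}

#' Sigmoidal start-up ramp
#'
#' Quintic smoothstep \eqn{s(x) = 6x^5 - 15x^4 + 10x^3} on
#' \eqn{x = t/t_{ramp}}, clamped to \[0, 1\]. C2-continuous, so the ramped
#' kinematics have continuous acceleration.
#'
#' @param t Time(s), s.
#' @param t_ramp Ramp duration, s.
#' @param deriv 0, 1 or 2: return the ramp or its first or second time
#'   derivative.
#' @return Numeric vector of the same length as `t`.
#' @export
ramp_factor <- function(t, t_ramp, deriv = 0L) {
  stopifnot(t_ramp > 0)
  x <- pmin(pmax(t / t_ramp, 0), 1)
  inside <- t > 0 & t < t_ramp
  if (deriv == 0L) {
    6 * x^5 - 15 * x^4 + 10 * x^3
  } else if (deriv == 1L) {
    ifelse(inside, (30 * x^4 - 60 * x^3 + 30 * x^2) / t_ramp, 0)
  } else if (deriv == 2L) {
    ifelse(inside, (120 * x^3 - 180 * x^2 + 60 * x) / t_ramp^2, 0)
  } else {
    stop("deriv must be 0, 1 or 2")
  }
}

#' Stroke angle and its analytic time derivatives
#'
#' \eqn{\phi(t) = r(t) A_f \sin(2\pi f t)} with the ramp `r(t)` of
#' [ramp_factor()]; derivatives are computed analytically, including the
#' ramp derivatives.
#'
#' @param t Time(s), s.
#' @param spec A [kinematics_spec()].
#' @return Matrix with columns `phi`, `dphi`, `ddphi` (rad, rad/s, rad/s^2).
#' @export
stroke_state <- function(t, spec) {
  A <- spec$amplitude
  w <- 2 * pi * spec$frequency
  r0 <- ramp_factor(t, spec$t_ramp, 0L)
  r1 <- ramp_factor(t, spec$t_ramp, 1L)
  r2 <- ramp_factor(t, spec$t_ramp, 2L)
  s <- sin(w * t); cs <- cos(w * t)
  cbind(phi = A * r0 * s,
        dphi = A * (r1 * s + r0 * w * cs),
        ddphi = A * (r2 * s + 2 * r1 * w * cs - r0 * w^2 * s))
}

#' Body rotation angle, rate and acceleration
#'
#' The body rotation rate is ramped with the same sigmoid as the stroke:
#' \eqn{\dot\theta(t) = r(t)\,\Omega}. The angle integrates the quintic
#' smoothstep in closed form.
#'
#' @inheritParams stroke_state
#' @return Matrix with columns `theta`, `dtheta`, `ddtheta`.
#' @export
body_state <- function(t, spec) {
  Om <- spec$rotation_rate
  tr <- spec$t_ramp
  x <- pmin(pmax(t / tr, 0), 1)
  # integral of 6x^5 - 15x^4 + 10x^3 is x^6 - 3x^5 + 2.5x^4 (equals 1/2 at x = 1)
  int_s <- (x^6 - 3 * x^5 + 2.5 * x^4) * tr + pmax(t - tr, 0)
  cbind(theta = Om * int_s,
        dtheta = Om * ramp_factor(t, tr, 0L),
        ddtheta = Om * ramp_factor(t, tr, 1L))
}

#' Angular velocity and acceleration of the haltere-fixed frame
#'
#' Composes the body rotation (rate \eqn{\dot\theta} about global Z) with
#' the flapping rotation (rate \eqn{\dot\phi} about the base-plate Y axis)
#' and expresses the angular velocity \eqn{\omega} and acceleration
#' \eqn{\dot\omega} of the haltere-fixed frame in local x'y'z' coordinates:
#' \deqn{\omega = (-\dot\theta \sin\phi,\; \dot\phi,\; \dot\theta \cos\phi)}
#' with the corresponding analytic time derivative.
#'
#' @inheritParams stroke_state
#' @return List with elements `t`, `stroke`, `body` (the underlying states)
#'   and matrices `omega`, `domega` (n x 3, local components).
#' @export
frame_state <- function(t, spec) {
  st <- stroke_state(t, spec)
  bd <- body_state(t, spec)
  phi <- st[, "phi"]; dphi <- st[, "dphi"]
  dth <- bd[, "dtheta"]; ddth <- bd[, "ddtheta"]
  sp <- sin(phi); cp <- cos(phi)
  omega <- cbind(-dth * sp, dphi, dth * cp)
  domega <- cbind(-ddth * sp - dth * dphi * cp,
                  st[, "ddphi"],
                  ddth * cp - dth * dphi * sp)
  colnames(omega) <- colnames(domega) <- c("x", "y", "z")
  list(t = t, stroke = st, body = bd, omega = omega, domega = domega)
}

# cross product of two n x 3 matrices, row-wise
cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Rigid-frame acceleration of a point fixed in the haltere frame
#'
#' For a point at local position `r` moving rigidly with the haltere frame,
#' the inertial acceleration expressed in local coordinates is
#' \deqn{a = \dot\omega \times r + \omega \times (\omega \times r),}
#' the Euler (tangential) and centrifugal terms. With both flapping and
#' body rotation active, the cross terms between \eqn{\dot\phi} and
#' \eqn{\dot\theta} in these products are the Coriolis-type gyroscopic
#' loading: they appear out of the stroke plane at twice the flapping
#' frequency and reverse sign with the rotation direction.
#'
#' @param r Length-3 position vector in the local frame (metres).
#' @param t Time(s), s.
#' @param spec A [kinematics_spec()].
#' @param frame Optional precomputed [frame_state()] at `t`.
#' @return List of n x 3 matrices `total`, `euler`, `centrifugal` (m s^-2).
#' @export
rigid_acceleration <- function(r, t, spec, frame = NULL) {
  stopifnot(length(r) == 3)
  if (is.null(frame)) frame <- frame_state(t, spec)
  n <- length(frame$t)
  rm <- matrix(r, n, 3, byrow = TRUE)
  a_e <- cross3(frame$domega, rm)
  a_c <- cross3(frame$omega, cross3(frame$omega, rm))
  list(total = a_e + a_c, euler = a_e, centrifugal = a_c)
}

#' Nodal inertial load history for a haltere model
#'
#' Converts the rigid-frame acceleration field into a finite-element load
#' history: each stalk node carries the d'Alembert force of its tributary
#' mass, \eqn{-\rho A\, \ell\, a(x_k, t)}, plus a tributary torsional moment
#' from the cross-section's polar rotary inertia; the distal node
#' additionally carries the bulb force \eqn{-m_b a(r_{com}, t)} and moment
#' \eqn{-(I_c \dot\omega + \omega \times I_c \omega) + d \times F_b}, where
#' `d` is the rigid centre-of-mass offset from the node. Loads are
#' evaluated on the undeformed configuration (small-deflection
#' linearisation).
#'
#' @param model A [haltere_model()].
#' @param spec A [kinematics_spec()].
#' @param t Times at which to evaluate (defaults to the full [time_grid()]).
#' @return Matrix of size (6 * n_nodes) x length(t): nodal force/moment
#'   history in N and N m, DOF order (ux, uy, uz, rx, ry, rz) per node.
#' @export
load_history <- function(model, spec, t = time_grid(spec)) {
  stopifnot(inherits(model, "haltere_model"), inherits(spec, "kinematics_spec"))
  fr <- frame_state(t, spec)
  nt <- length(t)
  nodes <- model$nodes
  nn <- length(nodes)
  ndof <- 6L * nn
  sec <- model$section
  rhoA <- model$material$rho * sec$A * 1e-12            # kg / m
  rhoIp <- model$material$rho * (sec$I_y + sec$I_z) * 1e-24  # kg m
  el_len <- diff(nodes)
  trib <- c(el_len / 2, 0) + c(0, el_len / 2)           # tributary lengths
  F <- matrix(0, ndof, nt)
  # stalk nodes: translational d'Alembert force and torsional rotary moment
  ## acceleration at (x, 0, 0): a = domega x r + omega x (omega x r), linear in x
  ## precompute per-unit-x acceleration components
  wx <- fr$omega[, 1]; wy <- fr$omega[, 2]; wz <- fr$omega[, 3]
  dwx <- fr$domega[, 1]; dwy <- fr$domega[, 2]; dwz <- fr$domega[, 3]
  ax1 <- -(wy^2 + wz^2)          # a_x per unit x
  ay1 <- dwz + wx * wy           # a_y per unit x
  az1 <- -dwy + wx * wz          # a_z per unit x
  for (k in seq_len(nn)) {
    mk <- rhoA * trib[k]
    x <- nodes[k]
    i0 <- 6L * (k - 1L)
    F[i0 + 1L, ] <- F[i0 + 1L, ] - mk * ax1 * x
    F[i0 + 2L, ] <- F[i0 + 2L, ] - mk * ay1 * x
    F[i0 + 3L, ] <- F[i0 + 3L, ] - mk * az1 * x
    F[i0 + 4L, ] <- F[i0 + 4L, ] - rhoIp * trib[k] * dwx
  }
  # bulb at the distal node
  bp <- bulb_properties(model$bulb)
  d <- bp$com_offset
  r_com <- c(model$x_d, 0, 0) + d
  acc <- rigid_acceleration(r_com, t, spec, frame = fr)$total
  Fb <- -bp$mass * acc
  Iw <- fr$omega %*% t(bp$inertia)
  Mb <- -(fr$domega %*% t(bp$inertia) + cross3(fr$omega, Iw)) +
    cross3(matrix(d, nt, 3, byrow = TRUE), Fb)
  i0 <- 6L * (nn - 1L)
  F[i0 + (1:3), ] <- F[i0 + (1:3), ] + t(Fb)
  F[i0 + (4:6), ] <- F[i0 + (4:6), ] + t(Mb)
  F
}

#' Nodal load vector at a single time
#'
#' Convenience wrapper around [load_history()] for one time point.
#'
#' @inheritParams load_history
#' @param t A single time (s).
#' @return Numeric vector of length 6 * n_nodes.
#' @export
distributed_loads <- function(model, t, spec) {
  stopifnot(length(t) == 1L)
  drop(load_history(model, spec, t = t))
}
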