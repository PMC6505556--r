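#' Newmark time integration of the beam system
#'
#' Integrates `M u'' + C u' + K u = F(t)` with the average-acceleration
#' Newmark scheme (gamma = 1/2, beta = 1/4), which is unconditionally
#' stable and adds no numerical damping, so decay is governed entirely by
#' the physical Rayleigh damping. The effective stiffness is factorised
#' once (Cholesky) and reused at every step.
#'
#' @param sys A [build_beam()] system.
#' @param loads Load history: matrix of size ndof x nt whose columns are
#'   the load vectors at the sample times, or a function `f(t)` returning a
#'   load vector.
#' @param dt Time step (s).
#' @param duration Total integration time (s).
#' @param u0,v0 Optional initial displacement/velocity (full DOF vectors);
#'   default zero.
#' @return Object of class `haltere_sim` with the time grid `t` and the
#'   full nodal histories `U`, `V`, `A` (ndof x nt; clamped DOFs are
#'   identically zero).
#' @export
newmark_simulate <- function(sys, loads, dt, duration, u0 = NULL, v0 = NULL) {
  stopifnot(inherits(sys, "beam_system"), dt > 0, duration > dt)
  t <- seq(0, duration, by = dt)
  nt <- length(t)
  free <- sys$free
  ndof <- nrow(sys$K)
  if (is.function(loads)) {
    F <- vapply(t, loads, numeric(ndof))
  } else {
    F <- loads
    if (!is.matrix(F) || nrow(F) != ndof || ncol(F) < nt) {
      stop("load history must be an ndof x nt matrix matching the time grid")
    }
  }
  M <- sys$M[free, free]; C <- sys$C[free, free]; K <- sys$K[free, free]
  Ff <- F[free, , drop = FALSE]
  beta <- 0.25; gam <- 0.5
  c1 <- 1 / (beta * dt^2); c2 <- 1 / (beta * dt); c3 <- 1 / (2 * beta) - 1
  d1 <- gam / (beta * dt); d2 <- gam / beta - 1; d3 <- dt * (gam / (2 * beta) - 1)
  Keff <- K + d1 * C + c1 * M
  R <- chol(Keff)
  Rt <- t(R)
  n <- length(free)
  u <- if (is.null(u0)) numeric(n) else u0[free]
  v <- if (is.null(v0)) numeric(n) else v0[free]
  a <- solve(M, Ff[, 1] - C %*% v - K %*% u)
  U <- matrix(0, n, nt); V <- matrix(0, n, nt); Acc <- matrix(0, n, nt)
  U[, 1] <- u; V[, 1] <- v; Acc[, 1] <- a
  for (i in 2:nt) {
    rhs <- Ff[, i] + M %*% (c1 * u + c2 * v + c3 * a) +
      C %*% (d1 * u + d2 * v + d3 * a)
    un <- backsolve(R, forwardsolve(Rt, rhs))
    an <- c1 * (un - u) - c2 * v - c3 * a
    vn <- v + dt * ((1 - gam) * a + gam * an)
    u <- un; v <- drop(vn); a <- drop(an)
    U[, i] <- u; V[, i] <- v; Acc[, i] <- a
    if (i %% 1000L == 0L && !all(is.finite(u))) {
      stop("Newmark integration diverged: non-finite state at step ", i,
           " (t = ", signif(t[i], 6), " s)")
    }
  }
  if (!all(is.finite(U[, nt]))) {
    stop("Newmark integration diverged: non-finite state at the final step")
  }
  full <- function(X) {
    Y <- matrix(0, ndof, nt)
    Y[free, ] <- X
    Y
  }
  sim <- list(t = t, U = full(U), V = full(V), A = full(Acc),
              free = free, model = sys$model)
  class(sim) <- "haltere_sim"
  sim
}

#' Bulb deformation angles from a simulation
#'
#' Recovers the three deformation angles of the rigid bulb from the distal
#' node's displacement and rotation history: in-plane bending
#' \eqn{\Delta\phi = \arctan(\delta_z / x_d)}, out-of-plane bending
#' \eqn{\Delta\theta = \arctan(\delta_y / x_d)} (deflections of the bulb
#' centre of mass), and twist \eqn{\Delta\gamma} from the z' deflection
#' difference of two rigid-body side points placed at the bulb's y'
#' semi-axis on either side of the centre of mass, divided by their y'
#' separation. Deflections of off-node points use the small-rotation
#' rigid-body map \eqn{\delta = u + \theta \times r}.
#'
#' The arctangent of the deflection ratio is used; at the small angles
#' produced here it is numerically identical to the ratio itself.
#'
#' @param sim A [newmark_simulate()] result.
#' @param model Optional [haltere_model()] (defaults to the one stored in
#'   the simulation).
#' @return Data frame with columns `t`, `dphi`, `dtheta`, `dgamma` (rad).
#' @export
deformation_angles <- function(sim, model = sim$model) {
  stopifnot(inherits(sim, "haltere_sim"))
  nn <- length(model$nodes)
  i0 <- 6L * (nn - 1L)
  u <- sim$U[i0 + (1:3), , drop = FALSE]
  th <- sim$U[i0 + (4:6), , drop = FALSE]
  d <- bulb_properties(model$bulb)$com_offset
  s_y <- model$bulb$semi_axes[2] * 1e-6
  if (s_y <= 0) stop("bulb y' semi-axis must be positive to define the twist angle")
  # COM deflection: u + theta x d
  del <- u + rbind(th[2, ] * d[3] - th[3, ] * d[2],
                   th[3, ] * d[1] - th[1, ] * d[3],
                   th[1, ] * d[2] - th[2, ] * d[1])
  # side points at d +/- s_y e_y: z-deflection difference = 2 s_y * theta_x
  p1 <- d + c(0, s_y, 0)
  p2 <- d - c(0, s_y, 0)
  dz1 <- u[3, ] + th[1, ] * p1[2] - th[2, ] * p1[1]
  dz2 <- u[3, ] + th[1, ] * p2[2] - th[2, ] * p2[1]
  data.frame(t = sim$t,
             dphi = atan(del[3, ] / model$x_d),
             dtheta = atan(del[2, ] / model$x_d),
             dgamma = atan((dz1 - dz2) / (2 * s_y)))
}

#' Axial surface strain at a span position and circumferential angle
#'
#' Recovers the spanwise normal strain \eqn{\epsilon_{xx}} on the outer
#' fibre of the stalk from the beam solution, combining the axial stretch
#' with the Euler-Bernoulli bending terms
#' \deqn{\epsilon_{xx}(\alpha, t) = u_x'(x_s, t)
#'   - c \cos\alpha\, \kappa_z(x_s, t) - c \sin\alpha\, \kappa_y(x_s, t),}
#' where the curvatures are second derivatives of the Hermite shape
#' functions of the element containing `x_s`, `c` is the outer fibre
#' distance and the circumferential angle `alpha` is measured from the
#' dorsal (+z') fibre towards the lateral (+y') fibre.
#'
#' @param sim A [newmark_simulate()] result.
#' @param x_s Span position (\eqn{\mu m} from the base), strictly inside
#'   the stalk.
#' @param alpha Circumferential angle(s), rad.
#' @param model Optional [haltere_model()].
#' @return Matrix nt x length(alpha) of strain histories (dimensionless),
#'   with `alpha` as column names and the time grid as attribute `t`.
#' @export
strain_at <- function(sim, x_s, alpha, model = sim$model) {
  stopifnot(inherits(sim, "haltere_sim"))
  xs <- x_s * 1e-6
  nodes <- model$nodes
  if (xs <= 0 || xs >= model$x_d) {
    stop("x_s must lie strictly inside the stalk (0, ", model$x_d * 1e6, ") um")
  }
  e <- findInterval(xs, nodes, rightmost.closed = TRUE)
  l <- nodes[e + 1L] - nodes[e]
  s <- xs - nodes[e]
  i1 <- 6L * (e - 1L)
  i2 <- 6L * e
  # Hermite second derivatives at local coordinate s
  n1 <- -6 / l^2 + 12 * s / l^3
  n2 <- -4 / l + 6 * s / l^2
  n3 <- 6 / l^2 - 12 * s / l^3
  n4 <- -2 / l + 6 * s / l^2
  U <- sim$U
  du <- (U[i2 + 1L, ] - U[i1 + 1L, ]) / l
  # curvature of w (z' deflection): ry = -w'
  kz <- n1 * U[i1 + 3L, ] - n2 * U[i1 + 5L, ] + n3 * U[i2 + 3L, ] - n4 * U[i2 + 5L, ]
  # curvature of v (y' deflection): rz = +v'
  ky <- n1 * U[i1 + 2L, ] + n2 * U[i1 + 6L, ] + n3 * U[i2 + 2L, ] + n4 * U[i2 + 6L, ]
  cc <- model$section$c * 1e-6
  out <- vapply(alpha, function(a) du - cc * cos(a) * kz - cc * sin(a) * ky,
                numeric(length(sim$t)))
  out <- matrix(out, ncol = length(alpha))
  colnames(out) <- signif(alpha, 8)
  attr(out, "t") <- sim$t
  attr(out, "alpha") <- alpha
  out
}

#' Peak-to-peak amplitude over a time window
#'
#' @param t Time vector.
#' @param x Signal.
#' @param window Length-2 vector `c(start, end)`; defaults to the full
#'   range.
#' @return `max(x) - min(x)` over the window.
#' @export
peak_to_peak <- function(t, x, window = range(t)) {
  sel <- t >= window[1] & t <= window[2]
  max(x[sel]) - min(x[sel])
}

#' Dominant frequency of a signal over a window
#'
#' Removes the mean, applies an FFT over the (integer-period) window and
#' returns the frequency of the largest spectral line.
#'
#' @inheritParams peak_to_peak
#' @return Frequency in Hz.
#' @export
dominant_frequency <- function(t, x, window = range(t)) {
  sel <- t >= window[1] & t <= window[2]
  xs <- x[sel] - mean(x[sel])
  n <- length(xs)
  sp <- Mod(stats::fft(xs))[seq_len(floor(n / 2))]
  dt <- t[2] - t[1]
  freqs <- (seq_len(floor(n / 2)) - 1) / (n * dt)
  freqs[which.max(sp)]
}
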