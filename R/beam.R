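## 3D Euler-Bernoulli beam assembly.
##
## Each node carries 6 DOFs in the order (ux, uy, uz, rx, ry, rz); the beam
## axis is the local x' axis, so element matrices need no rotation. Bending
## uses cubic Hermite shape functions with the convention ry = -dw/dx
## (deflection w along z') and rz = +dv/dx (deflection v along y'). The
## rigid bulb enters as a 6x6 mass block at the distal node with exact
## translation-rotation coupling from its centre-of-mass offset.

# stiffness of one element; props in SI (EA N, EI N m^2, GJ N m^2), l in m
beam_element_k <- function(EA, EIy, EIz, GJ, l) {
  k <- matrix(0, 12, 12)
  idx <- function(i) i  # DOFs 1..6 node 1, 7..12 node 2
  # axial (ux1, ux2)
  ka <- EA / l
  k[c(1, 7), c(1, 7)] <- ka * matrix(c(1, -1, -1, 1), 2)
  # torsion (rx1, rx2)
  kt <- GJ / l
  k[c(4, 10), c(4, 10)] <- kt * matrix(c(1, -1, -1, 1), 2)
  # bending in x-y plane: (uy1, rz1, uy2, rz2)
  kb <- EIz / l^3 * matrix(c(
    12, 6 * l, -12, 6 * l,
    6 * l, 4 * l^2, -6 * l, 2 * l^2,
    -12, -6 * l, 12, -6 * l,
    6 * l, 2 * l^2, -6 * l, 4 * l^2), 4, 4, byrow = TRUE)
  iy <- c(2, 6, 8, 12)
  k[iy, iy] <- k[iy, iy] + kb
  # bending in x-z plane: (uz1, ry1, uz2, ry2), ry = -w'
  kz <- EIy / l^3 * matrix(c(
    12, -6 * l, -12, -6 * l,
    -6 * l, 4 * l^2, 6 * l, 2 * l^2,
    -12, 6 * l, 12, 6 * l,
    -6 * l, 2 * l^2, 6 * l, 4 * l^2), 4, 4, byrow = TRUE)
  iz <- c(3, 5, 9, 11)
  k[iz, iz] <- k[iz, iz] + kz
  k
}

# consistent mass of one element; rhoA kg/m, rhoIp kg m
beam_element_m <- function(rhoA, rhoIp, l) {
  m <- matrix(0, 12, 12)
  ma <- rhoA * l / 6
  m[c(1, 7), c(1, 7)] <- ma * matrix(c(2, 1, 1, 2), 2)
  mt <- rhoIp * l / 6
  m[c(4, 10), c(4, 10)] <- mt * matrix(c(2, 1, 1, 2), 2)
  mb <- rhoA * l / 420 * matrix(c(
    156, 22 * l, 54, -13 * l,
    22 * l, 4 * l^2, 13 * l, -3 * l^2,
    54, 13 * l, 156, -22 * l,
    -13 * l, -3 * l^2, -22 * l, 4 * l^2), 4, 4, byrow = TRUE)
  iy <- c(2, 6, 8, 12)
  m[iy, iy] <- m[iy, iy] + mb
  mz <- rhoA * l / 420 * matrix(c(
    156, -22 * l, 54, 13 * l,
    -22 * l, 4 * l^2, -13 * l, -3 * l^2,
    54, -13 * l, 156, 22 * l,
    13 * l, -3 * l^2, 22 * l, 4 * l^2), 4, 4, byrow = TRUE)
  iz <- c(3, 5, 9, 11)
  m[iz, iz] <- m[iz, iz] + mz
  m
}

skew3 <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

# 6x6 mass block of a rigid body attached at a node with COM offset d (m)
rigid_body_mass <- function(mass, inertia_com, d) {
  D <- skew3(d)
  M <- matrix(0, 6, 6)
  M[1:3, 1:3] <- diag(3) * mass
  M[1:3, 4:6] <- -mass * D
  M[4:6, 1:3] <- mass * D
  M[4:6, 4:6] <- inertia_com + mass * crossprod(D)  # parallel-axis term
  M
}

#' Assemble the beam finite-element system for a haltere model
#'
#' Builds global consistent mass, stiffness and Rayleigh damping operators
#' for the stalk discretised into 3D Euler-Bernoulli beam elements (axial,
#' torsional and two Hermite bending planes; 12 DOFs per element), adds the
#' rigid bulb as a lumped mass with rotary inertia and exact offset
#' coupling at the distal node, and clamps all six DOFs of the base node.
#'
#' @param model A [haltere_model()].
#' @param alpha_k Stiffness-proportional Rayleigh damping coefficient (s).
#' @param alpha_m Mass-proportional Rayleigh coefficient (s^-1).
#' @param n_elements Optional override of the model's element count (e.g.
#'   for mesh-convergence studies).
#' @return Object of class `beam_system`: dense `M`, `C`, `K` on all DOFs,
#'   the free-DOF index, node coordinates and the originating model.
#' @export
build_beam <- function(model, alpha_k = 1e-5, alpha_m = 0, n_elements = NULL) {
  stopifnot(inherits(model, "haltere_model"))
  if (!is.null(n_elements)) {
    model$n_elements <- as.integer(n_elements)
    model$nodes <- seq(0, model$x_d, length.out = model$n_elements + 1)
  }
  sec <- model$section
  mat <- model$material
  EA <- mat$E * sec$A * 1e-12
  EIy <- mat$E * sec$I_y * 1e-24
  EIz <- mat$E * sec$I_z * 1e-24
  GJ <- mat$G * sec$J * 1e-24
  rhoA <- mat$rho * sec$A * 1e-12
  rhoIp <- mat$rho * (sec$I_y + sec$I_z) * 1e-24
  nodes <- model$nodes
  nn <- length(nodes)
  ndof <- 6L * nn
  K <- matrix(0, ndof, ndof)
  M <- matrix(0, ndof, ndof)
  for (e in seq_len(nn - 1L)) {
    l <- nodes[e + 1L] - nodes[e]
    idx <- c(6L * (e - 1L) + 1:6, 6L * e + 1:6)
    K[idx, idx] <- K[idx, idx] + beam_element_k(EA, EIy, EIz, GJ, l)
    M[idx, idx] <- M[idx, idx] + beam_element_m(rhoA, rhoIp, l)
  }
  bp <- bulb_properties(model$bulb)
  it <- 6L * (nn - 1L) + 1:6
  M[it, it] <- M[it, it] + rigid_body_mass(bp$mass, bp$inertia, bp$com_offset)
  C <- alpha_k * K + alpha_m * M
  free <- 7:ndof  # base node fully clamped
  kf <- K[free, free]
  cond <- tryCatch(rcond(kf), error = function(e) 0)
  if (!is.finite(cond) || cond < 1e-16) {
    stop("assembled stiffness is singular after applying the base clamp")
  }
  sys <- list(M = M, C = C, K = K, free = free, nodes = nodes,
              alpha_k = alpha_k, alpha_m = alpha_m, model = model)
  class(sys) <- "beam_system"
  sys
}

#' @export
print.beam_system <- function(x, ...) {
  cat("<beam_system>", length(x$nodes), "nodes,", length(x$free),
      "free DOFs, alpha_k =", x$alpha_k, ", alpha_m =", x$alpha_m, "\n")
  invisible(x)
}

#' Static solution K u = f
#'
#' Solves the clamped static problem on the free DOFs; clamped DOFs are
#' returned as zeros.
#'
#' @param sys A [build_beam()] system.
#' @param load Full-length load vector (6 DOFs per node).
#' @return Displacement vector of the same length as `load`.
#' @export
static_solve <- function(sys, load) {
  stopifnot(inherits(sys, "beam_system"), length(load) == nrow(sys$K))
  u <- numeric(length(load))
  u[sys$free] <- solve(sys$K[sys$free, sys$free], load[sys$free])
  u
}

#' Natural frequencies of the clamped beam system
#'
#' Solves the generalised symmetric eigenproblem `K v = omega^2 M v` on the
#' free DOFs via a Cholesky reduction of the mass matrix.
#'
#' @param sys A [build_beam()] system.
#' @param n Number of frequencies to return.
#' @return Numeric vector of the first `n` natural frequencies (Hz),
#'   ascending.
#' @export
modal_frequencies <- function(sys, n = 6) {
  stopifnot(n >= 1)
  Mf <- sys$M[sys$free, sys$free]
  Kf <- sys$K[sys$free, sys$free]
  L <- t(chol(Mf))
  A <- forwardsolve(L, t(forwardsolve(L, Kf)))
  A <- (A + t(A)) / 2
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev <- sort(ev[ev > 0])
  sqrt(ev[seq_len(min(n, length(ev)))]) / (2 * pi)
}
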