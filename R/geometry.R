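#' Cross-section properties of an annular (hollow circular) stalk
#'
#' Computes area, bending second moments of area, Saint-Venant torsion
#' constant and outer fibre distance for a hollow circular cross-section.
#' All inputs and derived section properties are in micrometres
#' (\eqn{\mu m^2} for area, \eqn{\mu m^4} for moments); they are converted
#' to SI internally when a model is assembled.
#'
#' For a circular annulus the two bending moments are equal,
#' \eqn{I_y = I_z = \pi (r_{out}^4 - r_{in}^4)/4}, and the torsion constant
#' equals the polar moment, \eqn{J = 2 I}.
#'
#' @param r_out Outer radius (\eqn{\mu m}).
#' @param r_in Inner radius (\eqn{\mu m}); use 0 for a solid circle.
#' @return An object of class `haltere_section` with fields `kind`, `dims`,
#'   `A`, `I_y`, `I_z`, `J` and `c` (outer fibre distance).
#' @seealso [plus_section()], [match_second_moment()]
#' @examples
#' cs <- annulus_section(150, 50)
#' cs$I_y   # ~3.93e8 um^4
#' @export
annulus_section <- function(r_out, r_in) {
  stopifnot(is.numeric(r_out), is.numeric(r_in), length(r_out) == 1L, length(r_in) == 1L)
  if (!(r_out > r_in && r_in >= 0)) {
    stop("invalid annulus geometry: need r_out > r_in >= 0 (got r_out = ",
         r_out, ", r_in = ", r_in, ")")
  }
  I <- pi / 4 * (r_out^4 - r_in^4)
  sec <- list(
    kind = "annulus",
    dims = c(r_out = r_out, r_in = r_in),
    A = pi * (r_out^2 - r_in^2),
    I_y = I,
    I_z = I,
    J = 2 * I,
    c = r_out
  )
  class(sec) <- "haltere_section"
  sec
}

#' Cross-section properties of a plus-shaped (cruciform) stalk
#'
#' The plus-shaped section consists of two orthogonal rectangles of height
#' `h` and thickness `t` sharing a common centre. The central `t` by `t`
#' overlap is counted once in the area and bending moments. The torsion
#' constant uses the Saint-Venant thin-open-section result with the
#' aspect-ratio correction from the membrane analogy,
#' \deqn{J = 2\,k(h/t)\,h\,t^3, \quad
#'       k(a) = \tfrac{1}{3}\left(1 - 0.63/a + 0.052/a^5\right),}
#' which makes the open section torsionally compliant (`J` well below `I`)
#' while its bending stiffness matches a closed section of equal `I`.
#'
#' @param h Rectangle height (\eqn{\mu m}).
#' @param t Rectangle thickness (\eqn{\mu m}); must satisfy `h > t > 0`.
#' @return A `haltere_section` object (see [annulus_section()]).
#' @examples
#' ps <- plus_section(481, 40.8)
#' annulus_section(150, 50)$J / ps$J  # torsion-constant ratio ~38
#' @export
plus_section <- function(h, t) {
  stopifnot(is.numeric(h), is.numeric(t), length(h) == 1L, length(t) == 1L)
  if (!(h > t && t > 0)) {
    stop("invalid plus-section geometry: need h > t > 0 (got h = ", h,
         ", t = ", t, ")")
  }
  I <- t * h^3 / 12 + h * t^3 / 12 - t^4 / 12
  ar <- h / t
  k <- (1 - 0.63 / ar + 0.052 / ar^5) / 3
  sec <- list(
    kind = "plus",
    dims = c(h = h, t = t),
    A = 2 * h * t - t^2,
    I_y = I,
    I_z = I,
    J = 2 * k * h * t^3,
    c = h / 2
  )
  class(sec) <- "haltere_section"
  sec
}

#' @export
print.haltere_section <- function(x, ...) {
  cat("<haltere_section> kind:", x$kind, "\n")
  cat("  dims:", paste(names(x$dims), signif(x$dims, 6), sep = " = ", collapse = ", "), "um\n")
  cat(sprintf("  A = %.6g um^2, I_y = I_z = %.6g um^4, J = %.6g um^4, c = %.6g um\n",
              x$A, x$I_y, x$J, x$c))
  invisible(x)
}

#' Plus-section dimensions matching a target second moment of area
#'
#' Solves for the rectangle height `h` (with thickness `t = h/aspect_ratio`)
#' such that the plus-shaped section has the requested bending second moment
#' of area. At a fixed aspect ratio the second moment grows monotonically as
#' \eqn{h^4}, so the root is bracketed and found by `uniroot`.
#'
#' @param aspect_ratio Height-to-thickness ratio `h/t` (> 1).
#' @param target_I Target second moment of area (\eqn{\mu m^4}).
#' @return A list with elements `h`, `t` (\eqn{\mu m}) and the achieved
#'   `section`.
#' @export
match_second_moment <- function(aspect_ratio, target_I) {
  stopifnot(aspect_ratio > 1, target_I > 0)
  I_of_h <- function(h) plus_section(h, h / aspect_ratio)$I_y - target_I
  # I ~ h^4 / const: bracket generously around the thin-strip estimate
  h0 <- (12 * target_I * aspect_ratio / (aspect_ratio^2 + 1))^(1 / 4)
  lo <- h0 / 4
  hi <- h0 * 4
  if (I_of_h(lo) > 0 || I_of_h(hi) < 0) {
    stop("match_second_moment: no root in bracket [", signif(lo, 4), ", ",
         signif(hi, 4), "] um")
  }
  h <- stats::uniroot(I_of_h, c(lo, hi), tol = 1e-10 * h0)$root
  list(h = h, t = h / aspect_ratio, section = plus_section(h, h / aspect_ratio))
}

#' Semi-minor axis of an equal-volume prolate ellipsoid
#'
#' Given a sphere radius and the semi-major axis of a prolate spheroid
#' (two equal minor axes), returns the semi-minor axis `b` that conserves
#' volume: \eqn{a b^2 = r^3}.
#'
#' @param sphere_radius Radius of the reference sphere (\eqn{\mu m}).
#' @param semi_major Semi-major axis of the ellipsoid (\eqn{\mu m}).
#' @return Semi-minor axis (\eqn{\mu m}).
#' @examples
#' equal_volume_ellipsoid(500, 1000)  # ~353.6 um
#' @export
equal_volume_ellipsoid <- function(sphere_radius, semi_major) {
  stopifnot(sphere_radius > 0, semi_major > 0)
  sqrt(sphere_radius^3 / semi_major)
}

#' Rigid bulb specification
#'
#' Describes the rigid end-knob of the haltere: a sphere or ellipsoid of
#' uniform density, optionally with its centre of mass offset laterally
#' (along the local y' axis, out of the stroke plane) and/or vertically
#' (along z', within the stroke plane) from the stalk axis.
#'
#' The semi-axes are given along the local x' (spanwise), y' (lateral) and
#' z' (stroke-plane) directions, so a "vertical" ellipsoid has its long axis
#' along z' and a "horizontal" one along y'.
#'
#' @param shape `"sphere"` or `"ellipsoid"`.
#' @param radius Sphere radius (\eqn{\mu m}); used when `shape = "sphere"`.
#' @param semi_axes Numeric length-3 vector of semi-axes along (x', y', z')
#'   in \eqn{\mu m}; used when `shape = "ellipsoid"`.
#' @param offset Length-2 numeric vector `c(y, z)`: centre-of-mass offset in
#'   \eqn{\mu m} along y' and z'.
#' @param density Bulb density (kg m^-3).
#' @return Object of class `bulb_spec`.
#' @export
bulb_spec <- function(shape = c("sphere", "ellipsoid"), radius = 500,
                      semi_axes = NULL, offset = c(0, 0), density = 1200) {
  shape <- match.arg(shape)
  if (shape == "sphere") {
    semi_axes <- rep(radius, 3)
  } else {
    stopifnot(!is.null(semi_axes), length(semi_axes) == 3, all(semi_axes > 0))
  }
  stopifnot(length(offset) == 2, density > 0)
  spec <- list(shape = shape, semi_axes = as.numeric(semi_axes),
               offset = as.numeric(offset), density = density)
  class(spec) <- "bulb_spec"
  spec
}

#' Mass properties of a rigid bulb
#'
#' Returns the mass, centre-of-mass offset vector and inertia tensor about
#' the centre of mass for a [bulb_spec()]. The inertia of a uniform
#' ellipsoid with semi-axes \eqn{(a, b, c)} is diagonal in its principal
#' frame with \eqn{I_x = m(b^2 + c^2)/5} and cyclic permutations; a sphere
#' is the isotropic special case.
#'
#' @param spec A [bulb_spec()].
#' @return List with `mass` (kg), `com_offset` (length-3 vector, metres, in
#'   the local frame; zero x' component) and `inertia` (3x3 matrix, kg m^2,
#'   about the centre of mass, principal axes along x'y'z').
#' @export
bulb_properties <- function(spec) {
  stopifnot(inherits(spec, "bulb_spec"))
  ax <- spec$semi_axes * 1e-6  # m
  m <- 4 / 3 * pi * prod(ax) * spec$density
  I <- diag(m / 5 * c(ax[2]^2 + ax[3]^2, ax[1]^2 + ax[3]^2, ax[1]^2 + ax[2]^2))
  list(mass = m,
       com_offset = c(0, spec$offset[1], spec$offset[2]) * 1e-6,
       inertia = I)
}

#' Material constants of the haltere cuticle
#'
#' @param youngs_modulus Young's modulus E (Pa).
#' @param density Density (kg m^-3).
#' @param poisson Poisson ratio (dimensionless, in (0, 0.5)).
#' @return Object of class `material_spec` with derived shear modulus
#'   `G = E / (2 (1 + nu))`.
#' @export
material_spec <- function(youngs_modulus = 1.5e9, density = 1200, poisson = 0.33) {
  stopifnot(youngs_modulus > 0, density > 0, poisson > 0, poisson < 0.5)
  mat <- list(E = youngs_modulus, rho = density, nu = poisson,
              G = youngs_modulus / (2 * (1 + poisson)))
  class(mat) <- "material_spec"
  mat
}

#' Assemble a haltere model description
#'
#' Combines a stalk cross-section, material, rigid bulb and discretisation
#' into a model object. The stalk spans the local x' axis from the clamped
#' base at x' = 0 to the bulb centre of mass at `length` (the distance from
#' base to bulb centre); the bulb is attached rigidly at the distal node,
#' with any lateral centre-of-mass offset enforced through a rigid link.
#'
#' @param section A [annulus_section()] or [plus_section()].
#' @param material A [material_spec()].
#' @param bulb A [bulb_spec()].
#' @param length Distance from the base to the bulb centre of mass
#'   (\eqn{\mu m}).
#' @param n_elements Number of beam elements along the stalk (>= 4).
#' @return Object of class `haltere_model`. Node coordinates are stored in
#'   metres.
#' @export
haltere_model <- function(section, material = material_spec(),
                          bulb = bulb_spec("sphere"),
                          length = 5000, n_elements = 31) {
  stopifnot(inherits(section, "haltere_section"),
            inherits(material, "material_spec"),
            inherits(bulb, "bulb_spec"),
            length > 0, n_elements >= 4)
  model <- list(
    section = section,
    material = material,
    bulb = bulb,
    x_d = length * 1e-6,
    n_elements = as.integer(n_elements),
    nodes = seq(0, length * 1e-6, length.out = n_elements + 1)
  )
  class(model) <- "haltere_model"
  model
}

#' @export
print.haltere_model <- function(x, ...) {
  cat("<haltere_model>\n")
  cat("  stalk:", x$section$kind, "section, length", x$x_d * 1e6, "um,",
      x$n_elements, "elements\n")
  bp <- bulb_properties(x$bulb)
  cat(sprintf("  bulb: %s, mass %.4g kg, COM offset (y', z') = (%g, %g) um\n",
              x$bulb$shape, bp$mass, x$bulb$offset[1], x$bulb$offset[2]))
  cat(sprintf("  material: E = %.3g Pa, rho = %g kg/m^3, nu = %g\n",
              x$material$E, x$material$rho, x$material$nu))
  invisible(x)
}
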