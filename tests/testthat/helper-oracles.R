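# Independent numerical oracles for cross-section properties.

# Area and second moment (about the y axis through the centroid, i.e.
# integral of z^2 dA) by 2D quadrature over the section domain.
quad_annulus <- function(r_out, r_in) {
  A <- pracma::integral2(function(r, th) r + 0 * th,
                         r_in, r_out, 0, 2 * pi, reltol = 1e-10)$Q
  I <- pracma::integral2(function(r, th) (r * cos(th))^2 * r,
                         r_in, r_out, 0, 2 * pi, reltol = 1e-10)$Q
  list(A = A, I = I)
}

quad_plus <- function(h, t) {
  # union of a vertical rectangle (width t, height h) and a horizontal one
  # (width h, height t); the central t x t square counted once
  rect <- function(w, ht, f) {
    pracma::integral2(function(y, z) f(y, z), -w / 2, w / 2, -ht / 2, ht / 2,
                      reltol = 1e-10)$Q
  }
  one <- function(y, z) 1 + 0 * y
  zz <- function(y, z) z^2
  list(A = rect(t, h, one) + rect(h, t, one) - rect(t, t, one),
       I = rect(t, h, zz) + rect(h, t, zz) - rect(t, t, zz))
}

# Saint-Venant torsion constant by finite differences on the Prandtl
# stress function: lap(psi) = -2 inside the section, psi = 0 on the wall,
# J = 2 * integral(psi) dA. Cell-centred grid with ghost-cell mirroring
# (psi_ghost = -psi) so the Dirichlet condition sits exactly on walls that
# lie on cell edges; spacing is t/m so the arm walls are edge-aligned.
prandtl_J <- function(inside, half_y, half_z, hh) {
  gy <- seq(hh / 2, half_y, by = hh)
  gy <- c(-rev(gy), gy)
  gz <- seq(hh / 2, half_z, by = hh)
  gz <- c(-rev(gz), gz)
  ny <- length(gy)
  pts <- expand.grid(y = gy, z = gz)
  keep <- inside(pts$y, pts$z)
  idx <- integer(length(keep))
  idx[keep] <- seq_len(sum(keep))
  n <- sum(keep)
  p <- which(keep)
  iy <- ((p - 1L) %% ny) + 1L
  iz <- ((p - 1L) %/% ny) + 1L
  nz <- length(gz)
  missing <- integer(n)
  rows <- idx[p]; cols <- idx[p]
  nb_rows <- list(); nb_cols <- list()
  for (sh in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    jy <- iy + sh[1]; jz <- iz + sh[2]
    ok <- jy >= 1L & jy <= ny & jz >= 1L & jz <= nz
    q <- (jz - 1L) * ny + jy
    ok[ok] <- keep[q[ok]]
    missing <- missing + as.integer(!ok)
    nb_rows[[length(nb_rows) + 1L]] <- idx[p[ok]]
    nb_cols[[length(nb_cols) + 1L]] <- idx[q[ok]]
  }
  nb_i <- unlist(nb_rows)
  nb_j <- unlist(nb_cols)
  Amat <- Matrix::sparseMatrix(
    i = c(rows, nb_i), j = c(cols, nb_j),
    x = c(4 + missing, rep(-1, length(nb_i))), dims = c(n, n))
  psi <- as.numeric(Matrix::solve(Amat, rep(2 * hh^2, n)))
  2 * sum(psi) * hh^2
}

prandtl_J_plus <- function(h, t, m = 16) {
  hh <- t / m
  inside <- function(y, z) (abs(y) < t / 2 & abs(z) < h / 2) |
    (abs(z) < t / 2 & abs(y) < h / 2)
  prandtl_J(inside, h / 2, h / 2, hh)
}

# solid circle oracle (closed form pi r^4 / 2) used to validate the solver
prandtl_J_circle <- function(r, m = 40) {
  hh <- r / m
  inside <- function(y, z) y^2 + z^2 < r^2
  prandtl_J(inside, r, r, hh)
}
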