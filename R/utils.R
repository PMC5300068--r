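# Small geometric helpers shared across modules.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation of `angle` degrees
#' about the (not necessarily unit) axis vector.
#'
#' @param axis numeric length-3 axis vector.
#' @param angle rotation angle in degrees.
#' @return a 3x3 rotation matrix.
#' @keywords internal
#' @noRd
rotation_matrix <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) abort("rotation axis has zero length")
  u <- axis / n
  th <- angle * pi / 180
  ct <- cos(th); st <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) + st * K + (1 - ct) * (K %*% K)
}

# rotate rows of an n x 3 matrix about an axis through `origin`
rotate_about <- function(xyz, origin, axis, angle) {
  R <- rotation_matrix(axis, angle)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

# dihedral angle (degrees, in (-180, 180]) defined by four points
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  b2n <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / b2n
  atan2(y, x) * 180 / pi
}

# angle (degrees) at vertex v subtended by points a and b
vertex_angle <- function(a, v, b) {
  u <- a - v; w <- b - v
  cu <- sqrt(sum(u^2)); cw <- sqrt(sum(w^2))
  if (cu < 1e-12 || cw < 1e-12) abort("degenerate angle: coincident points")
  cosang <- sum(u * w) / (cu * cw)
  acos(max(-1, min(1, cosang))) * 180 / pi
}

# coordinates of a model/sphere tibble as an n x 3 matrix
coords_matrix <- function(df) {
  cbind(df$x, df$y, df$z)
}

# mass-unweighted radius of gyration of points (all equal weights)
points_rg <- function(xyz) {
  ctr <- colMeans(xyz)
  sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
}

# evenly distributed unit vectors on the sphere (deterministic golden
# spiral); used by the SASA integrator
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# derive a reproducible 31-bit sub-seed from a master seed and counter
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
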