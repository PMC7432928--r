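# Internal 3D geometry helpers shared by the template builders, the mutant
# modeller and the secondary-structure assignment.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' @noRd
# Place atom D given positions of A, B, C, the bond length |C-D|, the angle
# B-C-D (degrees) and the dihedral A-B-C-D (degrees).  Standard NeRF
# construction used for all internal-coordinate templates.
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  dih <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(dih),
          bond * sin(ang) * sin(dih))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Dihedral angle A-B-C-D in degrees, in (-180, 180].
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Kabsch superposition: rotation R and translation t minimizing
# || (x %*% R + t) - y ||, rows are points.  Returns the transform.
kabsch_fit <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3L)
  cx <- colMeans(x)
  cy <- colMeans(y)
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  s <- svd(t(xc) %*% yc)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(rotation = rot, center_x = cx, center_y = cy)
}

apply_kabsch <- function(coords, fit) {
  sweep(sweep(coords, 2, fit$center_x) %*% fit$rotation, 2, fit$center_y, "+")
}

# Rodrigues rotation of points (rows) about a unit axis through origin.
rotate_about_axis <- function(coords, axis, theta) {
  k <- unit(axis)
  ct <- cos(theta)
  st <- sin(theta)
  kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0),
               3, 3, byrow = TRUE)
  rot <- diag(3) * ct + st * kx + (1 - ct) * (k %o% k)
  coords %*% t(rot)
}

rmsd_coords <- function(a, b) sqrt(mean(rowSums((a - b)^2)))
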