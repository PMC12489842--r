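# Low-level vector geometry shared by the superposition and validation code.
# All coordinates are in Angstrom, all angles in degrees unless noted.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Angle at vertex b of the triple a-b-c, in degrees
#' @noRd
vec_angle <- function(a, b, c) {
  u <- unit(a - b)
  v <- unit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

#' Signed dihedral a-b-c-d in degrees, in (-180, 180]
#' @noRd
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation: returns the 3x3 matrix rotating by `angle_deg`
#' degrees about `axis` (right-hand rule).
#'
#' @param axis length-3 direction vector (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  k <- unit(axis)
  th <- deg2rad(angle_deg)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Place a new atom D from internal coordinates relative to placed atoms
#' A-B-C: bond |C-D|, angle B-C-D, torsion A-B-C-D (NeRF construction).
#' @noRd
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- deg2rad(180 - angle_deg)
  ph <- -deg2rad(torsion_deg)
  d2 <- c(bond * cos(th),
          bond * sin(th) * cos(ph),
          bond * sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(cross3(b - a, bc))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c)
}

#' Least-squares plane normal of a point set (rows = points).
#' Errors when the points are collinear.
#' @noRd
plane_normal <- function(xyz) {
  if (nrow(xyz) < 3) stop("need at least 3 points to define a plane", call. = FALSE)
  centered <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centered)
  if (sv$d[2] < 1e-6 * max(sv$d[1], 1e-12)) {
    stop("degenerate (collinear) point set: plane undefined", call. = FALSE)
  }
  sv$v[, 3]
}

#' Pairwise Euclidean distances between the rows of two coordinate matrices
#' @noRd
cross_dist <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  out <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) out <- out + outer(a[, k], b[, k], "-")^2
  sqrt(out)
}
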