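#' Wrap angles into (-180, 180]
#'
#' Circular difference helper used throughout: torsion residuals are wrapped
#' so that 359 and 1 degrees are 2 degrees apart, not 358.
#'
#' @param x Numeric vector of angles in degrees.
#' @return Angles wrapped into (-180, 180].
#' @export
wrap180 <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' @rdname wrap180
#' @export
wrap360 <- function(x) x %% 360

#' Circular Euclidean distance between two torsion vectors
#'
#' @param t1,t2 Numeric vectors of angles in degrees (same length).
#' @return Distance in degrees: sqrt of the sum of squared wrapped
#'   per-coordinate differences.
#' @export
torsion_distance <- function(t1, t2) {
  stopifnot(length(t1) == length(t2))
  sqrt(sum(wrap180(t1 - t2)^2))
}

#' Dihedral angle of four points
#'
#' Standard signed torsion about the p2-p3 axis, mapped to \[0, 360): the
#' cis arrangement gives 0 and trans gives 180.
#'
#' @param p1,p2,p3,p4 Numeric length-3 coordinate vectors (Angstrom).
#' @return Angle in degrees on \[0, 360).
#' @export
#' @examples
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))   # cis: 0
#' dihedral(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))  # trans: 180
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (sum(b2^2) == 0) stop("undefined dihedral: p2 and p3 coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sum(n1^2) < 1e-20 || sum(n2^2) < 1e-20)
    stop("undefined dihedral: collinear points")
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  # sign convention: clockwise looking from p2 to p3 is positive
  wrap360(-ang)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Bond angle of three points, in degrees
#' @param p1,p2,p3 Numeric length-3 coordinates; angle at p2.
#' @return Angle in degrees on \[0, 180\].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three placed atoms a, b, c, returns the position d such that
#' |cd| = `length`, the angle b-c-d equals `angle` and the dihedral
#' a-b-c-d equals `torsion` (same sign convention as [dihedral()]).
#'
#' @param a,b,c Numeric length-3 coordinates of the three reference atoms.
#' @param length Bond length c-d in Angstrom.
#' @param angle Bond angle b-c-d in degrees.
#' @param torsion Dihedral a-b-c-d in degrees.
#' @return Numeric length-3 coordinates of the new atom.
#' @export
place_atom <- function(a, b, c, length, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("place_atom: reference atoms are collinear")
  n <- n / nn
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(rot %*% d2 + c)
}

#' Rotate points about an axis
#'
#' Rodrigues rotation of `pts` (n x 3 matrix) about the axis through
#' `origin` with direction `axis`, by `angle` degrees.  Positive angles
#' follow the same handedness as [dihedral()]: rotating the fourth atom of
#' a dihedral by +x about the p2-p3 axis increases the dihedral by x.
#'
#' @param pts Matrix (n x 3) of coordinates.
#' @param origin,axis Length-3 numerics defining the rotation axis.
#' @param angle Rotation angle in degrees.
#' @return Rotated n x 3 matrix.
#' @export
rotate_about_axis <- function(pts, origin, axis, angle) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180  # sign matched to dihedral() convention
  p <- sweep(pts, 2, origin)
  kx <- cross_mat(k)
  rot <- diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
  sweep(p %*% t(rot), 2, origin, "+")
}

cross_mat <- function(k) {
  matrix(c(0, -k[3], k[2],
           k[3], 0, -k[1],
           -k[2], k[1], 0), 3, 3, byrow = TRUE)
}
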