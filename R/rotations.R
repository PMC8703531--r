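# Rotation helpers shared by the fitting module.

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 axis (need not be unit length).
#' @param angle rotation angle in radians.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c0 <- cos(angle); s0 <- sin(angle)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) * c0 + s0 * K + (1 - c0) * tcrossprod(u)
}

.quat_to_matrix <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Deterministic quasi-uniform rotation set
#'
#' Super-Fibonacci spiral on the rotation group: a deterministic low-
#' discrepancy sequence of unit quaternions, used as the global search grid
#' for rigid fitting. No randomness is involved.
#'
#' @param n number of rotations (>= 1).
#' @return List of `n` rotation matrices; the first is always the identity.
#' @export
rotation_grid <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(list(diag(3)))
  phi <- sqrt(2)
  psi <- 1.533751168755204288118041          # root of psi^4 = psi + 4
  out <- vector("list", n)
  out[[1]] <- diag(3)
  for (i in seq_len(n - 1)) {
    s <- i - 1 + 0.5
    t <- s / (n - 1)
    r <- sqrt(t); R <- sqrt(1 - t)
    a <- 2 * pi * s / phi
    b <- 2 * pi * s / psi
    out[[i + 1]] <- .quat_to_matrix(c(r * sin(a), r * cos(a),
                                      R * sin(b), R * cos(b)))
  }
  out
}

#' Geodesic distance between two rotations
#' @param R1,R2 3 x 3 rotation matrices.
#' @return Rotation angle of `R1^T R2` in degrees, in `[0, 180]`.
#' @export
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  tr <- sum(diag(crossprod(R1, R2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2))) * 180 / pi
}

#' Nominal angular spacing of a rotation grid
#'
#' The rotation angle `theta` such that the Haar-measure ball of radius
#' `theta` around each of `n` grid points tiles the rotation group once
#' (fraction of SO(3) within angle theta is `(theta - sin theta) / pi`),
#' doubled as a covering-radius allowance.
#'
#' @param n grid size.
#' @return Angular spacing in degrees.
#' @export
rotation_grid_spacing_deg <- function(n) {
  f <- function(th) (th - sin(th)) / pi - 1 / n
  th <- stats::uniroot(f, c(1e-6, pi))$root
  2 * th * 180 / pi
}
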