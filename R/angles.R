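#' Wrap angles into [-180, 180)
#'
#' All angular bookkeeping in the package is in degrees on the half-open
#' interval \eqn{[-180, 180)}, matching the Relion Euler-angle convention.
#'
#' @param x numeric vector of angles in degrees.
#' @return numeric vector of wrapped angles.
#' @export
wrap_angle <- function(x) {
  ((x + 180) %% 360) - 180
}

#' Circular distance between angles (degrees)
#'
#' @param a,b angles in degrees.
#' @return absolute circular distance in [0, 180].
#' @export
circular_distance <- function(a, b) {
  abs(wrap_angle(a - b))
}

#' Circular mean of angles (degrees)
#'
#' Mean direction of the unit vectors \code{(cos x, sin x)}; undefined input
#' (zero resultant) returns \code{NA}.
#'
#' @param x angles in degrees.
#' @return circular mean in [-180, 180).
#' @export
circular_mean <- function(x) {
  r <- x * pi / 180
  s <- mean(sin(r)); c <- mean(cos(r))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  wrap_angle(atan2(s, c) * 180 / pi)
}

#' Circular median of angles (degrees)
#'
#' The data value minimising the summed circular distance to all points.
#' Ties are broken toward the smaller wrapped angle, so the result is
#' deterministic.
#'
#' @param x angles in degrees.
#' @return circular median in [-180, 180).
#' @export
circular_median <- function(x) {
  stopifnot(length(x) >= 1)
  cand <- wrap_angle(x)
  cost <- vapply(cand, function(a) sum(circular_distance(a, cand)), numeric(1))
  best <- cand[cost <= min(cost) + 1e-12]
  min(best)
}

## --- rotation matrices (Relion ZYZ convention) -------------------------

rot_z <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), sin(r), 0, -sin(r), cos(r), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  r <- deg * pi / 180
  matrix(c(cos(r), 0, -sin(r), 0, 1, 0, sin(r), 0, cos(r)), 3, 3)
}

#' Euler angles (ZYZ, degrees) to rotation matrix
#'
#' Composition \code{Rz(psi) Ry(tilt) Rz(rot)}: the matrix that maps
#' reference-frame coordinates into the particle frame under the Relion
#' rot/tilt/psi parameterisation.
#'
#' @param rot,tilt,psi Euler angles in degrees.
#' @return 3x3 proper rotation matrix.
#' @export
euler_to_matrix <- function(rot, tilt, psi) {
  rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot)
}

#' Rotation matrix to Euler angles (ZYZ, degrees)
#'
#' Inverse of [euler_to_matrix()]. At the gimbal-lock poles
#' (\code{tilt} near 0 or 180) \code{rot} is fixed to 0 and the residual
#' in-plane rotation is absorbed into \code{psi}.
#'
#' @param m 3x3 rotation matrix.
#' @return named numeric vector \code{c(rot, tilt, psi)} in degrees.
#' @export
matrix_to_euler <- function(m) {
  ct <- max(-1, min(1, m[3, 3]))
  tilt <- acos(ct) * 180 / pi
  st <- sqrt(max(0, 1 - ct^2))
  if (st < 1e-9) {
    rot <- 0
    psi <- atan2(m[2, 1], m[1, 1]) * 180 / pi
    if (ct < 0) psi <- -psi  # Rz(psi) Ry(180) Rz(rot) = Rz(psi - rot) Ry(180)
  } else {
    rot <- atan2(m[3, 2], -m[3, 1]) * 180 / pi
    psi <- atan2(m[2, 3], m[1, 3]) * 180 / pi
  }
  c(rot = wrap_angle(rot), tilt = tilt, psi = wrap_angle(psi))
}

#' Rotation angle and axis of a rotation matrix
#'
#' Angle from the matrix trace, axis from the antisymmetric part (or from
#' the eigen decomposition near 180 degrees). For angles below \code{tol}
#' the axis is undefined and flagged.
#'
#' @param m 3x3 proper rotation matrix.
#' @param tol angle (degrees) below which the axis is reported undefined.
#' @return list with \code{angle} (degrees, in [0, 180]), \code{axis}
#'   (unit 3-vector or NA), \code{axis_defined} (logical).
#' @export
rotation_angle_axis <- function(m, tol = 1e-6) {
  v <- c(m[3, 2] - m[2, 3], m[1, 3] - m[3, 1], m[2, 1] - m[1, 2])
  s <- 0.5 * sqrt(sum(v^2))              # sin(angle)
  cth <- (sum(diag(m)) - 1) / 2          # cos(angle)
  angle <- atan2(s, cth) * 180 / pi      # well-conditioned at 0 and 180
  if (angle < tol) {
    return(list(angle = angle, axis = rep(NA_real_, 3), axis_defined = FALSE))
  }
  if (angle > 180 - 1e-4) {
    # axis = eigenvector of eigenvalue +1
    ev <- eigen(m)
    i <- which.min(abs(ev$values - 1))
    ax <- Re(ev$vectors[, i])
  } else {
    ax <- v
  }
  ax <- ax / sqrt(sum(ax^2))
  list(angle = angle, axis = ax, axis_defined = TRUE)
}
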