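# Minimal SO(3) toolkit. All rotations are 3x3 proper orthogonal matrices;
# rotation vectors are axis * angle in radians.

#' Standard gravity used throughout the package (m/s^2)
#' @keywords internal
GRAVITY <- 9.80665

skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

vnorm <- function(v) sqrt(sum(v^2))

unit3 <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps * 10) {
    fc_contract_error("cannot normalize a (near-)zero 3-vector")
  }
  v / n
}

#' Rotation matrix from a rotation vector (Rodrigues formula)
#'
#' Series expansion is used below 1e-8 rad so the map is smooth through the
#' identity.
#' @param v numeric length-3 rotation vector (axis * angle, rad).
#' @return 3x3 rotation matrix.
#' @keywords internal
rotvec_to_matrix <- function(v) {
  th <- vnorm(v)
  S <- skew3(v)
  if (th < 1e-8) {
    # sin(th)/th ~ 1 - th^2/6, (1-cos th)/th^2 ~ 1/2 - th^2/24
    diag(3) + S * (1 - th^2 / 6) + (S %*% S) * (0.5 - th^2 / 24)
  } else {
    diag(3) + S * (sin(th) / th) + (S %*% S) * ((1 - cos(th)) / th^2)
  }
}

#' Rotation vector (axis * angle) of a rotation matrix
#' @param R 3x3 rotation matrix.
#' @return numeric length-3 rotation vector, angle between 0 and pi.
#' @keywords internal
matrix_to_rotvec <- function(R) {
  w <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2
  s <- vnorm(w)                      # sin(theta)
  c_ <- (sum(diag(R)) - 1) / 2       # cos(theta)
  c_ <- min(1, max(-1, c_))
  th <- atan2(s, c_)
  if (th < 1e-8) return(w * (1 + th^2 / 6))
  if (th > pi - 1e-6) {
    # near pi the skew part vanishes; recover axis from the symmetric part
    B <- (R + diag(3)) / 2           # = aa^T + O(pi - th)
    ax <- sqrt(pmax(diag(B), 0))
    i <- which.max(ax)
    axis <- B[, i] / ax[i]
    axis <- unit3(axis)
    # fix sign using the largest component of w (may be ~0; sign free at pi)
    if (s > 1e-12 && sum(axis * w) < 0) axis <- -axis
    return(axis * th)
  }
  w * (th / s)
}

#' Angle of a rotation matrix in radians
#' @keywords internal
rotation_angle <- function(R) {
  c_ <- (sum(diag(R)) - 1) / 2
  acos(min(1, max(-1, c_)))
}

#' Nearest proper rotation to an arbitrary 3x3 matrix (polar projection)
#'
#' Orthogonal Procrustes solution: the rotation minimizing the Frobenius
#' distance to `M`.
#' @keywords internal
nearest_rotation <- function(M) {
  sv <- svd(M)
  d <- det(sv$u %*% t(sv$v))
  sv$u %*% diag(c(1, 1, sign(d))) %*% t(sv$v)
}

#' Minimal rotation taking unit vector `a` onto unit vector `b`
#'
#' Axis a x b, angle acos(a.b); identity when already aligned. Errors if the
#' vectors are anti-parallel (axis undefined) beyond 1e-9.
#' @keywords internal
rotation_between <- function(a, b) {
  a <- unit3(a); b <- unit3(b)
  ax <- c(a[2] * b[3] - a[3] * b[2],
          a[3] * b[1] - a[1] * b[3],
          a[1] * b[2] - a[2] * b[1])
  s <- vnorm(ax)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    fc_contract_error("rotation_between: vectors are anti-parallel, axis undefined")
  }
  rotvec_to_matrix(ax / s * atan2(s, c_))
}

is_rotation <- function(R, tol = 1e-6) {
  is.matrix(R) && all(dim(R) == c(3, 3)) &&
    abs(det(R) - 1) < tol &&
    max(abs(t(R) %*% R - diag(3))) < tol
}
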