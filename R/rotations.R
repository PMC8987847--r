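#' Rotation utilities
#'
#' Rotations are stored as 3x3 orthonormal matrices with det = +1 and
#' parameterized as axis-angle 3-vectors (Rodrigues) during optimization.
#' All public interfaces take degrees; these helpers work in radians.
#'
#' @name rotations
#' @keywords internal
NULL

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Skew-symmetric (cross-product) matrix of a 3-vector
#' @keywords internal
skew3 <- function(v) {
  matrix(c(0, v[3], -v[2],
           -v[3], 0, v[1],
           v[2], -v[1], 0), 3, 3)
}

#' Axis-angle to rotation matrix (Rodrigues)
#'
#' @param w axis-angle 3-vector (radians; direction = axis, norm = angle)
#' @return 3x3 rotation matrix
#' @export
rot_from_axis_angle <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) {
    K <- skew3(w)
    return(diag(3) + K + 0.5 * K %*% K)
  }
  K <- skew3(w / th)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation matrix to axis-angle 3-vector (radians)
#' @param R 3x3 rotation matrix
#' @export
axis_angle_from_rot <- function(R) {
  tr <- sum(diag(R))
  cth <- max(-1, min(1, (tr - 1) / 2))
  th <- acos(cth)
  if (th < 1e-10) {
    # first-order: R ~ I + [w]x
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (th > pi - 1e-6) {
    # near 180 deg: axis from the symmetric part
    A <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(A), 0))
    # fix signs from off-diagonals
    i <- which.max(axis)
    if (i == 1) {
      axis[2] <- A[1, 2] / axis[1]; axis[3] <- A[1, 3] / axis[1]
    } else if (i == 2) {
      axis[1] <- A[1, 2] / axis[2]; axis[3] <- A[2, 3] / axis[2]
    } else {
      axis[1] <- A[1, 3] / axis[3]; axis[2] <- A[2, 3] / axis[3]
    }
    axis <- axis / sqrt(sum(axis^2))
    return(axis * th)
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  v / (2 * sin(th)) * th
}

#' Rotation about the +Z axis
#' @param angle_rad angle in radians, right-handed about +Z
#' @export
rot_z <- function(angle_rad) {
  ca <- cos(angle_rad); sa <- sin(angle_rad)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

#' Project a near-rotation matrix onto SO(3)
#'
#' Nearest orthonormal matrix with positive determinant (via SVD); used to
#' re-orthonormalize after compounded optimizer updates.
#' @param R approximate rotation matrix
#' @export
orthonormalize <- function(R) {
  s <- svd(R)
  O <- s$u %*% t(s$v)
  if (det(O) < 0) {
    s$v[, 3] <- -s$v[, 3]
    O <- s$u %*% t(s$v)
  }
  O
}

#' Angle (degrees) of the relative rotation between two rotations
#' @param R1,R2 3x3 rotation matrices
#' @export
rotation_angle_deg <- function(R1, R2 = diag(3)) {
  Q <- R1 %*% t(R2)
  cth <- max(-1, min(1, (sum(diag(Q)) - 1) / 2))
  rad2deg(acos(cth))
}

#' Chordal mean of a list of rotations
#'
#' Averages rotation matrices element-wise and projects back onto SO(3);
#' adequate for tightly clustered rotations (per-step turntable increments).
#' @param Rs list of 3x3 rotation matrices
#' @keywords internal
mean_rotation <- function(Rs) {
  M <- Reduce(`+`, Rs) / length(Rs)
  orthonormalize(M)
}
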