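#' Rodrigues rotation vector to rotation matrix
#'
#' Axis-angle exponential map: the direction of `rvec` is the rotation axis
#' and its norm the angle in radians. Calibration files store rotations in
#' this form.
#'
#' @param rvec Length-3 numeric vector.
#' @return 3x3 rotation matrix.
#' @export
rodrigues_to_matrix <- function(rvec) {
  rvec <- as.numeric(rvec)
  stopifnot(length(rvec) == 3)
  theta <- sqrt(sum(rvec^2))
  K <- matrix(c(0, -rvec[3], rvec[2],
                rvec[3], 0, -rvec[1],
                -rvec[2], rvec[1], 0), nrow = 3, byrow = TRUE)
  if (theta < 1e-12) {
    # second-order expansion keeps the map smooth through the identity
    return(diag(3) + K + 0.5 * (K %*% K))
  }
  diag(3) + sin(theta) / theta * K + (1 - cos(theta)) / theta^2 * (K %*% K)
}

#' Rotation matrix to Rodrigues vector
#'
#' Inverse of [rodrigues_to_matrix()]; the returned angle lies in `[0, pi]`.
#'
#' @param R 3x3 rotation matrix.
#' @return Length-3 numeric Rodrigues vector.
#' @export
matrix_to_rodrigues <- function(R) {
  R <- as.matrix(R)
  stopifnot(all(dim(R) == c(3, 3)))
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  theta <- acos(ct)
  if (theta < 1e-12) {
    # antisymmetric part gives the axis*angle directly near the identity
    return(0.5 * c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]))
  }
  if (pi - theta < 1e-6) {
    # near pi the antisymmetric part vanishes; recover axis from R + I
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs using the largest component
    i <- which.max(axis)
    if (axis[i] > 0) {
      s <- sign(B[i, ]) ; s[s == 0] <- 1
      axis <- abs(axis) * s
      axis[i] <- abs(axis[i])
    }
    axis <- axis / sqrt(sum(axis^2))
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
    (2 * sin(theta))
  axis * theta
}

#' Rotation matrix about a unit axis
#' @param axis Length-3 axis (normalized internally).
#' @param angle Angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n == 0) stop("axis must be non-zero")
  rodrigues_to_matrix(axis / n * angle)
}

#' Nearest rotation matrix (orthonormal projection)
#' @param M Approximate 3x3 rotation.
#' @return Orthonormal matrix with determinant +1 closest to `M` in Frobenius
#'   norm.
#' @keywords internal
nearest_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
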