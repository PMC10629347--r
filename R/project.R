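# Pinhole projection and distortion-map inversion.

# Apply the radial-tangential distortion polynomial to normalized image
# coordinates. x, y are equal-length numeric vectors; d = (k1,k2,p1,p2,k3).
distort_normalized <- function(x, y, d) {
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  cbind(xd, yd, deparse.level = 0)
}

#' Project world points into a camera
#'
#' Applies the world-to-camera rigid transform, perspective division,
#' radial-tangential distortion, and the intrinsic mapping. Points must have
#' positive depth in the camera frame.
#'
#' @param cam A `camera`.
#' @param points_world Numeric matrix (n x 3) or length-3 vector, mm.
#' @param on_behind What to do with non-positive depth: `"error"` aborts,
#'   `"na"` returns NA pixels for those rows.
#' @return n x 2 matrix of pixel coordinates (u, v); a length-2 vector when a
#'   single point was supplied.
#' @export
project <- function(cam, points_world, on_behind = c("error", "na")) {
  on_behind <- match.arg(on_behind)
  single <- is.null(dim(points_world))
  X <- if (single) matrix(as.numeric(points_world), nrow = 1) else
    as.matrix(points_world)
  stopifnot(ncol(X) == 3)
  Xc <- X %*% t(cam$pose$rotation) +
    matrix(cam$pose$translation, nrow(X), 3, byrow = TRUE)
  z <- Xc[, 3]
  behind <- z <= 0
  if (any(behind) && on_behind == "error") {
    stop("point(s) behind camera ", cam$camera_id, " (non-positive depth)")
  }
  z[behind] <- NA_real_
  x <- Xc[, 1] / z
  y <- Xc[, 2] / z
  intr <- cam$intrinsics
  dn <- distort_normalized(x, y, intr$distortion)
  u <- intr$focal_u * dn[, 1] + intr$skew * dn[, 2] + intr$principal_u
  v <- intr$focal_v * dn[, 2] + intr$principal_v
  uv <- cbind(u = u, v = v)
  if (single) drop(uv) else uv
}

#' Undistort pixels to normalized image coordinates
#'
#' Inverts the intrinsic mapping and the distortion polynomial by fixed-point
#' iteration. For distortion magnitudes typical of machine-vision lenses the
#' round trip distort(undistort(p)) returns p to better than 1e-8 px within
#' the unit normalized disc.
#'
#' @param intr A `camera_intrinsics`.
#' @param pixels n x 2 matrix or length-2 vector of (u, v) pixels.
#' @param max_iter Iteration cap.
#' @param tol Convergence tolerance in normalized coordinates.
#' @return n x 2 matrix of normalized (x, y); a length-2 vector for a single
#'   input pixel.
#' @export
undistort <- function(intr, pixels, max_iter = 200, tol = 1e-14) {
  single <- is.null(dim(pixels))
  P <- if (single) matrix(as.numeric(pixels), nrow = 1) else as.matrix(pixels)
  stopifnot(ncol(P) == 2)
  d <- intr$distortion
  yd <- (P[, 2] - intr$principal_v) / intr$focal_v
  xd <- (P[, 1] - intr$principal_u - intr$skew * yd) / intr$focal_u
  x <- xd
  y <- yd
  if (any(d != 0)) {
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      r2 <- x^2 + y^2
      radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
      dx <- 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
      dy <- d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
      xn <- (xd - dx) / radial
      yn <- (yd - dy) / radial
      delta <- max(abs(xn - x), abs(yn - y))
      x <- xn
      y <- yn
      if (delta < tol) { converged <- TRUE; break }
    }
    if (!converged) {
      # verify via the forward map before giving up: loose fixed points are
      # acceptable if the round trip already closes
      fwd <- distort_normalized(x, y, d)
      if (max(abs(fwd[, 1] - xd), abs(fwd[, 2] - yd)) > 1e-10) {
        stop("undistort did not converge within ", max_iter, " iterations")
      }
    }
  }
  xy <- cbind(x = x, y = y)
  if (single) drop(xy) else xy
}
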