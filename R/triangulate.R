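# Multi-view triangulation: linear DLT on undistorted rays, optional
# Gauss-Newton reprojection refinement.

point3d_estimate <- function(coordinates = c(NA_real_, NA_real_, NA_real_),
                             n_cameras_used = 0L, reprojection_rms = NA_real_,
                             valid = FALSE) {
  structure(list(coordinates = as.numeric(coordinates),
                 n_cameras_used = as.integer(n_cameras_used),
                 reprojection_rms = reprojection_rms, valid = valid),
            class = "point3d_estimate")
}

# Reprojection residual vector (px) of world point X over a list of cameras
# with observed pixels uv (n x 2).
reprojection_residuals <- function(cameras, uv, X) {
  res <- numeric(2 * length(cameras))
  for (i in seq_along(cameras)) {
    p <- project(cameras[[i]], X, on_behind = "na")
    res[2 * i - 1] <- p[1] - uv[i, 1]
    res[2 * i] <- p[2] - uv[i, 2]
  }
  res
}

# Residuals and analytic Jacobian of the pixel reprojection of world point X
# in one camera. Returns NULL when the point is behind the camera.
project_point_jacobian <- function(cam, X) {
  R <- cam$pose$rotation
  Xc <- drop(R %*% X + cam$pose$translation)
  z <- Xc[3]
  if (z <= 0) return(NULL)
  x <- Xc[1] / z
  y <- Xc[2] / z
  d <- cam$intrinsics$distortion
  r2 <- x^2 + y^2
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  dradial <- d[1] + 2 * d[2] * r2 + 3 * d[5] * r2^2
  xd <- x * radial + 2 * d[3] * x * y + d[4] * (r2 + 2 * x^2)
  yd <- y * radial + d[3] * (r2 + 2 * y^2) + 2 * d[4] * x * y
  dxd_dx <- radial + 2 * x^2 * dradial + 2 * d[3] * y + 6 * d[4] * x
  dxd_dy <- 2 * x * y * dradial + 2 * d[3] * x + 2 * d[4] * y
  dyd_dx <- 2 * x * y * dradial + 2 * d[3] * x + 2 * d[4] * y
  dyd_dy <- radial + 2 * y^2 * dradial + 6 * d[3] * y + 2 * d[4] * x
  intr <- cam$intrinsics
  u <- intr$focal_u * xd + intr$skew * yd + intr$principal_u
  v <- intr$focal_v * yd + intr$principal_v
  # d(x, y)/dXc, then chain through R
  dx_dXc <- c(1 / z, 0, -x / z)
  dy_dXc <- c(0, 1 / z, -y / z)
  du_dXc <- intr$focal_u * (dxd_dx * dx_dXc + dxd_dy * dy_dXc) +
    intr$skew * (dyd_dx * dx_dXc + dyd_dy * dy_dXc)
  dv_dXc <- intr$focal_v * (dyd_dx * dx_dXc + dyd_dy * dy_dXc)
  list(uv = c(u, v), J = rbind(du_dXc, dv_dXc) %*% R)
}

refine_point <- function(cameras, uv, X0, max_iter = 15, tol = 1e-14) {
  n <- length(cameras)
  X <- X0
  eval_at <- function(P) {
    r <- numeric(2 * n)
    J <- matrix(0, 2 * n, 3)
    for (i in seq_len(n)) {
      pj <- project_point_jacobian(cameras[[i]], P)
      if (is.null(pj)) return(NULL)
      r[(2 * i - 1):(2 * i)] <- pj$uv - uv[i, ]
      J[(2 * i - 1):(2 * i), ] <- pj$J
    }
    list(r = r, J = J)
  }
  cur <- eval_at(X)
  if (is.null(cur)) return(list(X = X0, rms = NA_real_))
  cost <- sum(cur$r^2)
  for (iter in seq_len(max_iter)) {
    step <- tryCatch(
      solve(crossprod(cur$J) + 1e-12 * diag(3), -crossprod(cur$J, cur$r)),
      error = function(e) NULL)
    if (is.null(step)) break
    # backtracking: accept only improving steps so refinement never worsens DLT
    lambda <- 1
    improved <- FALSE
    for (bt in 1:10) {
      nxt <- eval_at(X + lambda * drop(step))
      if (!is.null(nxt) && sum(nxt$r^2) < cost) {
        rel <- (cost - sum(nxt$r^2)) / max(cost, 1e-300)
        X <- X + lambda * drop(step)
        cur <- nxt
        cost <- sum(nxt$r^2)
        improved <- TRUE
        if (rel < tol) iter <- max_iter
        break
      }
      lambda <- lambda / 2
    }
    if (!improved || cost < 1e-26) break
  }
  list(X = X, rms = sqrt(cost / n))
}

#' Triangulate a 3D point from calibrated views
#'
#' Linear least-squares intersection (homogeneous DLT) of the undistorted
#' viewing rays, optionally polished by Gauss-Newton minimisation of the
#' total squared pixel reprojection error. With fewer than two observations
#' the estimate is returned invalid rather than raising an error, so per-frame
#' dropout can be handled gracefully by callers.
#'
#' @param cameras List of `camera` objects.
#' @param observations n x 2 matrix of observed pixels, one row per camera.
#' @param refine Run the nonlinear reprojection refinement (default TRUE).
#' @return A `point3d_estimate`: coordinates (mm), number of cameras used,
#'   reprojection RMS (px), validity flag.
#' @export
triangulate <- function(cameras, observations, refine = TRUE) {
  if (is.null(dim(observations))) {
    observations <- matrix(as.numeric(observations), ncol = 2, byrow = TRUE)
  }
  n <- length(cameras)
  stopifnot(nrow(observations) == n)
  if (n < 2) return(point3d_estimate())

  A <- matrix(0, 2 * n, 4)
  for (i in seq_len(n)) {
    cam <- cameras[[i]]
    xy <- undistort(cam$intrinsics, observations[i, ])
    P <- cbind(cam$pose$rotation, cam$pose$translation)
    A[2 * i - 1, ] <- xy[1] * P[3, ] - P[1, ]
    A[2 * i, ] <- xy[2] * P[3, ] - P[2, ]
  }
  s <- svd(A)
  if (s$d[3] < 1e-10 * s$d[1]) {
    stop("degenerate triangulation geometry (parallel rays or coincident centres)")
  }
  Xh <- s$v[, 4]
  if (abs(Xh[4]) < 1e-14 * max(abs(Xh))) {
    stop("triangulated point at infinity (degenerate geometry)")
  }
  X <- Xh[1:3] / Xh[4]
  r <- reprojection_residuals(cameras, observations, X)
  rms <- if (anyNA(r)) NA_real_ else sqrt(sum(r^2) / n)
  if (refine && !anyNA(r)) {
    ref <- refine_point(cameras, observations, X)
    if (!is.na(ref$rms) && (is.na(rms) || ref$rms <= rms)) {
      X <- ref$X; rms <- ref$rms
    }
  }
  point3d_estimate(X, n, rms, valid = TRUE)
}

#' Triangulate a detection table into a 3D keypoint series
#'
#' For each frame and keypoint, collects the usable detections (not missing,
#' confidence at or above the threshold, camera within the requested subset)
#' and triangulates when at least `min_views` views remain; otherwise the
#' frame/keypoint is marked invalid.
#'
#' @param rig A `rig_calibration`.
#' @param detections A detection data frame (see [detection_set()]).
#' @param subset Character vector of camera ids to use; default all.
#' @param min_views Minimum usable views per estimate (default 2).
#' @param confidence_threshold Detections below this confidence are ignored
#'   (default 0.5).
#' @param refine Nonlinear reprojection refinement (default TRUE).
#' @return A `pose3d_series` data frame: frame, keypoint, x, y, z (mm),
#'   n_cameras_used, reprojection_rms (px), valid.
#' @export
triangulate_series <- function(rig, detections, subset = NULL, min_views = 2,
                               confidence_threshold = 0.5, refine = TRUE) {
  ids <- rig_camera_ids(rig)
  if (is.null(subset)) subset <- ids
  unknown <- setdiff(subset, ids)
  if (length(unknown)) {
    stop("unknown camera id(s) in subset: ", paste(unknown, collapse = ", "))
  }
  det <- detections[!detections$missing &
                      detections$confidence >= confidence_threshold &
                      detections$camera_id %in% subset, , drop = FALSE]
  frames <- sort(unique(detections$frame))
  keypoints <- unique(detections$keypoint)
  cams <- rig$cameras

  key <- paste(det$frame, det$keypoint, sep = "\r")
  groups <- split(seq_len(nrow(det)), key)

  n_out <- length(frames) * length(keypoints)
  out <- data.frame(
    frame = rep(frames, each = length(keypoints)),
    keypoint = rep(keypoints, times = length(frames)),
    x = NA_real_, y = NA_real_, z = NA_real_,
    n_cameras_used = 0L, reprojection_rms = NA_real_, valid = FALSE,
    stringsAsFactors = FALSE
  )
  rowkey <- paste(out$frame, out$keypoint, sep = "\r")
  idx <- match(names(groups), rowkey)
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    if (length(rows) < min_views) next
    o <- idx[g]
    est <- triangulate(cams[det$camera_id[rows]],
                       cbind(det$u[rows], det$v[rows]), refine = refine)
    if (est$valid) {
      out$x[o] <- est$coordinates[1]
      out$y[o] <- est$coordinates[2]
      out$z[o] <- est$coordinates[3]
      out$n_cameras_used[o] <- est$n_cameras_used
      out$reprojection_rms[o] <- est$reprojection_rms
      out$valid[o] <- TRUE
    }
  }
  class(out) <- c("pose3d_series", "data.frame")
  out
}
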