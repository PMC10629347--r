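# Camera resectioning (DLT + decomposition) and rig refinement.

# Gauss-Newton over a 6-parameter pose (Rodrigues vector + translation),
# minimising squared pixel reprojection error with intrinsics held fixed.
refine_pose <- function(intr, X, uv, R0, t0, max_iter = 60, tol = 1e-12) {
  theta <- c(matrix_to_rodrigues(R0), t0)
  cam_of <- function(th) {
    camera("tmp", intr, camera_pose(rodrigues_to_matrix(th[1:3]), th[4:6]))
  }
  resid <- function(th) {
    p <- project(cam_of(th), X, on_behind = "na")
    as.numeric(t(p - uv))
  }
  r <- resid(theta)
  if (anyNA(r)) return(list(rotation = R0, translation = t0,
                            rms = NA_real_, diverged = TRUE))
  cost <- sum(r^2)
  diverged <- FALSE
  for (iter in seq_len(max_iter)) {
    J <- matrix(0, length(r), 6)
    for (k in 1:6) {
      h <- 1e-6 * max(1, abs(theta[k]))
      e <- numeric(6); e[k] <- h
      J[, k] <- (resid(theta + e) - resid(theta - e)) / (2 * h)
    }
    if (anyNA(J)) { diverged <- TRUE; break }
    step <- tryCatch(solve(crossprod(J) + 1e-12 * diag(6), -crossprod(J, r)),
                     error = function(e) NULL)
    if (is.null(step)) { diverged <- TRUE; break }
    lambda <- 1
    improved <- FALSE
    for (bt in 1:15) {
      thn <- theta + lambda * drop(step)
      rn <- resid(thn)
      if (!anyNA(rn) && sum(rn^2) < cost) {
        rel <- (cost - sum(rn^2)) / max(cost, 1e-300)
        theta <- thn; r <- rn; cost <- sum(rn^2)
        improved <- TRUE
        if (rel < tol) iter <- max_iter  # converged
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    if (cost < 1e-28) break
  }
  list(rotation = rodrigues_to_matrix(theta[1:3]), translation = theta[4:6],
       rms = sqrt(cost / nrow(uv)), diverged = diverged)
}

#' Resect a camera from 3D-2D correspondences
#'
#' Estimates a camera from known world points and their pixel observations by
#' direct linear transform. With known intrinsics only the pose is solved
#' (pixels are undistorted first, then the normalized-coordinate DLT pose is
#' polished by reprojection Gauss-Newton). Without intrinsics the full 3x4
#' projection matrix is estimated and decomposed (RQ) into intrinsics and
#' pose; distortion is taken as zero at this stage.
#'
#' @param points_world n x 3 matrix of world points, mm (n >= 6, not all
#'   coplanar).
#' @param pixels n x 2 matrix of observed pixels.
#' @param intrinsics_known Optional `camera_intrinsics`; when given, only the
#'   pose is estimated.
#' @param camera_id Id for the returned camera.
#' @param image_size Length-2 (width, height) used when intrinsics are
#'   estimated; defaults to twice the recovered principal point.
#' @return A `camera` with attribute `"reprojection_rms"` (px).
#' @export
resect <- function(points_world, pixels, intrinsics_known = NULL,
                   camera_id = "resected", image_size = NULL) {
  X <- as.matrix(points_world)
  uv <- as.matrix(pixels)
  stopifnot(ncol(X) == 3, ncol(uv) == 2, nrow(X) == nrow(uv))
  n <- nrow(X)
  if (n < 6) stop("resection needs at least 6 correspondences")
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  if (sv[3] < 1e-8 * sv[1]) {
    stop("degenerate correspondences: points are (nearly) coplanar")
  }

  if (!is.null(intrinsics_known)) {
    xy <- undistort(intrinsics_known, uv)
    P <- dlt_projection(X, xy)
    dec <- pose_from_normalized_P(P, X)
    ref <- refine_pose(intrinsics_known, X, uv, dec$rotation, dec$translation)
    cam <- camera(camera_id, intrinsics_known,
                  camera_pose(ref$rotation, ref$translation))
    attr(cam, "reprojection_rms") <- ref$rms
    return(cam)
  }

  P <- dlt_projection(X, uv)
  # make sure points are in front: w = P[3,] . (X,1) must be positive
  w <- X %*% P[3, 1:3] + P[3, 4]
  if (mean(w > 0) < 0.5) P <- -P
  M <- P[, 1:3]
  kr <- rq3(M)
  K <- kr$K / kr$K[3, 3]
  R <- kr$R
  # with the cheirality sign fixed above and K's diagonal positive, det(R) = +1
  if (det(R) < 0) stop("resection produced an improper rotation; degenerate input")
  t <- drop(solve(K, P[, 4]))
  if (is.null(image_size)) image_size <- 2 * c(K[1, 3], K[2, 3])
  intr <- camera_intrinsics(focal_u = K[1, 1], focal_v = K[2, 2],
                            principal_u = K[1, 3], principal_v = K[2, 3],
                            skew = K[1, 2],
                            image_width = image_size[1],
                            image_height = image_size[2])
  R <- nearest_rotation(R)
  ref <- refine_pose(intr, X, uv, R, t)
  cam <- camera(camera_id, intr, camera_pose(ref$rotation, ref$translation))
  attr(cam, "reprojection_rms") <- ref$rms
  cam
}

# Homogeneous DLT estimate of a 3x4 projection matrix mapping world points to
# (possibly normalized) image coordinates. Inputs are Hartley-normalized for
# conditioning.
dlt_projection <- function(X, xy) {
  n <- nrow(X)
  # condition: zero-mean, unit-RMS scaling on both sides
  cX <- colMeans(X); sX <- sqrt(mean(rowSums(sweep(X, 2, cX)^2)) / 3)
  cx <- colMeans(xy); sx <- sqrt(mean(rowSums(sweep(xy, 2, cx)^2)) / 2)
  if (sX == 0 || sx == 0) stop("degenerate correspondences")
  Xn <- sweep(X, 2, cX) / sX
  xn <- sweep(xy, 2, cx) / sx
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    Xi <- c(Xn[i, ], 1)
    A[2 * i - 1, ] <- c(Xi, rep(0, 4), -xn[i, 1] * Xi)
    A[2 * i, ] <- c(rep(0, 4), Xi, -xn[i, 2] * Xi)
  }
  p <- svd(A)$v[, 12]
  Pn <- matrix(p, 3, 4, byrow = TRUE)
  # undo conditioning: P = T_img^-1 Pn T_world
  Timg <- matrix(c(sx, 0, cx[1], 0, sx, cx[2], 0, 0, 1), 3, byrow = TRUE)
  Twrl <- rbind(cbind(diag(3) / sX, -cX / sX), c(0, 0, 0, 1))
  P <- Timg %*% Pn %*% Twrl
  P / sqrt(sum(P[3, 1:3]^2))
}

# Extract a rigid pose from a normalized-coordinate projection matrix [R|t]
# (up to scale/sign); sign fixed so points lie in front of the camera.
pose_from_normalized_P <- function(P, X) {
  w <- X %*% P[3, 1:3] + P[3, 4]
  if (mean(w > 0) < 0.5) P <- -P
  R <- nearest_rotation(P[, 1:3])
  scale <- sum(diag(crossprod(R, P[, 1:3]))) / 3
  list(rotation = R, translation = P[, 4] / scale)
}

# RQ decomposition of a 3x3 matrix: M = K R with K upper triangular
# (positive diagonal) and R orthonormal.
rq3 <- function(M) {
  # reverse rows, QR-decompose the transpose, reverse back
  Pm <- diag(3)[3:1, ]
  qr_ <- qr(t(Pm %*% M))
  Q <- qr.Q(qr_)
  Rt <- qr.R(qr_)
  K <- Pm %*% t(Rt) %*% Pm
  R <- Pm %*% t(Q)
  # force positive diagonal on K
  D <- diag(sign(diag(K)))
  K <- K %*% D
  R <- D %*% R
  list(K = K, R = R)
}

#' Refine a rig's extrinsics against per-camera correspondences
#'
#' Bundle-adjustment-style polish: each camera's pose is refined by
#' Gauss-Newton on its own 3D-2D correspondences (world points fixed, so
#' cameras decouple). The total squared reprojection error over the rig never
#' increases; refinement stops at an iteration cap or when the relative
#' improvement falls below `tol`.
#'
#' @param rig A `rig_calibration`.
#' @param correspondences Named list (by camera id) of lists with elements
#'   `points_world` (n x 3) and `pixels` (n x 2), n >= 6 each.
#' @param tol Relative improvement threshold (default 1e-10).
#' @return A `rig_calibration` with attributes `"initial_error"`,
#'   `"final_error"` (total squared px error) and `"warning_flag"` (TRUE when
#'   any camera's refinement step diverged and its best-so-far pose was kept).
#' @export
refine_rig <- function(rig, correspondences, tol = 1e-10) {
  ids <- rig_camera_ids(rig)
  missing_ids <- setdiff(ids, names(correspondences))
  if (length(missing_ids)) {
    stop("no correspondences for camera(s): ", paste(missing_ids, collapse = ", "))
  }
  total0 <- 0
  total1 <- 0
  warn <- FALSE
  cams <- rig$cameras
  for (id in ids) {
    co <- correspondences[[id]]
    X <- as.matrix(co$points_world)
    uv <- as.matrix(co$pixels)
    if (nrow(X) < 6) stop("camera ", id, " has fewer than 6 correspondences")
    cam <- cams[[id]]
    p0 <- project(cam, X, on_behind = "na")
    e0 <- sum((p0 - uv)^2)
    ref <- refine_pose(cam$intrinsics, X, uv, cam$pose$rotation,
                       cam$pose$translation, tol = tol)
    e1 <- nrow(uv) * ref$rms^2
    if (is.na(e1) || e1 > e0) {
      # keep the original pose if the step failed to improve
      e1 <- e0
      warn <- warn || ref$diverged
    } else {
      cams[[id]] <- camera(id, cam$intrinsics,
                           camera_pose(ref$rotation, ref$translation))
      warn <- warn || ref$diverged
    }
    total0 <- total0 + e0
    total1 <- total1 + e1
  }
  out <- rig_calibration(cams)
  attr(out, "initial_error") <- total0
  attr(out, "final_error") <- total1
  attr(out, "warning_flag") <- warn
  out
}
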