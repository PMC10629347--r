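#' Camera intrinsics
#'
#' Internal parameters of a pinhole camera with a 5-coefficient
#' radial-tangential distortion model (k1, k2, p1, p2, k3), the model used by
#' OpenCV and Anipose. Focal lengths and principal point are in pixels; the
#' image origin is the top-left corner with v increasing downwards.
#'
#' @param focal_u,focal_v Focal length in pixels along u and v.
#' @param principal_u,principal_v Principal point in pixels.
#' @param skew Skew coefficient (almost always 0 for machine-vision sensors).
#' @param distortion Numeric 5-vector `(k1, k2, p1, p2, k3)`.
#' @param image_width,image_height Sensor size in pixels.
#' @return An object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(focal_u, focal_v = focal_u,
                              principal_u, principal_v,
                              skew = 0,
                              distortion = c(0, 0, 0, 0, 0),
                              image_width, image_height) {
  stopifnot(focal_u > 0, focal_v > 0, image_width > 0, image_height > 0)
  distortion <- as.numeric(distortion)
  if (length(distortion) != 5) {
    stop("`distortion` must be a 5-vector (k1, k2, p1, p2, k3)")
  }
  structure(list(
    focal_u = as.numeric(focal_u), focal_v = as.numeric(focal_v),
    principal_u = as.numeric(principal_u), principal_v = as.numeric(principal_v),
    skew = as.numeric(skew), distortion = distortion,
    image_width = as.numeric(image_width), image_height = as.numeric(image_height)
  ), class = "camera_intrinsics")
}

#' Intrinsic matrix of a camera
#' @param intr A `camera_intrinsics` object.
#' @return 3x3 upper-triangular intrinsic matrix K.
#' @export
intrinsic_matrix <- function(intr) {
  matrix(c(intr$focal_u, intr$skew, intr$principal_u,
           0, intr$focal_v, intr$principal_v,
           0, 0, 1), nrow = 3, byrow = TRUE)
}

#' Camera pose (extrinsics)
#'
#' World-to-camera rigid transform: `X_cam = R %*% X_world + t`. The rotation
#' must be orthonormal with determinant +1.
#'
#' @param rotation 3x3 rotation matrix (world to camera).
#' @param translation Length-3 translation vector, mm.
#' @param tol Orthonormality tolerance.
#' @return An object of class `camera_pose`.
#' @export
camera_pose <- function(rotation, translation, tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > tol || abs(det(rotation) - 1) > tol) {
    stop("`rotation` must be orthonormal with determinant +1")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "camera_pose")
}

#' A calibrated camera
#' @param camera_id Character id, unique within a rig.
#' @param intrinsics A `camera_intrinsics`.
#' @param pose A `camera_pose`.
#' @return An object of class `camera`.
#' @export
camera <- function(camera_id, intrinsics, pose) {
  stopifnot(is.character(camera_id), length(camera_id) == 1,
            inherits(intrinsics, "camera_intrinsics"),
            inherits(pose, "camera_pose"))
  structure(list(camera_id = camera_id, intrinsics = intrinsics, pose = pose),
            class = "camera")
}

#' Optical centre of a camera in world coordinates
#' @param cam A `camera`.
#' @return Length-3 numeric vector, mm.
#' @export
camera_center <- function(cam) {
  -drop(crossprod(cam$pose$rotation, cam$pose$translation))
}

#' A calibrated multi-camera rig
#'
#' Ordered collection of calibrated cameras sharing one world frame. All 3D
#' quantities are in millimetres.
#'
#' @param cameras List of `camera` objects (at least 2, unique ids, distinct
#'   optical centres).
#' @return An object of class `rig_calibration`.
#' @export
rig_calibration <- function(cameras) {
  stopifnot(is.list(cameras), length(cameras) >= 2)
  ids <- vapply(cameras, function(c) c$camera_id, character(1))
  if (anyDuplicated(ids)) stop("camera ids must be unique within a rig")
  centers <- t(vapply(cameras, camera_center, numeric(3)))
  d <- stats::dist(centers)
  if (any(d <= 1e-6)) stop("two cameras share an optical centre")
  names(cameras) <- ids
  structure(list(cameras = cameras, units_note = "mm"),
            class = "rig_calibration")
}

#' @export
print.rig_calibration <- function(x, ...) {
  cat("<rig_calibration> ", length(x$cameras), " cameras (",
      paste(names(x$cameras), collapse = ", "), "), units mm\n", sep = "")
  invisible(x)
}

#' Camera ids of a rig, in file order
#' @param rig A `rig_calibration`.
#' @return Character vector of camera ids.
#' @export
rig_camera_ids <- function(rig) names(rig$cameras)
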