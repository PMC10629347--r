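# Synthetic surround-view rig, rigid-object trajectory, and detector-like
# noisy 2D detections. The simulator stands in for the physical arena, the
# cameras, and the neural-network 2D detector; its noise model captures the
# detector's statistical behaviour (pixel jitter, dropout, occasional gross
# mislocalisation), not its appearance model.

#' Default sensor intrinsics template
#'
#' 1280 x 800 monochrome global-shutter sensor, principal point at the image
#' centre, focal length in pixels derived from a 2.4 mm lens and an assumed
#' 3 um pixel pitch (2.4 / 0.003 = 800 px). Only relative geometry matters
#' for the validation properties, so the pitch assumption is exposed rather
#' than hidden.
#'
#' @param focal_mm Lens focal length, mm.
#' @param pixel_pitch_mm Pixel pitch, mm.
#' @param image_width,image_height Sensor size, px.
#' @param distortion 5-vector (k1,k2,p1,p2,k3).
#' @return A `camera_intrinsics`.
#' @export
default_intrinsics <- function(focal_mm = 2.4, pixel_pitch_mm = 0.003,
                               image_width = 1280, image_height = 800,
                               distortion = c(0, 0, 0, 0, 0)) {
  f <- focal_mm / pixel_pitch_mm
  camera_intrinsics(focal_u = f, focal_v = f,
                    principal_u = image_width / 2,
                    principal_v = image_height / 2,
                    distortion = distortion,
                    image_width = image_width, image_height = image_height)
}

#' Surround-view rig layout
#'
#' `n_side_cameras` cameras on a horizontal ring around the arena centre plus
#' one camera below the (transparent) floor aimed upward. The world frame has
#' its origin at the arena-floor centre with +z up.
#'
#' @param n_side_cameras Number of ring cameras (>= 1).
#' @param camera_distance Ring radius, mm from the arena centre.
#' @param side_elevation Height of the ring cameras above the floor, mm.
#' @param bottom_depth Depth of the bottom camera below the floor, mm.
#' @param intrinsics_template `camera_intrinsics` shared by all cameras.
#' @param look_at Point every camera is aimed at (default origin).
#' @return An object of class `rig_layout`.
#' @export
rig_layout <- function(n_side_cameras = 3, camera_distance = 120,
                       side_elevation = 0, bottom_depth = 60,
                       intrinsics_template = default_intrinsics(),
                       look_at = c(0, 0, 0)) {
  stopifnot(n_side_cameras >= 1, camera_distance > 0, bottom_depth > 0)
  structure(list(n_side_cameras = as.integer(n_side_cameras),
                 camera_distance = camera_distance,
                 side_elevation = side_elevation,
                 bottom_depth = bottom_depth,
                 intrinsics_template = intrinsics_template,
                 look_at = as.numeric(look_at)),
            class = "rig_layout")
}

#' Arena presets
#'
#' `"small"`: 89 mm diameter arena, ring cameras 120 mm from the centre.
#' `"large"`: 320 mm diameter arena, ring cameras 340 mm from the centre.
#'
#' @param preset `"small"` or `"large"`.
#' @param ... Overrides passed to [rig_layout()].
#' @return A `rig_layout`.
#' @export
arena_preset <- function(preset = c("small", "large"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  defaults <- switch(preset,
    small = list(camera_distance = 120, bottom_depth = 60),
    large = list(camera_distance = 340, bottom_depth = 120)
  )
  defaults[names(args)] <- args
  do.call(rig_layout, defaults)
}

# World->camera pose aiming the camera at `target` from `center`, image v
# pointing "down" in the world (-z) where possible.
look_at_pose <- function(center, target, up_hint = c(0, 0, 1)) {
  zc <- target - center
  nz <- sqrt(sum(zc^2))
  if (nz == 0) stop("camera centre coincides with look-at target")
  zc <- zc / nz
  xc <- cross3(zc, up_hint)
  if (sqrt(sum(xc^2)) < 1e-9) xc <- cross3(zc, c(1, 0, 0))
  xc <- xc / sqrt(sum(xc^2))
  yc <- cross3(zc, xc)
  R <- rbind(xc, yc, zc)
  dimnames(R) <- NULL
  camera_pose(nearest_rotation(R), -drop(R %*% center))
}

#' Build a calibrated rig from a layout
#'
#' Side cameras are spaced at equal azimuths (360 / n_side degrees apart,
#' starting at azimuth 0 on the +x axis) on a ring of radius
#' `camera_distance` at height `side_elevation`; the bottom camera sits at
#' `(0, 0, -bottom_depth)`. Every camera is aimed exactly at `look_at`.
#' Cameras are named `cam_0 .. cam_{n-1}` with the bottom camera last.
#'
#' @param layout A `rig_layout`.
#' @return A `rig_calibration` with attribute `"bottom_id"`.
#' @export
build_rig <- function(layout) {
  stopifnot(inherits(layout, "rig_layout"))
  n <- layout$n_side_cameras
  cams <- vector("list", n + 1L)
  for (i in seq_len(n)) {
    az <- 2 * pi * (i - 1) / n
    center <- c(layout$camera_distance * cos(az),
                layout$camera_distance * sin(az),
                layout$side_elevation)
    cams[[i]] <- camera(paste0("cam_", i - 1L), layout$intrinsics_template,
                        look_at_pose(center, layout$look_at))
  }
  bottom_center <- c(0, 0, -layout$bottom_depth)
  cams[[n + 1L]] <- camera(paste0("cam_", n), layout$intrinsics_template,
                           look_at_pose(bottom_center, layout$look_at,
                                        up_hint = c(0, 1, 0)))
  rig <- rig_calibration(cams)
  attr(rig, "bottom_id") <- paste0("cam_", n)
  rig
}

#' Trajectory configuration
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_rate Frames per second (default 30).
#' @param rotation_rate Object rotation, degrees per frame (default 2).
#' @param translation_amplitude Peak translation excursion, mm (default 10).
#' @param seed Integer seed for the trajectory stream.
#' @return An object of class `trajectory_config`.
#' @export
trajectory_config <- function(n_frames = 200, frame_rate = 30,
                              rotation_rate = 2, translation_amplitude = 10,
                              seed = 1L) {
  stopifnot(n_frames >= 1, frame_rate > 0)
  structure(list(n_frames = as.integer(n_frames), frame_rate = frame_rate,
                 rotation_rate = rotation_rate,
                 translation_amplitude = translation_amplitude,
                 seed = as.integer(seed)),
            class = "trajectory_config")
}

# Smooth seeded scalar signal in [-1, 1]: a small sum of random-phase
# harmonics, normalized to unit peak. Deterministic given the RNG state.
smooth_signal <- function(n, n_harmonics = 4) {
  t <- seq_len(n) / n
  amp <- stats::runif(n_harmonics, 0.3, 1)
  freq <- stats::runif(n_harmonics, 0.5, 3)
  phase <- stats::runif(n_harmonics, 0, 2 * pi)
  s <- rowSums(vapply(seq_len(n_harmonics), function(k) {
    amp[k] * sin(2 * pi * freq[k] * t + phase[k])
  }, numeric(n)))
  m <- max(abs(s))
  if (m == 0) rep(0, n) else s / m
}

#' Simulate a smooth rigid-object trajectory
#'
#' The object rotates at `rotation_rate` degrees per frame about an axis that
#' precesses slowly, while its centre follows a bounded smooth excursion of
#' peak amplitude `translation_amplitude` around `center`. Identical seeds
#' give bitwise-identical pose lists.
#'
#' @param spec A `test_object_spec` (carried along for convenience; the
#'   trajectory itself depends only on the config).
#' @param config A `trajectory_config`.
#' @param center Trajectory centre in world coordinates, mm.
#' @return List of `rigid_pose`, one per frame.
#' @export
simulate_trajectory <- function(spec, config, center = c(0, 0, 0)) {
  stopifnot(inherits(config, "trajectory_config"))
  n <- config$n_frames
  poses <- vector("list", n)
  rot_step <- config$rotation_rate * pi / 180
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  set.seed(config$seed)
  # precessing rotation axis: slowly varying spherical angles
  az <- cumsum(c(stats::runif(1, 0, 2 * pi), stats::rnorm(n - 1, 0, 0.02)))
  el <- cumsum(c(stats::runif(1, -0.5, 0.5), stats::rnorm(n - 1, 0, 0.01)))
  trans <- config$translation_amplitude *
    cbind(smooth_signal(n), smooth_signal(n), smooth_signal(n))
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)

  R <- diag(3)
  for (i in seq_len(n)) {
    if (i > 1 && rot_step != 0) {
      axis <- c(cos(el[i]) * cos(az[i]), cos(el[i]) * sin(az[i]), sin(el[i]))
      R <- rotation_about_axis(axis, rot_step) %*% R
      R <- nearest_rotation(R)
    }
    tr <- if (config$translation_amplitude == 0) center else center + trans[i, ]
    poses[[i]] <- rigid_pose(R, tr)
  }
  poses
}

#' Detector noise model
#'
#' Statistical stand-in for a 2D keypoint detector: isotropic Gaussian pixel
#' jitter, per-observation dropout (the occlusion proxy), occasional gross
#' outliers (mislocalisation), and a rule assigning reported confidences.
#' Dropout and outlier probabilities can be overridden per camera or per
#' (camera, keypoint) for asymmetric-visibility scenarios.
#'
#' @param pixel_sigma Gaussian pixel noise SD, px (default 1).
#' @param p_miss Dropout probability per (camera, keypoint, frame), default
#'   0.02.
#' @param p_miss_by_camera Optional named numeric vector of per-camera
#'   dropout overrides.
#' @param outlier_prob Probability that a rendered detection is a gross
#'   outlier.
#' @param outlier_sigma Outlier noise SD, px.
#' @param overrides Optional data frame (camera_id, keypoint, p_miss,
#'   outlier_prob) of per-(camera, keypoint) overrides; `"*"` wildcards
#'   allowed in either id column.
#' @param confidence_law `"binary"` (1 for rendered, 0 for missing) or
#'   `"noisy"` (confidence shrinks with realized noise magnitude).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(pixel_sigma = 1, p_miss = 0.02,
                        p_miss_by_camera = NULL,
                        outlier_prob = 0, outlier_sigma = 30,
                        overrides = NULL,
                        confidence_law = c("binary", "noisy")) {
  confidence_law <- match.arg(confidence_law)
  stopifnot(pixel_sigma >= 0, outlier_sigma >= 0,
            p_miss >= 0, p_miss <= 1, outlier_prob >= 0, outlier_prob <= 1)
  if (!is.null(p_miss_by_camera)) {
    stopifnot(!is.null(names(p_miss_by_camera)),
              all(p_miss_by_camera >= 0 & p_miss_by_camera <= 1))
  }
  structure(list(pixel_sigma = pixel_sigma, p_miss = p_miss,
                 p_miss_by_camera = p_miss_by_camera,
                 outlier_prob = outlier_prob, outlier_sigma = outlier_sigma,
                 overrides = overrides, confidence_law = confidence_law),
            class = "noise_model")
}

# Resolve dropout / outlier probability for one (camera, keypoint).
resolve_rate <- function(noise, field, camera_id, keypoint) {
  val <- noise[[field]]
  if (field == "p_miss" && !is.null(noise$p_miss_by_camera) &&
      camera_id %in% names(noise$p_miss_by_camera)) {
    val <- unname(noise$p_miss_by_camera[camera_id])
  }
  ov <- noise$overrides
  if (!is.null(ov) && field %in% names(ov)) {
    hit <- (ov$camera_id == camera_id | ov$camera_id == "*") &
      (ov$keypoint == keypoint | ov$keypoint == "*")
    if (any(hit)) val <- ov[[field]][which(hit)[1]]
  }
  val
}

#' Create an empty detection table
#' @return Zero-row detection data frame with the canonical columns.
#' @export
detection_set <- function() {
  structure(data.frame(frame = integer(), camera_id = character(),
                       keypoint = character(), u = numeric(), v = numeric(),
                       confidence = numeric(), missing = logical(),
                       stringsAsFactors = FALSE),
            class = c("detection_set", "data.frame"))
}

#' Render noisy 2D detections of an object trajectory
#'
#' For every (frame, camera, keypoint): the world point is projected; it is
#' marked missing when behind the camera, outside the image bounds, or lost
#' to a dropout draw; surviving detections receive Gaussian pixel noise (or
#' outlier noise with the configured probability) and a confidence per the
#' noise model's confidence law. Missing records keep NA pixels and
#' confidence 0 — missingness is explicit, never encoded as (0, 0).
#'
#' @param rig A `rig_calibration`.
#' @param spec A `test_object_spec`.
#' @param poses List of `rigid_pose`, one per frame.
#' @param noise A `noise_model`.
#' @param seed Integer seed for the noise/dropout streams.
#' @return A `detection_set` data frame (frames 0-based) with attribute
#'   `"truth_3d"`: list of per-frame named keypoint world coordinate
#'   matrices.
#' @export
render_detections <- function(rig, spec, poses, noise = noise_model(),
                              seed = 1L) {
  ids <- rig_camera_ids(rig)
  kn <- names(spec$keypoints)
  nf <- length(poses)
  nk <- length(kn)
  nc <- length(ids)

  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv))
  set.seed(as.integer(seed))
  # independent sub-streams so dropout pattern does not shift with sigma
  seeds <- sample.int(.Machine$integer.max, 3)

  truth <- lapply(poses, function(p) place_object(spec, p))

  # dropout stream
  set.seed(seeds[1])
  drop_draw <- array(stats::runif(nf * nc * nk), dim = c(nf, nc, nk))
  out_draw <- array(stats::runif(nf * nc * nk), dim = c(nf, nc, nk))
  # noise stream
  set.seed(seeds[2])
  gnoise <- array(stats::rnorm(nf * nc * nk * 2), dim = c(nf, nc, nk, 2))
  set.seed(seeds[3])
  onoise <- array(stats::rnorm(nf * nc * nk * 2), dim = c(nf, nc, nk, 2))

  n_rows <- nf * nc * nk
  frame <- integer(n_rows); camid <- character(n_rows)
  keyp <- character(n_rows); u <- rep(NA_real_, n_rows)
  v <- rep(NA_real_, n_rows); conf <- numeric(n_rows)
  miss <- rep(TRUE, n_rows)

  row <- 0L
  for (ci in seq_len(nc)) {
    cam <- rig$cameras[[ci]]
    W <- cam$intrinsics$image_width
    H <- cam$intrinsics$image_height
    p_miss_k <- vapply(kn, function(k) {
      resolve_rate(noise, "p_miss", ids[ci], k)
    }, numeric(1))
    p_out_k <- vapply(kn, function(k) {
      resolve_rate(noise, "outlier_prob", ids[ci], k)
    }, numeric(1))
    for (fi in seq_len(nf)) {
      uv <- project(cam, truth[[fi]], on_behind = "na")
      for (ki in seq_len(nk)) {
        row <- row + 1L
        frame[row] <- fi - 1L
        camid[row] <- ids[ci]
        keyp[row] <- kn[ki]
        pu <- uv[ki, 1]; pv <- uv[ki, 2]
        in_view <- !is.na(pu) && pu >= 0 && pu <= W && pv >= 0 && pv <= H
        dropped <- drop_draw[fi, ci, ki] < p_miss_k[ki]
        if (!in_view || dropped) next  # stays missing
        if (out_draw[fi, ci, ki] < p_out_k[ki]) {
          du <- noise$outlier_sigma * onoise[fi, ci, ki, 1]
          dv <- noise$outlier_sigma * onoise[fi, ci, ki, 2]
        } else {
          du <- noise$pixel_sigma * gnoise[fi, ci, ki, 1]
          dv <- noise$pixel_sigma * gnoise[fi, ci, ki, 2]
        }
        u[row] <- pu + du
        v[row] <- pv + dv
        miss[row] <- FALSE
        conf[row] <- if (noise$confidence_law == "binary") 1 else
          1 / (1 + sqrt(du^2 + dv^2) / 5)
      }
    }
  }
  det <- data.frame(frame = frame, camera_id = camid, keypoint = keyp,
                    u = u, v = v, confidence = conf, missing = miss,
                    stringsAsFactors = FALSE)
  class(det) <- c("detection_set", "data.frame")
  attr(det, "truth_3d") <- truth
  det
}

#' Mouse-like asymmetric-visibility preset
#'
#' A rigid stand-in "skeleton" (snout, tail base, spine mid, four paws) with
#' a noise model in which ventral keypoints (the paws) are poorly visible
#' from the ring cameras: high dropout and, for the detections that survive,
#' an elevated gross-mislocalisation probability — occluded keypoints are
#' both missed and mis-placed by real detectors. The bottom camera sees the
#' ventral keypoints nearly unimpeded.
#'
#' @param n_side Number of ring cameras in the rig the preset targets
#'   (bottom camera assumed to be `cam_{n_side}`, as built by [build_rig()]).
#' @param side_p_miss Ventral-keypoint dropout on ring cameras (default 0.5).
#' @param bottom_p_miss Ventral-keypoint dropout on the bottom camera
#'   (default 0.05).
#' @param side_outlier_prob Mislocalisation probability for surviving
#'   ring-camera ventral detections (default 0.15).
#' @return List with elements `spec` (a `test_object_spec`), `noise`
#'   (a `noise_model`) and `ventral_keypoints`.
#' @export
mouse_like_preset <- function(n_side = 3, side_p_miss = 0.5,
                              bottom_p_miss = 0.05,
                              side_outlier_prob = 0.15) {
  kp <- list(
    snout = c(35, 0, 12),
    spine_mid = c(0, 0, 18),
    tail_base = c(-35, 0, 14),
    paw_front_left = c(18, 10, 1),
    paw_front_right = c(18, -10, 1),
    paw_hind_left = c(-15, 12, 1),
    paw_hind_right = c(-15, -12, 1)
  )
  spec <- test_object_spec("mouse_like_rigid", kp)
  ventral <- grep("^paw_", names(kp), value = TRUE)
  side_ids <- paste0("cam_", seq_len(n_side) - 1L)
  bottom_id <- paste0("cam_", n_side)
  ov <- rbind(
    data.frame(camera_id = rep(side_ids, each = length(ventral)),
               keypoint = rep(ventral, times = length(side_ids)),
               p_miss = side_p_miss, outlier_prob = side_outlier_prob,
               stringsAsFactors = FALSE),
    data.frame(camera_id = bottom_id, keypoint = ventral,
               p_miss = bottom_p_miss, outlier_prob = 0.01,
               stringsAsFactors = FALSE)
  )
  noise <- noise_model(pixel_sigma = 1, p_miss = 0.05, overrides = ov,
                       outlier_prob = 0.01, outlier_sigma = 40)
  list(spec = spec, noise = noise, ventral_keypoints = ventral,
       bottom_id = bottom_id)
}

#' Simulate a full capture session
#'
#' Convenience wrapper: build the rig, simulate a trajectory, render
#' detections. One global seed is expanded into independent per-stage seeds.
#'
#' @param layout A `rig_layout` (default small-arena preset).
#' @param spec A `test_object_spec` (default [make_xyz_object()]).
#' @param n_frames Number of frames.
#' @param noise A `noise_model`.
#' @param seed Global integer seed.
#' @param trajectory_center World centre of the object trajectory.
#' @param ... Further arguments to [trajectory_config()].
#' @return List (`simulation_bundle`): `rig`, `detections`, `truth_3d`,
#'   `spec`, `poses`, `config` echo with seed.
#' @export
simulate_session <- function(layout = arena_preset("small"),
                             spec = make_xyz_object(),
                             n_frames = 200,
                             noise = noise_model(),
                             seed = 1L,
                             trajectory_center = c(0, 0, 0), ...) {
  old <- if (exists(".Random.seed", envir = .GlobalEnv)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max, 2)
  if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  rig <- build_rig(layout)
  cfg <- trajectory_config(n_frames = n_frames, seed = seeds[1], ...)
  poses <- simulate_trajectory(spec, cfg, center = trajectory_center)
  det <- render_detections(rig, spec, poses, noise, seed = seeds[2])
  structure(list(rig = rig, detections = det,
                 truth_3d = attr(det, "truth_3d"),
                 spec = spec, poses = poses,
                 config = list(layout = layout, trajectory = cfg,
                               noise = noise, seed = as.integer(seed))),
            class = "simulation_bundle")
}
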