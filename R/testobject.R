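#' Rigid test-object specification
#'
#' Named 3D keypoints in an object-fixed frame (mm), plus the list of keypoint
#' pairs whose inter-keypoint distances serve as the accuracy proxy.
#'
#' @param name Object name.
#' @param keypoints Named list (or named n x 3 matrix) of 3-vectors, mm,
#'   object-frame coordinates. At least 3 keypoints with unique names.
#' @param pairs Optional list of character 2-vectors; defaults to all
#'   unordered keypoint pairs with non-zero ground-truth distance.
#' @return An object of class `test_object_spec`.
#' @export
test_object_spec <- function(name, keypoints, pairs = NULL) {
  if (is.matrix(keypoints)) {
    keypoints <- stats::setNames(
      lapply(seq_len(nrow(keypoints)), function(i) as.numeric(keypoints[i, ])),
      rownames(keypoints))
  }
  stopifnot(is.list(keypoints), length(keypoints) >= 3)
  kn <- names(keypoints)
  if (is.null(kn) || anyDuplicated(kn) || any(kn == "")) {
    stop("keypoints must have unique non-empty names")
  }
  keypoints <- lapply(keypoints, function(p) {
    p <- as.numeric(p)
    if (length(p) != 3 || anyNA(p)) stop("each keypoint must be a finite 3-vector")
    p
  })
  if (is.null(pairs)) {
    cmb <- utils::combn(kn, 2, simplify = FALSE)
    pairs <- cmb
  } else {
    pairs <- lapply(pairs, as.character)
  }
  for (p in pairs) {
    if (length(p) != 2 || !all(p %in% kn)) {
      stop("each pair must name two known keypoints")
    }
    d <- sqrt(sum((keypoints[[p[1]]] - keypoints[[p[2]]])^2))
    if (d <= 0) stop("pair (", p[1], ", ", p[2], ") has zero ground-truth distance")
  }
  structure(list(name = name, keypoints = keypoints, pairs = pairs),
            class = "test_object_spec")
}

#' @export
print.test_object_spec <- function(x, ...) {
  cat("<test_object_spec> '", x$name, "': ", length(x$keypoints),
      " keypoints, ", length(x$pairs), " evaluated pairs\n", sep = "")
  invisible(x)
}

keypoint_matrix <- function(spec) {
  do.call(rbind, spec$keypoints)
}

#' Rigid pose of an object in the world frame
#' @param rotation 3x3 orthonormal matrix, det +1.
#' @param translation Length-3 vector, mm.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  p <- camera_pose(rotation, translation)
  class(p) <- "rigid_pose"
  p
}

#' Build the perpendicular-rod XYZ test object
#'
#' Three rods of equal length meet at the origin along the +x, +y and +z
#' axes, mutually perpendicular; the letter at the end of each rod is
#' represented by an anchor keypoint at the rod tip (optionally a secondary
#' keypoint offset along the rod to stand in for the letter's extent). The
#' asymmetric letters on the physical object give each rod a unique visual
#' identity; here the keypoints themselves carry the identity through their
#' names.
#'
#' @param rod_length Rod length, mm (> 0); default 40.
#' @param letter_offset Offset of an optional secondary keypoint per letter,
#'   mm beyond the rod tip (0 = no secondary keypoints).
#' @return A `test_object_spec` with keypoints `origin`, `X`, `Y`, `Z`
#'   (plus `X2`, `Y2`, `Z2` when `letter_offset > 0`).
#' @export
make_xyz_object <- function(rod_length = 40, letter_offset = 0) {
  if (!is.numeric(rod_length) || rod_length <= 0) {
    stop("`rod_length` must be a positive length in mm")
  }
  if (letter_offset < 0) stop("`letter_offset` must be >= 0")
  kp <- list(
    origin = c(0, 0, 0),
    X = c(rod_length, 0, 0),
    Y = c(0, rod_length, 0),
    Z = c(0, 0, rod_length)
  )
  if (letter_offset > 0) {
    kp$X2 <- c(rod_length + letter_offset, 0, 0)
    kp$Y2 <- c(0, rod_length + letter_offset, 0)
    kp$Z2 <- c(0, 0, rod_length + letter_offset)
  }
  test_object_spec("xyz_test_object", kp)
}

#' Ground-truth inter-keypoint distances
#' @param spec A `test_object_spec`.
#' @return Data frame with columns `keypoint_a`, `keypoint_b`, `distance`
#'   (mm), one row per configured pair.
#' @export
ground_truth_distances <- function(spec) {
  stopifnot(inherits(spec, "test_object_spec"))
  a <- vapply(spec$pairs, `[`, character(1), 1)
  b <- vapply(spec$pairs, `[`, character(1), 2)
  d <- mapply(function(i, j) {
    sqrt(sum((spec$keypoints[[i]] - spec$keypoints[[j]])^2))
  }, a, b, USE.NAMES = FALSE)
  data.frame(keypoint_a = a, keypoint_b = b, distance = d,
             stringsAsFactors = FALSE)
}

#' Place an object in the world frame
#' @param spec A `test_object_spec`.
#' @param pose A `rigid_pose` (world pose of the object frame).
#' @return Named n x 3 matrix of world coordinates, mm.
#' @export
place_object <- function(spec, pose) {
  stopifnot(inherits(spec, "test_object_spec"))
  if (!inherits(pose, c("rigid_pose", "camera_pose"))) {
    pose <- rigid_pose(pose$rotation, pose$translation)
  }
  K <- keypoint_matrix(spec)
  W <- K %*% t(pose$rotation) +
    matrix(pose$translation, nrow(K), 3, byrow = TRUE)
  rownames(W) <- names(spec$keypoints)
  W
}

#' Enumerate axis-aligned rotational symmetries of an object
#'
#' Checks each of the 24 proper axis-aligned (cube-group) rotations against
#' the keypoint set, both as an unlabeled point set and as a labeled map
#' (each keypoint must land on the same-named keypoint). For the default XYZ
#' object the unlabeled tip set retains the cube's 3-fold symmetry about
#' (1,1,1); the letter identities — carried here by keypoint names — break
#' it, so only the identity survives the labeled check.
#'
#' @param spec A `test_object_spec`.
#' @param tol Position tolerance, mm.
#' @return List with integer counts `n_unlabeled` and `n_labeled` of
#'   symmetries found (identity included) and the rotation matrices of the
#'   labeled symmetries.
#' @export
object_symmetries <- function(spec, tol = 1e-9) {
  K <- keypoint_matrix(spec)
  rots <- cube_rotations()
  unlab <- 0L
  lab <- 0L
  lab_rots <- list()
  for (R in rots) {
    M <- K %*% t(R)
    # labeled: every keypoint maps to its own position
    if (max(abs(M - K)) < tol) {
      lab <- lab + 1L
      lab_rots[[length(lab_rots) + 1L]] <- R
    }
    # unlabeled: mapped set equals original set (greedy nearest match)
    used <- rep(FALSE, nrow(K))
    ok <- TRUE
    for (i in seq_len(nrow(K))) {
      dd <- sqrt(rowSums((K - matrix(M[i, ], nrow(K), 3, byrow = TRUE))^2))
      dd[used] <- Inf
      j <- which.min(dd)
      if (dd[j] < tol) used[j] <- TRUE else { ok <- FALSE; break }
    }
    if (ok) unlab <- unlab + 1L
  }
  list(n_unlabeled = unlab, n_labeled = lab, labeled_rotations = lab_rots)
}

# The 24 proper rotations of the cube group.
cube_rotations <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  out <- list()
  for (p in perms) {
    for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
      R <- matrix(0, 3, 3)
      signs <- c(s1, s2, s3)
      for (i in 1:3) R[i, p[i]] <- signs[i]
      if (abs(det(R) - 1) < 1e-12) out[[length(out) + 1L]] <- R
    }
  }
  out
}

#' Write / read a test-object specification as JSON
#'
#' Format: `{"name": ..., "keypoints": {"name": [x,y,z], ...},
#' "pairs": [["a","b"], ...]}`, coordinates in mm, object frame.
#'
#' @param spec A `test_object_spec`.
#' @param path File path.
#' @return `read_object_json` returns a `test_object_spec`;
#'   `write_object_json` returns `path` invisibly.
#' @export
write_object_json <- function(spec, path) {
  obj <- list(name = spec$name,
              keypoints = spec$keypoints,
              pairs = spec$pairs)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_object_json
#' @export
read_object_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kp <- lapply(obj$keypoints, as.numeric)
  pairs <- NULL
  if (!is.null(obj$pairs)) {
    pairs <- if (is.matrix(obj$pairs)) {
      lapply(seq_len(nrow(obj$pairs)), function(i) obj$pairs[i, ])
    } else obj$pairs
  }
  test_object_spec(obj$name, kp, pairs)
}
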