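# File formats: DeepLabCut-style detection CSV, Anipose-dialect calibration
# TOML, wide 3D series CSV. Frames are 0-based in every file; pixels are
# continuous with the origin at the top-left corner; 3D units are mm.

#' Write detections as a DeepLabCut-style CSV
#'
#' Three header rows (scorer / bodyparts / coords with x, y, likelihood per
#' keypoint), one row per frame, first column the 0-based frame index.
#' Missing detections are written as empty cells (read back as missing).
#'
#' @param detections Detection table (one camera's rows, or pass
#'   `camera_id` to select).
#' @param path Output path.
#' @param camera_id Optional camera id filter.
#' @param scorer Scorer label for the header.
#' @return `path`, invisibly.
#' @export
write_dlc_csv <- function(detections, path, camera_id = NULL,
                          scorer = "rigcheck") {
  det <- detections
  if (!is.null(camera_id)) det <- det[det$camera_id == camera_id, , drop = FALSE]
  if (!nrow(det)) stop("no detections to write")
  if (length(unique(det$camera_id)) > 1) {
    stop("one DLC CSV holds one camera; filter with `camera_id`")
  }
  kps <- unique(det$keypoint)
  frames <- sort(unique(det$frame))
  h1 <- c("scorer", rep(scorer, 3 * length(kps)))
  h2 <- c("bodyparts", rep(kps, each = 3))
  h3 <- c("coords", rep(c("x", "y", "likelihood"), times = length(kps)))
  key <- paste(det$frame, det$keypoint, sep = "\r")
  M <- matrix("", length(frames), 3 * length(kps))
  for (j in seq_along(kps)) {
    i <- match(paste(frames, kps[j], sep = "\r"), key)
    hit <- !is.na(i) & !det$missing[i]
    M[hit, 3 * j - 2] <- format(det$u[i[hit]], digits = 17, trim = TRUE,
                                scientific = FALSE)
    M[hit, 3 * j - 1] <- format(det$v[i[hit]], digits = 17, trim = TRUE,
                                scientific = FALSE)
    M[hit, 3 * j] <- format(det$confidence[i[hit]], digits = 17,
                            trim = TRUE, scientific = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(h1, collapse = ","), con)
  writeLines(paste(h2, collapse = ","), con)
  writeLines(paste(h3, collapse = ","), con)
  body <- cbind(as.character(frames), M)
  writeLines(apply(body, 1, paste, collapse = ","), con)
  invisible(path)
}

#' Read a DeepLabCut-style detection CSV
#'
#' Expects the 3-row scorer / bodyparts / coords header; the x, y and
#' likelihood columns of each bodypart are located by header label, so
#' permuted column order is handled. Non-finite or empty coordinates become
#' missing records.
#'
#' @param path CSV path.
#' @param camera_id Camera id to stamp on the records.
#' @return A detection table.
#' @export
read_dlc_csv <- function(path, camera_id) {
  if (!file.exists(path)) stop("detection file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 4) stop("malformed DLC CSV: fewer than 4 rows in ", path)
  h1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  h2 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  h3 <- strsplit(lines[3], ",", fixed = TRUE)[[1]]
  if (tolower(h1[1]) != "scorer") {
    stop("malformed DLC CSV header row 1 (expected 'scorer'): ", path)
  }
  if (tolower(h2[1]) != "bodyparts") {
    stop("malformed DLC CSV header row 2 (expected 'bodyparts'): ", path)
  }
  if (tolower(h3[1]) != "coords") {
    stop("malformed DLC CSV header row 3 (expected 'coords'): ", path)
  }
  body <- utils::read.csv(text = lines[-(1:3)], header = FALSE,
                          stringsAsFactors = FALSE)
  frames <- as.integer(body[[1]])
  kps <- unique(h2[-1])
  rows <- list()
  for (kp in kps) {
    cols <- which(h2 == kp)
    xi <- cols[h3[cols] == "x"][1]
    yi <- cols[h3[cols] == "y"][1]
    li <- cols[h3[cols] == "likelihood"][1]
    if (is.na(xi) || is.na(yi)) {
      stop("bodypart '", kp, "' lacks x/y columns in ", path)
    }
    u <- suppressWarnings(as.numeric(body[[xi]]))
    v <- suppressWarnings(as.numeric(body[[yi]]))
    conf <- if (!is.na(li)) suppressWarnings(as.numeric(body[[li]])) else
      rep(1, length(u))
    miss <- !is.finite(u) | !is.finite(v)
    conf[miss | !is.finite(conf)] <- 0
    u[miss] <- NA_real_
    v[miss] <- NA_real_
    rows[[kp]] <- data.frame(frame = frames, camera_id = camera_id,
                             keypoint = kp, u = u, v = v, confidence = conf,
                             missing = miss, stringsAsFactors = FALSE)
  }
  det <- do.call(rbind, rows)
  rownames(det) <- NULL
  det <- det[order(det$frame, det$keypoint), , drop = FALSE]
  class(det) <- c("detection_set", "data.frame")
  det
}

# ---- Anipose-dialect calibration TOML ----
# One section per camera: [cam_0] ... with name, size, matrix (3x3 row-major
# nested array), distortions (5-vector), rotation (Rodrigues 3-vector),
# translation (3-vector, mm). No TOML package ships with the environment,
# so this minimal dialect reader/writer is implemented here; the reader
# tolerates unknown keys and the writer emits exactly the dialect keys.

toml_fmt_num <- function(x) {
  vapply(x, function(v) {
    s <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
    if (!grepl("[.eE]", s)) s <- paste0(s, ".0")
    s
  }, character(1))
}

#' Write a rig calibration as Anipose-dialect TOML
#' @param rig A `rig_calibration`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration_toml <- function(rig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ids <- rig_camera_ids(rig)
  for (i in seq_along(ids)) {
    cam <- rig$cameras[[i]]
    intr <- cam$intrinsics
    K <- intrinsic_matrix(intr)
    rvec <- matrix_to_rodrigues(cam$pose$rotation)
    writeLines(sprintf("[cam_%d]", i - 1L), con)
    writeLines(sprintf('name = "%s"', cam$camera_id), con)
    writeLines(sprintf("size = [ %s, %s ]",
                       format(intr$image_width), format(intr$image_height)), con)
    writeLines(sprintf("matrix = [ [ %s ], [ %s ], [ %s ] ]",
                       paste(toml_fmt_num(K[1, ]), collapse = ", "),
                       paste(toml_fmt_num(K[2, ]), collapse = ", "),
                       paste(toml_fmt_num(K[3, ]), collapse = ", ")), con)
    writeLines(sprintf("distortions = [ %s ]",
                       paste(toml_fmt_num(intr$distortion), collapse = ", ")), con)
    writeLines(sprintf("rotation = [ %s ]",
                       paste(toml_fmt_num(rvec), collapse = ", ")), con)
    writeLines(sprintf("translation = [ %s ]",
                       paste(toml_fmt_num(cam$pose$translation), collapse = ", ")), con)
    writeLines("", con)
  }
  invisible(path)
}

# Parse a (possibly nested) TOML array literal into an R object.
parse_toml_array <- function(s) {
  s <- trimws(s)
  stopifnot(startsWith(s, "["), endsWith(s, "]"))
  inner <- substr(s, 2, nchar(s) - 1)
  # split on top-level commas
  depth <- 0
  parts <- character(0)
  buf <- ""
  for (ch in strsplit(inner, "")[[1]]) {
    if (ch == "[") depth <- depth + 1
    if (ch == "]") depth <- depth - 1
    if (ch == "," && depth == 0) {
      parts <- c(parts, buf)
      buf <- ""
    } else buf <- paste0(buf, ch)
  }
  if (nzchar(trimws(buf))) parts <- c(parts, buf)
  parts <- trimws(parts)
  if (!length(parts)) return(numeric(0))
  if (startsWith(parts[1], "[")) {
    do.call(rbind, lapply(parts, parse_toml_array))
  } else {
    as.numeric(parts)
  }
}

#' Read an Anipose-dialect calibration TOML
#'
#' Extra keys in a camera section are ignored; sections other than
#' `[cam_*]` (e.g. calibration metadata) are skipped.
#'
#' @param path TOML path.
#' @return A `rig_calibration`.
#' @export
read_calibration_toml <- function(path) {
  if (!file.exists(path)) stop("calibration file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  sections <- list()
  current <- NULL
  for (ln in lines) {
    ln <- trimws(ln)
    if (grepl("^\\[.*\\]$", ln)) {
      current <- gsub("^\\[|\\]$", "", ln)
      sections[[current]] <- list()
      next
    }
    if (is.null(current)) next
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(ln, 1, eq - 1))
    val <- trimws(substr(ln, eq + 1, nchar(ln)))
    sections[[current]][[key]] <- val
  }
  cam_names <- grep("^cam_[0-9]+$", names(sections), value = TRUE)
  cam_names <- cam_names[order(as.integer(sub("cam_", "", cam_names)))]
  if (length(cam_names) < 2) stop("calibration file has fewer than 2 cameras")
  cams <- lapply(cam_names, function(sec) {
    s <- sections[[sec]]
    need <- c("matrix", "distortions", "rotation", "translation", "size")
    miss <- setdiff(need, names(s))
    if (length(miss)) {
      stop("section [", sec, "] missing key(s): ", paste(miss, collapse = ", "))
    }
    K <- parse_toml_array(s$matrix)
    dist <- parse_toml_array(s$distortions)
    rvec <- parse_toml_array(s$rotation)
    tvec <- parse_toml_array(s$translation)
    size <- parse_toml_array(s$size)
    name <- if (!is.null(s$name)) gsub('^"|"$', "", s$name) else sec
    R <- rodrigues_to_matrix(rvec)
    if (max(abs(crossprod(R) - diag(3))) > 1e-6) {
      stop("section [", sec, "]: rotation is not orthonormalizable")
    }
    intr <- camera_intrinsics(focal_u = K[1, 1], focal_v = K[2, 2],
                              principal_u = K[1, 3], principal_v = K[2, 3],
                              skew = K[1, 2], distortion = dist,
                              image_width = size[1], image_height = size[2])
    camera(name, intr, camera_pose(nearest_rotation(R), tvec))
  })
  rig_calibration(cams)
}

# ---- wide 3D series CSV ----

#' Write / read a reconstructed 3D series as wide CSV
#'
#' Columns: `frame`, then `<kp>_x, <kp>_y, <kp>_z, <kp>_error, <kp>_ncams`
#' per keypoint (mm and px); invalid estimates have empty coordinate cells.
#'
#' @param series A `pose3d_series`.
#' @param path CSV path.
#' @return `read_pose3d_csv` returns a `pose3d_series`; the writer returns
#'   `path` invisibly.
#' @export
write_pose3d_csv <- function(series, path) {
  kps <- unique(series$keypoint)
  frames <- sort(unique(series$frame))
  cols <- list(frame = frames)
  key <- paste(series$frame, series$keypoint, sep = "\r")
  for (kp in kps) {
    i <- match(paste(frames, kp, sep = "\r"), key)
    valid <- !is.na(i) & series$valid[i]
    g <- function(v) ifelse(valid, v[i], NA_real_)
    cols[[paste0(kp, "_x")]] <- g(series$x)
    cols[[paste0(kp, "_y")]] <- g(series$y)
    cols[[paste0(kp, "_z")]] <- g(series$z)
    cols[[paste0(kp, "_error")]] <- g(series$reprojection_rms)
    cols[[paste0(kp, "_ncams")]] <- ifelse(valid, series$n_cameras_used[i], 0L)
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pose3d_csv
#' @export
read_pose3d_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  kps <- unique(sub("_x$", "", grep("_x$", names(df), value = TRUE)))
  rows <- lapply(kps, function(kp) {
    x <- df[[paste0(kp, "_x")]]
    data.frame(frame = as.integer(df$frame), keypoint = kp,
               x = x, y = df[[paste0(kp, "_y")]], z = df[[paste0(kp, "_z")]],
               n_cameras_used = as.integer(df[[paste0(kp, "_ncams")]]),
               reprojection_rms = df[[paste0(kp, "_error")]],
               valid = is.finite(x), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$frame, out$keypoint), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pose3d_series", "data.frame")
  out
}

#' Write ground-truth 3D keypoint trajectories as wide CSV
#' @param truth_3d List of per-frame named keypoint matrices (as produced by
#'   [render_detections()]).
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth_3d, path) {
  kps <- rownames(truth_3d[[1]])
  cols <- list(frame = seq_along(truth_3d) - 1L)
  for (kp in kps) {
    M <- t(vapply(truth_3d, function(fr) fr[kp, ], numeric(3)))
    cols[[paste0(kp, "_x")]] <- M[, 1]
    cols[[paste0(kp, "_y")]] <- M[, 2]
    cols[[paste0(kp, "_z")]] <- M[, 3]
  }
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE)
  invisible(path)
}
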