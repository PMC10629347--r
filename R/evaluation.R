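# Validation statistics: camera-subset ablation, inter-keypoint distance
# error, deviation from a full-rig reference, bias/variance, boxplot
# summaries, error-vs-image-centre correlation, configuration ANOVA.

#' Enumerate camera-subset configurations and their symmetry classes
#'
#' All subsets of the rig of size >= `min_size`, each labeled with its
#' symmetry class "(n side cameras)s" with "+b" appended when the bottom
#' camera is included (ring cameras at equal azimuth spacing are geometrically
#' interchangeable, so e.g. all three 2-ring-camera pairs share class "2s").
#'
#' @param rig A `rig_calibration`.
#' @param bottom_id Camera id of the bottom camera.
#' @param min_size Minimum subset size (default 2).
#' @return Data frame: `config_id` (comma-joined member ids), `n_cameras`,
#'   `includes_bottom`, `symmetry_class`, and list-column `members`.
#' @export
enumerate_configs <- function(rig, bottom_id, min_size = 2) {
  ids <- rig_camera_ids(rig)
  if (!bottom_id %in% ids) stop("unknown bottom camera id: ", bottom_id)
  subsets <- list()
  for (k in seq(min_size, length(ids))) {
    cmb <- utils::combn(ids, k, simplify = FALSE)
    subsets <- c(subsets, cmb)
  }
  n_side <- vapply(subsets, function(s) sum(s != bottom_id), integer(1))
  has_b <- vapply(subsets, function(s) bottom_id %in% s, logical(1))
  cls <- paste0(n_side, "s", ifelse(has_b, "+b", ""))
  out <- data.frame(
    config_id = vapply(subsets, paste, character(1), collapse = ","),
    n_cameras = lengths(subsets),
    includes_bottom = has_b,
    symmetry_class = cls,
    stringsAsFactors = FALSE
  )
  out$members <- subsets
  out
}

empty_error_table <- function() {
  data.frame(frame = integer(), item = character(),
             config_class = character(), config_id = character(),
             signed_error = numeric(), abs_error = numeric(),
             metric = character(), stringsAsFactors = FALSE)
}

#' Inter-keypoint distance error of a reconstructed series
#'
#' For every frame and configured keypoint pair with both endpoints validly
#' reconstructed, the signed error is the observed Euclidean distance minus
#' the ground-truth distance. Frames with an invalid endpoint are excluded
#' and counted in the `"coverage"` attribute rather than imputed.
#'
#' @param series A `pose3d_series`.
#' @param spec A `test_object_spec` sharing keypoint names with the series.
#' @param config_class,config_id Labels copied onto every record.
#' @return Error table with `metric = "interkeypoint"` and, as attributes,
#'   `"coverage"` (fraction of frame-pairs usable) and `"observed_distance"`
#'   column retained for variance computations.
#' @export
interkeypoint_error <- function(series, spec, config_class = NA_character_,
                                config_id = NA_character_) {
  common <- intersect(unique(series$keypoint), names(spec$keypoints))
  if (!length(common)) stop("series and spec share no keypoints")
  gtd <- ground_truth_distances(spec)
  gtd <- gtd[gtd$keypoint_a %in% common & gtd$keypoint_b %in% common, ,
             drop = FALSE]
  if (!nrow(gtd)) stop("no evaluable keypoint pairs in the series")
  ok <- series[series$valid, , drop = FALSE]
  rows <- list()
  n_total <- 0L
  n_used <- 0L
  frames <- sort(unique(series$frame))
  # index: (frame, keypoint) -> coordinates
  key <- paste(ok$frame, ok$keypoint, sep = "\r")
  coord <- cbind(ok$x, ok$y, ok$z)
  for (p in seq_len(nrow(gtd))) {
    a <- gtd$keypoint_a[p]; b <- gtd$keypoint_b[p]
    ia <- match(paste(frames, a, sep = "\r"), key)
    ib <- match(paste(frames, b, sep = "\r"), key)
    use <- !is.na(ia) & !is.na(ib)
    n_total <- n_total + length(frames)
    n_used <- n_used + sum(use)
    if (!any(use)) next
    d_obs <- sqrt(rowSums((coord[ia[use], , drop = FALSE] -
                             coord[ib[use], , drop = FALSE])^2))
    rows[[p]] <- data.frame(
      frame = frames[use], item = paste(a, b, sep = "-"),
      config_class = config_class, config_id = config_id,
      signed_error = d_obs - gtd$distance[p],
      abs_error = abs(d_obs - gtd$distance[p]),
      metric = "interkeypoint", observed_distance = d_obs,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    e <- empty_error_table(); e$observed_distance <- numeric(); e
  }
  attr(out, "coverage") <- if (n_total) n_used / n_total else NA_real_
  out
}

#' Deviation of a reconstruction from a reference reconstruction
#'
#' Per frame and keypoint valid in both series: the Euclidean distance (mm)
#' between the two 3D estimates. Used when no ground truth exists and the
#' full-rig reconstruction serves as the standard.
#'
#' @param series A `pose3d_series` (the configuration under test).
#' @param reference A `pose3d_series` (the standard).
#' @param config_class,config_id Labels copied onto every record.
#' @return Error table with `metric = "reference_deviation"`; the deviation
#'   is unsigned, stored in `abs_error` (and mirrored in `signed_error`).
#' @export
deviation_from_reference <- function(series, reference,
                                     config_class = NA_character_,
                                     config_id = NA_character_) {
  common <- intersect(unique(series$keypoint), unique(reference$keypoint))
  if (!length(common)) stop("series and reference share no keypoints")
  a <- series[series$valid & series$keypoint %in% common, , drop = FALSE]
  b <- reference[reference$valid & reference$keypoint %in% common, , drop = FALSE]
  kb <- paste(b$frame, b$keypoint, sep = "\r")
  ib <- match(paste(a$frame, a$keypoint, sep = "\r"), kb)
  use <- !is.na(ib)
  a <- a[use, , drop = FALSE]
  ib <- ib[use]
  dev <- sqrt((a$x - b$x[ib])^2 + (a$y - b$y[ib])^2 + (a$z - b$z[ib])^2)
  out <- data.frame(frame = a$frame, item = a$keypoint,
                    config_class = config_class, config_id = config_id,
                    signed_error = dev, abs_error = dev,
                    metric = "reference_deviation", stringsAsFactors = FALSE)
  out
}

#' Bias / variance decomposition of inter-keypoint distance measurements
#'
#' Per keypoint pair: bias is the mean signed distance error over frames
#' (expected minus true value); variance is the sample variance (n - 1
#' denominator) of the repeated observed distances.
#'
#' @param errors An inter-keypoint error table (from
#'   [interkeypoint_error()], must retain `observed_distance`).
#' @return Data frame: `item`, `bias` (mm), `variance` (mm^2), `n`,
#'   `variance_defined`.
#' @export
bias_variance <- function(errors) {
  if (!all(errors$metric == "interkeypoint")) {
    stop("bias_variance requires inter-keypoint distance errors")
  }
  items <- unique(errors$item)
  res <- lapply(items, function(it) {
    e <- errors[errors$item == it, , drop = FALSE]
    n <- nrow(e)
    data.frame(item = it,
               bias = mean(e$signed_error),
               variance = if (n >= 2) stats::var(e$observed_distance) else NA_real_,
               n = n, variance_defined = n >= 2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Angle error between rigid-body direction vectors
#'
#' The complement of the length-preservation check: a rigid motion also
#' preserves angles between direction vectors within the body. For each
#' configured pair of vectors (each a (from, to) keypoint pair), reports the
#' absolute difference in degrees between the reconstructed and ground-truth
#' angle, per frame.
#'
#' @param series A `pose3d_series`.
#' @param spec A `test_object_spec`.
#' @param vector_pairs List of pairs of character 2-vectors, e.g.
#'   `list(list(c("origin","X"), c("origin","Y")))`. Default: all pairs of
#'   rod vectors from the first keypoint to each other keypoint.
#' @param config_class,config_id Labels copied onto every record.
#' @return Error table with `metric = "angle"`; `abs_error` in degrees.
#'   Frames with an invalid endpoint or a zero-length observed vector are
#'   skipped.
#' @export
angle_error <- function(series, spec, vector_pairs = NULL,
                        config_class = NA_character_,
                        config_id = NA_character_) {
  kn <- names(spec$keypoints)
  if (is.null(vector_pairs)) {
    root <- kn[1]
    vecs <- lapply(kn[-1], function(k) c(root, k))
    if (length(vecs) < 2) stop("need at least two vectors for angle error")
    idx <- utils::combn(length(vecs), 2)
    vector_pairs <- lapply(seq_len(ncol(idx)), function(j) {
      list(vecs[[idx[1, j]]], vecs[[idx[2, j]]])
    })
  }
  ok <- series[series$valid, , drop = FALSE]
  key <- paste(ok$frame, ok$keypoint, sep = "\r")
  coord <- cbind(ok$x, ok$y, ok$z)
  frames <- sort(unique(series$frame))
  ang <- function(v1, v2) {
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0) return(NA_real_)
    acos(min(1, max(-1, sum(v1 * v2) / (n1 * n2)))) * 180 / pi
  }
  rows <- list()
  for (vp in vector_pairs) {
    v1 <- vp[[1]]; v2 <- vp[[2]]
    if (!all(c(v1, v2) %in% kn)) stop("vector endpoints must be spec keypoints")
    gt <- ang(spec$keypoints[[v1[2]]] - spec$keypoints[[v1[1]]],
              spec$keypoints[[v2[2]]] - spec$keypoints[[v2[1]]])
    item <- paste0(v1[1], ">", v1[2], "|", v2[1], ">", v2[2])
    for (f in frames) {
      i <- match(paste(f, c(v1, v2), sep = "\r"), key)
      if (anyNA(i)) next
      o <- ang(coord[i[2], ] - coord[i[1], ], coord[i[4], ] - coord[i[3], ])
      if (is.na(o)) next
      rows[[length(rows) + 1L]] <- data.frame(
        frame = f, item = item, config_class = config_class,
        config_id = config_id, signed_error = o - gt,
        abs_error = abs(o - gt), metric = "angle", stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else empty_error_table()
}

#' Boxplot summary with 1.5-IQR whiskers
#'
#' Quartiles by linear interpolation between order statistics; whiskers at
#' Q1 - 1.5 IQR and Q3 + 1.5 IQR, clipped to the most extreme data values
#' inside those fences. Values beyond the fences are counted as outliers and
#' excluded from whisker placement.
#'
#' @param values Numeric vector (n >= 1, NAs dropped).
#' @return List of class `boxplot_stats`: `Q0`, `Q1`, `median`, `Q3`, `Q4`,
#'   `IQR`, `n`, `n_outliers`.
#' @export
boxplot_stats <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("boxplot_stats needs at least one value")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  structure(list(
    Q0 = min(values[inside]), Q1 = q[1], median = q[2], Q3 = q[3],
    Q4 = max(values[inside]), IQR = iqr, n = length(values),
    n_outliers = sum(!inside)
  ), class = "boxplot_stats")
}

#' @export
print.boxplot_stats <- function(x, ...) {
  cat(sprintf("<boxplot_stats> n=%d  Q0=%.4g Q1=%.4g median=%.4g Q3=%.4g Q4=%.4g  (%d outliers)\n",
              x$n, x$Q0, x$Q1, x$median, x$Q3, x$Q4, x$n_outliers))
  invisible(x)
}

# Spearman rank correlation with tie-averaged ranks and a large-n normal
# approximation for the p-value.
spearman_rho <- function(x, y) {
  n <- length(x)
  rho <- stats::cor(rank(x), rank(y))
  z <- rho * sqrt(n - 1)
  list(rho = rho, p_value = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Error versus distance from the image centre
#'
#' Pairs each error record with the mean — over the camera views in which
#' its keypoint(s) were observed — of the pixel distance between the
#' observation midpoint and that camera's principal point, then reports the
#' Spearman rank correlation between error magnitude and that distance.
#' Observations whose covariate exceeds `border_threshold` are counted as
#' beyond the usable field border.
#'
#' @param errors An error table (inter-keypoint pairs or per-keypoint
#'   deviations).
#' @param detections The detection table the errors derive from.
#' @param rig The rig calibration (for principal points).
#' @param border_threshold Field-border flag threshold, px (default 486).
#' @param view_mode `"mean"` (average over contributing views, default) or
#'   `"worst"` (maximum single-view distance).
#' @return List of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `border_threshold`, `n_flagged_beyond_border`.
#' @export
error_vs_image_center <- function(errors, detections, rig,
                                  border_threshold = 486,
                                  view_mode = c("mean", "worst")) {
  view_mode <- match.arg(view_mode)
  det <- detections[!detections$missing, , drop = FALSE]
  pp <- lapply(rig$cameras, function(cm) {
    c(cm$intrinsics$principal_u, cm$intrinsics$principal_v)
  })
  dkey <- paste(det$frame, det$camera_id, det$keypoint, sep = "\r")
  ids <- rig_camera_ids(rig)
  covariate <- rep(NA_real_, nrow(errors))
  for (i in seq_len(nrow(errors))) {
    kps <- if (errors$metric[i] == "interkeypoint") {
      strsplit(errors$item[i], "-", fixed = TRUE)[[1]]
    } else errors$item[i]
    dists <- numeric(0)
    for (cid in ids) {
      j <- match(paste(errors$frame[i], cid, kps, sep = "\r"), dkey)
      if (anyNA(j)) next
      mid <- c(mean(det$u[j]), mean(det$v[j]))
      dists <- c(dists, sqrt(sum((mid - pp[[cid]])^2)))
    }
    if (length(dists)) {
      covariate[i] <- if (view_mode == "mean") mean(dists) else max(dists)
    }
  }
  use <- !is.na(covariate) & !is.na(errors$abs_error)
  if (sum(use) < 3) stop("fewer than 3 usable error/position pairs")
  sp <- spearman_rho(covariate[use], errors$abs_error[use])
  structure(list(rho = sp$rho, p_value = sp$p_value, n = sp$n,
                 border_threshold = border_threshold,
                 n_flagged_beyond_border = sum(covariate[use] > border_threshold)),
            class = "correlation_result")
}

# Parse "2s" / "2s+b" symmetry-class labels into factors for the ANOVA.
parse_class_label <- function(cls) {
  m <- regmatches(cls, regexec("^([0-9]+)s(\\+b)?$", cls))
  n_side <- vapply(m, function(x) as.integer(x[2]), integer(1))
  bottom <- vapply(m, function(x) !is.na(x[3]) && nzchar(x[3]), logical(1))
  data.frame(n_side = n_side, includes_bottom = bottom,
             n_cameras = n_side + bottom)
}

#' Two-way configuration ANOVA with Tukey post hoc comparisons
#'
#' Models absolute error as a function of camera number and configuration
#' (bottom camera included or not) with interaction, using type-II sums of
#' squares; pairwise symmetry-class differences are assessed with Tukey's
#' HSD (studentized-range adjustment). When the camera-number x bottom
#' design has empty cells (as it must when the full rig's class is
#' included), the interaction is dropped and a main-effects model is fitted
#' with a warning.
#'
#' @param errors An error table with `config_class` labels (at least 2
#'   levels of camera number and of bottom inclusion).
#' @return List of class `anova_result`: `F_camera_number`,
#'   `F_configuration`, `F_interaction`, matching `p_*` values,
#'   `tukey_table` (group_a, group_b, mean_difference mm, adjusted_p),
#'   `interaction_estimable`.
#' @export
config_anova <- function(errors) {
  if (any(is.na(errors$config_class))) {
    errors <- errors[!is.na(errors$config_class), , drop = FALSE]
  }
  fac <- parse_class_label(errors$config_class)
  d <- data.frame(abs_error = errors$abs_error,
                  camera_number = factor(fac$n_cameras),
                  bottom = factor(ifelse(fac$includes_bottom, "bottom",
                                         "no_bottom")),
                  class = factor(errors$config_class))
  if (nlevels(d$camera_number) < 2 || nlevels(d$bottom) < 2) {
    stop("config_anova needs >= 2 levels of camera number and configuration")
  }
  cells <- table(d$camera_number, d$bottom)
  estimable <- all(cells > 0)
  if (estimable) {
    fit <- stats::lm(abs_error ~ camera_number * bottom, data = d)
    tab <- car::Anova(fit, type = 2)
    F_int <- tab["camera_number:bottom", "F value"]
    p_int <- tab["camera_number:bottom", "Pr(>F)"]
  } else {
    warning("empty cells in camera_number x configuration design; ",
            "fitting main effects only")
    fit <- stats::lm(abs_error ~ camera_number + bottom, data = d)
    tab <- car::Anova(fit, type = 2)
    F_int <- NA_real_
    p_int <- NA_real_
  }
  tk <- stats::TukeyHSD(stats::aov(abs_error ~ class, data = d))$class
  groups <- strsplit(rownames(tk), "-", fixed = TRUE)
  tukey_table <- data.frame(
    group_a = vapply(groups, `[`, character(1), 1),
    group_b = vapply(groups, `[`, character(1), 2),
    mean_difference = unname(tk[, "diff"]),
    adjusted_p = unname(tk[, "p adj"]),
    stringsAsFactors = FALSE
  )
  structure(list(
    F_camera_number = tab["camera_number", "F value"],
    p_camera_number = tab["camera_number", "Pr(>F)"],
    F_configuration = tab["bottom", "F value"],
    p_configuration = tab["bottom", "Pr(>F)"],
    F_interaction = F_int, p_interaction = p_int,
    interaction_estimable = estimable,
    tukey_table = tukey_table
  ), class = "anova_result")
}
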