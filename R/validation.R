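# Orchestration: run every camera-subset configuration through
# reconstruction and the full statistics suite, and emit a report.

utils::globalVariables(c("config_class", "abs_error"))

#' Median temporal filter for 2D detections
#'
#' Running-median smoothing of each (camera, keypoint) pixel trajectory,
#' offered as the filtering slot for before/after comparisons. Missing
#' detections are left untouched and do not contribute to neighbours'
#' windows.
#'
#' @param detections A detection table.
#' @param window Odd window length in frames (default 3).
#' @return Filtered detection table.
#' @export
median_filter_detections <- function(detections, window = 3) {
  stopifnot(window >= 1, window %% 2 == 1)
  if (window == 1) return(detections)
  half <- (window - 1) / 2
  out <- detections
  groups <- split(seq_len(nrow(detections)),
                  paste(detections$camera_id, detections$keypoint, sep = "\r"))
  for (g in groups) {
    g <- g[order(detections$frame[g])]
    u <- detections$u[g]; v <- detections$v[g]
    ok <- !detections$missing[g]
    n <- length(g)
    fu <- u; fv <- v
    for (i in which(ok)) {
      w <- seq(max(1, i - half), min(n, i + half))
      w <- w[ok[w]]
      fu[i] <- stats::median(u[w])
      fv[i] <- stats::median(v[w])
    }
    out$u[g] <- fu
    out$v[g] <- fv
  }
  out
}

#' Run the full rig-validation analysis
#'
#' For every camera-subset symmetry class: triangulate, compute
#' inter-keypoint distance errors (and optionally rigid angle errors),
#' summarise with boxplot statistics and bias/variance. When a reference
#' configuration is named (default: the full rig), per-class deviation from
#' that reference is computed, the error-versus-image-centre Spearman
#' correlation is evaluated on the reference configuration's errors, and a
#' camera-configuration ANOVA with Tukey post hoc comparisons is run on the
#' deviations.
#'
#' @param rig A `rig_calibration`.
#' @param detections A detection table.
#' @param spec A `test_object_spec`.
#' @param bottom_id Bottom-camera id (default: the rig's `"bottom_id"`
#'   attribute, else the last camera).
#' @param reference `"full"` (default) to use the full rig as the deviation
#'   standard, `NULL` to skip deviation analysis, or a character vector of
#'   camera ids.
#' @param confidence_threshold,min_views Passed to [triangulate_series()].
#' @param angle_errors Also compute rigid angle errors per class (default
#'   FALSE).
#' @param filter `"none"` (default) or `"median"` 2D pre-filter.
#' @param filter_window Window for the median filter.
#' @param refine Nonlinear triangulation refinement (default TRUE).
#' @return List of class `validation_report`; see Details.
#' @details The report contains `classes` (per symmetry class: boxplot
#'   stats of absolute inter-keypoint error, bias/variance per pair,
#'   coverage, n, deviation boxplot stats when a reference is set),
#'   `spearman` (a `correlation_result`), `anova` (an `anova_result` over
#'   deviations, when a reference is set and >= 2 factor levels exist), and
#'   `configs` (the enumeration table).
#' @export
run_validation <- function(rig, detections, spec,
                           bottom_id = NULL, reference = "full",
                           confidence_threshold = 0.5, min_views = 2,
                           angle_errors = FALSE,
                           filter = c("none", "median"), filter_window = 3,
                           refine = TRUE) {
  filter <- match.arg(filter)
  if (is.null(bottom_id)) {
    bottom_id <- attr(rig, "bottom_id")
    if (is.null(bottom_id)) bottom_id <- rev(rig_camera_ids(rig))[1]
  }
  if (filter == "median") {
    detections <- median_filter_detections(detections, filter_window)
  }
  configs <- enumerate_configs(rig, bottom_id)
  all_ids <- rig_camera_ids(rig)

  ref_ids <- NULL
  if (identical(reference, "full")) ref_ids <- all_ids
  else if (is.character(reference)) ref_ids <- reference

  series_by_config <- lapply(seq_len(nrow(configs)), function(i) {
    triangulate_series(rig, detections, subset = configs$members[[i]],
                       min_views = min_views,
                       confidence_threshold = confidence_threshold,
                       refine = refine)
  })
  names(series_by_config) <- configs$config_id

  ref_series <- NULL
  if (!is.null(ref_ids)) {
    ref_key <- paste(sort(ref_ids), collapse = ",")
    hit <- match(ref_key, vapply(configs$members, function(m) {
      paste(sort(m), collapse = ",")
    }, character(1)))
    ref_series <- if (!is.na(hit)) series_by_config[[hit]] else
      triangulate_series(rig, detections, subset = ref_ids,
                         min_views = min_views,
                         confidence_threshold = confidence_threshold,
                         refine = refine)
  }

  classes <- unique(configs$symmetry_class)
  class_results <- list()
  ik_all <- list()
  dev_all <- list()
  for (cl in classes) {
    in_cl <- which(configs$symmetry_class == cl)
    ik <- list(); dev <- list(); ang <- list(); cov <- numeric(0)
    for (i in in_cl) {
      s <- series_by_config[[i]]
      e <- interkeypoint_error(s, spec, config_class = cl,
                               config_id = configs$config_id[i])
      cov <- c(cov, attr(e, "coverage"))
      ik[[length(ik) + 1L]] <- e
      if (angle_errors) {
        ang[[length(ang) + 1L]] <- angle_error(s, spec, config_class = cl,
                                               config_id = configs$config_id[i])
      }
      if (!is.null(ref_series)) {
        dev[[length(dev) + 1L]] <- deviation_from_reference(
          s, ref_series, config_class = cl, config_id = configs$config_id[i])
      }
    }
    ik <- do.call(rbind, ik)
    ik_all[[cl]] <- ik
    res <- list(
      symmetry_class = cl,
      n_configs = length(in_cl),
      n = nrow(ik),
      coverage = mean(cov),
      boxplot = if (nrow(ik)) boxplot_stats(ik$abs_error) else NULL,
      bias_variance = if (nrow(ik)) bias_variance(ik) else NULL
    )
    if (angle_errors) {
      a <- do.call(rbind, ang)
      res$angle_boxplot <- if (nrow(a)) boxplot_stats(a$abs_error) else NULL
    }
    if (!is.null(ref_series)) {
      dv <- do.call(rbind, dev)
      dev_all[[cl]] <- dv
      res$deviation_boxplot <- if (nrow(dv)) boxplot_stats(dv$abs_error) else NULL
      res$deviation_n <- nrow(dv)
    }
    class_results[[cl]] <- res
  }

  report <- list(classes = class_results, configs = configs,
                 reference = ref_ids, bottom_id = bottom_id,
                 filter = filter)

  # Spearman error-vs-image-centre on the reference (or full-rig) errors
  ref_errors <- if (!is.null(ref_series)) {
    interkeypoint_error(ref_series, spec)
  } else do.call(rbind, ik_all)
  report$spearman <- tryCatch(
    error_vs_image_center(ref_errors, detections, rig),
    error = function(e) NULL)

  if (length(dev_all)) {
    dv <- do.call(rbind, dev_all)
    # the reference class deviates from itself by 0; only proper subsets
    # enter the configuration comparison
    ref_cls <- configs$symmetry_class[match(
      paste(sort(ref_ids), collapse = ","),
      vapply(configs$members, function(m) paste(sort(m), collapse = ","),
             character(1)))]
    dv_sub <- dv[is.na(ref_cls) | dv$config_class != ref_cls, , drop = FALSE]
    report$anova <- tryCatch(config_anova(dv_sub), error = function(e) NULL,
                             warning = function(w) {
                               suppressWarnings(config_anova(dv_sub))
                             })
    report$deviations <- dv
  }
  report$interkeypoint_errors <- do.call(rbind, ik_all)
  class(report) <- "validation_report"
  report
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", length(x$classes), " symmetry classes\n", sep = "")
  for (cl in names(x$classes)) {
    r <- x$classes[[cl]]
    med <- if (!is.null(r$boxplot)) sprintf("%.4g", r$boxplot$median) else "NA"
    cat(sprintf("  %-6s n=%-6d median |interkeypoint error| = %s mm\n",
                cl, r$n, med))
  }
  if (!is.null(x$spearman)) {
    cat(sprintf("  Spearman error vs image centre: rho=%.3f p=%.3g (n=%d)\n",
                x$spearman$rho, x$spearman$p_value, x$spearman$n))
  }
  if (!is.null(x$anova)) {
    cat(sprintf("  ANOVA: F(camera number)=%.3g F(configuration)=%.3g F(interaction)=%s\n",
                x$anova$F_camera_number, x$anova$F_configuration,
                ifelse(is.na(x$anova$F_interaction), "n/a",
                       sprintf("%.3g", x$anova$F_interaction))))
  }
  invisible(x)
}

#' Serialize a validation report to JSON
#' @param report A `validation_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(r) {
    out <- list(symmetry_class = r$symmetry_class, n_configs = r$n_configs,
                n = r$n, coverage = r$coverage)
    if (!is.null(r$boxplot)) out$interkeypoint_boxplot <- unclass(r$boxplot)
    if (!is.null(r$bias_variance)) out$bias_variance <- r$bias_variance
    if (!is.null(r$angle_boxplot)) out$angle_boxplot <- unclass(r$angle_boxplot)
    if (!is.null(r$deviation_boxplot)) {
      out$deviation_boxplot <- unclass(r$deviation_boxplot)
      out$deviation_n <- r$deviation_n
    }
    out
  }
  obj <- list(
    classes = lapply(report$classes, strip),
    reference = report$reference,
    bottom_id = report$bottom_id,
    filter = report$filter
  )
  if (!is.null(report$spearman)) obj$spearman <- unclass(report$spearman)
  if (!is.null(report$anova)) {
    a <- unclass(report$anova)
    obj$anova <- a
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Boxplot figure of per-class absolute errors
#'
#' Mirrors the per-configuration boxplot layout used to compare camera
#' subsets: one box per symmetry class, whiskers at the 1.5-IQR fences,
#' outliers hidden.
#'
#' @param report A `validation_report`.
#' @param metric `"interkeypoint"` or `"deviation"`.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_error_boxplots <- function(report, metric = c("interkeypoint",
                                                   "deviation")) {
  metric <- match.arg(metric)
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_error_boxplots requires the ggplot2 package")
  }
  d <- if (metric == "interkeypoint") report$interkeypoint_errors else
    report$deviations
  if (is.null(d) || !nrow(d)) stop("no data for metric ", metric)
  ggplot2::ggplot(d, ggplot2::aes(x = config_class, y = abs_error)) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = NA) +
    ggplot2::coord_cartesian(ylim = c(0, stats::quantile(d$abs_error, 0.95))) +
    ggplot2::labs(x = "camera configuration (symmetry class)",
                  y = if (metric == "interkeypoint")
                    "absolute inter-keypoint distance error (mm)"
                  else "deviation from reference (mm)")
}
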