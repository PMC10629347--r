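# Validation statistics: configuration enumeration, error metrics,
# bias/variance, boxplot summaries, Spearman correlation, ANOVA.

test_that("a 3-side + bottom rig enumerates 11 subsets in 5 symmetry classes", {
  rig <- build_rig(arena_preset("small"))
  cfg <- enumerate_configs(rig, "cam_3")
  expect_equal(nrow(cfg), 11)  # 6 pairs + 4 triples + 1 quad
  expect_equal(sum(cfg$n_cameras == 2), 6)
  expect_equal(sum(cfg$n_cameras == 3), 4)
  expect_equal(sum(cfg$n_cameras == 4), 1)
  # pairs: 3 of (2 side) and 3 of (1 side + bottom)
  pair_cls <- table(cfg$symmetry_class[cfg$n_cameras == 2])
  expect_equal(as.vector(pair_cls[c("2s", "1s+b")]), c(3L, 3L))
  # triples: 1 of (3 side), 3 of (2 side + bottom)
  tri_cls <- table(cfg$symmetry_class[cfg$n_cameras == 3])
  expect_equal(as.vector(tri_cls[c("3s", "2s+b")]), c(1L, 3L))
  expect_setequal(unique(cfg$symmetry_class),
                  c("2s", "1s+b", "3s", "2s+b", "3s+b"))
  expect_error(enumerate_configs(rig, "nope"), "unknown bottom")
})

series_from_points <- function(points_by_frame) {
  rows <- lapply(seq_along(points_by_frame), function(f) {
    P <- points_by_frame[[f]]
    data.frame(frame = f - 1L, keypoint = rownames(P),
               x = P[, 1], y = P[, 2], z = P[, 3],
               n_cameras_used = 4L, reprojection_rms = 0, valid = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("pose3d_series", "data.frame")
  out
}

test_that("inter-keypoint error is zero at truth and scales with similarity", {
  spec <- make_xyz_object()
  W <- place_object(spec, rigid_pose(random_rotation(), c(2, 1, -3)))
  s <- series_from_points(list(W, W))
  e <- interkeypoint_error(s, spec)
  expect_true(all(abs(e$signed_error) < 1e-9))
  expect_equal(attr(e, "coverage"), 1)
  # scaling by 1.01 about any centre inflates every distance by 1%
  center <- c(10, -5, 2)
  W2 <- sweep(sweep(W, 2, center), 2, rep(1, 3), "*") * 1.01
  W2 <- sweep(W2, 2, center, "+")
  e2 <- interkeypoint_error(series_from_points(list(W2)), spec)
  gtd <- ground_truth_distances(spec)
  gd <- gtd$distance[match(e2$item, paste(gtd$keypoint_a, gtd$keypoint_b,
                                          sep = "-"))]
  expect_equal(e2$signed_error, 0.01 * gd, tolerance = 1e-9)
})

test_that("inter-keypoint error matches a brute-force norm oracle", {
  spec <- make_xyz_object()
  set.seed(41)
  W <- place_object(spec, rigid_pose())
  Wp <- W + matrix(rnorm(length(W), 0, 0.5), nrow(W))
  e <- interkeypoint_error(series_from_points(list(Wp)), spec)
  gtd <- ground_truth_distances(spec)
  for (i in seq_len(nrow(gtd))) {
    a <- gtd$keypoint_a[i]; b <- gtd$keypoint_b[i]
    oracle <- sqrt(sum((Wp[a, ] - Wp[b, ])^2)) - gtd$distance[i]
    expect_equal(e$signed_error[e$item == paste(a, b, sep = "-")], oracle,
                 tolerance = 1e-12)
  }
  # frames with an invalid endpoint are excluded and counted in coverage
  s <- series_from_points(list(Wp, Wp))
  s$valid[s$frame == 1 & s$keypoint == "X"] <- FALSE
  e2 <- interkeypoint_error(s, spec)
  expect_equal(attr(e2, "coverage"), (6 + 3) / 12)
})

test_that("deviation from reference is the per-keypoint Euclidean distance", {
  spec <- make_xyz_object()
  W <- place_object(spec, rigid_pose())
  ref <- series_from_points(list(W, W))
  # self-comparison: exactly zero everywhere
  dev0 <- deviation_from_reference(ref, ref)
  expect_true(all(dev0$abs_error == 0))
  # 3-4-5 translation: every deviation is 5 mm
  shifted <- series_from_points(list(W + matrix(c(3, 4, 0), nrow(W), 3,
                                                byrow = TRUE)))
  dev <- deviation_from_reference(shifted, ref)
  expect_equal(dev$abs_error, rep(5, nrow(dev)))
  # random perturbation agrees with a direct norm oracle
  set.seed(43)
  Wp <- W + matrix(rnorm(length(W)), nrow(W))
  devp <- deviation_from_reference(series_from_points(list(Wp)), ref)
  for (i in seq_len(nrow(devp))) {
    kp <- devp$item[i]
    expect_equal(devp$abs_error[i], sqrt(sum((Wp[kp, ] - W[kp, ])^2)),
                 tolerance = 1e-12)
  }
})

test_that("bias and variance decompose repeated distance measurements", {
  spec <- make_xyz_object()
  W <- place_object(spec, rigid_pose())
  # constant +2 mm on every distance: scale radially from the centroid is
  # messy; instead perturb the series so one pair has known offsets
  gtd <- ground_truth_distances(spec)
  # hand-built 5-row toy table
  toy <- data.frame(frame = 0:4, item = "origin-X", config_class = NA,
                    config_id = NA,
                    signed_error = c(1.5, 2.0, 2.5, 1.8, 2.2),
                    abs_error = c(1.5, 2.0, 2.5, 1.8, 2.2),
                    metric = "interkeypoint",
                    observed_distance = 40 + c(1.5, 2.0, 2.5, 1.8, 2.2))
  bv <- bias_variance(toy)
  expect_equal(bv$bias, mean(toy$signed_error))
  expect_equal(bv$variance, var(toy$observed_distance))
  expect_true(bv$variance_defined)
  # constant offset: bias = offset, variance = 0
  toy2 <- toy
  toy2$signed_error <- 2
  toy2$observed_distance <- 42
  bv2 <- bias_variance(toy2)
  expect_equal(bv2$bias, 2)
  expect_equal(bv2$variance, 0)
  # sampling distribution: zero-mean Gaussian sigma = 1 mm, n = 1e4
  set.seed(47)
  n <- 1e4
  noise <- rnorm(n, 0, 1)
  big <- data.frame(frame = seq_len(n) - 1, item = "origin-X",
                    config_class = NA, config_id = NA,
                    signed_error = noise, abs_error = abs(noise),
                    metric = "interkeypoint", observed_distance = 40 + noise)
  bvb <- bias_variance(big)
  expect_lt(abs(bvb$bias), 0.03)
  expect_gt(bvb$variance, 0.95)
  expect_lt(bvb$variance, 1.05)
  # single observation: variance undefined and flagged
  bv1 <- bias_variance(toy[1, ])
  expect_false(bv1$variance_defined)
})

test_that("angle errors vanish at truth and match an arccos oracle", {
  spec <- make_xyz_object()
  W <- place_object(spec, rigid_pose(random_rotation(), c(1, 2, 3)))
  s <- series_from_points(list(W))
  a <- angle_error(s, spec)
  expect_true(all(a$abs_error < 1e-6))
  # X and Y rods are perpendicular in ground truth
  gt_xy <- 90
  set.seed(51)
  Wp <- W + matrix(rnorm(length(W), 0, 1), nrow(W))
  ap <- angle_error(series_from_points(list(Wp)), spec,
                    vector_pairs = list(list(c("origin", "X"),
                                             c("origin", "Y"))))
  v1 <- Wp["X", ] - Wp["origin", ]
  v2 <- Wp["Y", ] - Wp["origin", ]
  obs <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  expect_equal(ap$abs_error, abs(obs - gt_xy), tolerance = 1e-9)
})

test_that("boxplot statistics match the sorted-interpolation oracle", {
  x <- as.numeric(1:100)
  bs <- boxplot_stats(x)
  expect_equal(bs$Q1, quartile_oracle(x, 0.25))
  expect_equal(bs$median, quartile_oracle(x, 0.5))
  expect_equal(bs$Q3, quartile_oracle(x, 0.75))
  expect_equal(bs$IQR, bs$Q3 - bs$Q1)
  expect_equal(bs$n_outliers, 0)
  expect_equal(bs$Q0, 1); expect_equal(bs$Q4, 100)
  # constant vector: everything collapses
  bc <- boxplot_stats(rep(3.2, 10))
  expect_true(all(c(bc$Q0, bc$Q1, bc$median, bc$Q3, bc$Q4) == 3.2))
  expect_equal(bc$IQR, 0)
  # appending a far outlier increments the count and leaves Q4 at the
  # largest non-outlier
  y <- c(x, 1000)
  by <- boxplot_stats(y)
  expect_equal(by$n_outliers, 1)
  expect_equal(by$Q4, 100)
  expect_lt(by$Q4, by$Q3 + 1.5 * by$IQR + 1e-12)
  # random instances against the oracle
  set.seed(53)
  for (i in 1:10) {
    z <- rexp(sample(5:200, 1))
    bz <- boxplot_stats(z)
    expect_equal(bz$Q1, quartile_oracle(z, 0.25), tolerance = 1e-12)
    expect_equal(bz$median, quartile_oracle(z, 0.5), tolerance = 1e-12)
    expect_equal(bz$Q3, quartile_oracle(z, 0.75), tolerance = 1e-12)
  }
  expect_error(boxplot_stats(numeric(0)), "at least one")
})

test_that("spearman correlation matches the rank-Pearson oracle and cor.test", {
  set.seed(57)
  # ties included
  x <- round(runif(50, 0, 10), 1)
  y <- round(x + rnorm(50, 0, 3), 1)
  sp <- spearman_rho(x, y)
  expect_equal(sp$rho, spearman_oracle(x, y), tolerance = 1e-12)
  expect_equal(sp$rho,
               suppressWarnings(cor.test(x, y, method = "spearman")$estimate[[1]]),
               tolerance = 1e-12)
  # perfect monotone relation
  expect_equal(spearman_rho(1:20, (1:20)^3)$rho, 1)
})

test_that("error_vs_image_center detects monotone structure and respects the null", {
  spec <- make_xyz_object()
  rig <- build_rig(arena_preset("small"))
  sim <- noiseless_session(n_frames = 30)
  s <- triangulate_series(sim$rig, sim$detections)
  e <- interkeypoint_error(s, sim$spec)
  det <- sim$detections
  # plant: error equal to the covariate gives rho = 1
  res0 <- error_vs_image_center(e, det, sim$rig)
  # recompute the covariate independently to plant a perfectly monotone error
  cov <- numeric(nrow(e))
  for (i in seq_len(nrow(e))) {
    kps <- strsplit(e$item[i], "-", fixed = TRUE)[[1]]
    dists <- c()
    for (cid in rig_camera_ids(sim$rig)) {
      d2 <- det[det$frame == e$frame[i] & det$camera_id == cid &
                  det$keypoint %in% kps & !det$missing, ]
      if (nrow(d2) == 2) {
        cm <- sim$rig$cameras[[cid]]
        dists <- c(dists, sqrt((mean(d2$u) - cm$intrinsics$principal_u)^2 +
                                 (mean(d2$v) - cm$intrinsics$principal_v)^2))
      }
    }
    cov[i] <- mean(dists)
  }
  e_planted <- e
  e_planted$abs_error <- cov
  res1 <- error_vs_image_center(e_planted, det, sim$rig)
  expect_equal(res1$rho, 1, tolerance = 1e-9)
  # null: error independent of position
  set.seed(59)
  e_null <- e[rep(seq_len(nrow(e)), length.out = 2000), ]
  e_null$abs_error <- rexp(2000)
  res2 <- error_vs_image_center(e_null, det, sim$rig)
  expect_lt(abs(res2$rho), 0.06)
  # border flags count covariates beyond the threshold
  res3 <- error_vs_image_center(e_planted, det, sim$rig,
                                border_threshold = median(cov))
  expect_equal(res3$n_flagged_beyond_border, sum(cov > median(cov)))
  expect_error(error_vs_image_center(e[1:2, ], det, sim$rig), "fewer than 3")
})

simulate_error_table <- function(n_per_cell, means, sd = 2) {
  classes <- names(means)
  do.call(rbind, lapply(classes, function(cl) {
    data.frame(frame = seq_len(n_per_cell) - 1, item = "kp",
               config_class = cl, config_id = cl,
               signed_error = NA_real_,
               abs_error = abs(rnorm(n_per_cell, means[[cl]], sd)),
               metric = "reference_deviation", stringsAsFactors = FALSE)
  }))
}

test_that("config_anova type-II F values match a nested-RSS oracle", {
  set.seed(61)
  tab <- simulate_error_table(80, c("2s" = 3, "1s+b" = 2.5,
                                    "3s" = 2, "2s+b" = 1.5))
  res <- config_anova(tab)
  fac <- parse_class_label(tab$config_class)
  oracle <- type2_anova_oracle(tab$abs_error, fac$n_cameras,
                               fac$includes_bottom)
  expect_equal(res$F_camera_number, oracle$F_a, tolerance = 1e-9)
  expect_equal(res$F_configuration, oracle$F_b, tolerance = 1e-9)
  expect_equal(res$F_interaction, oracle$F_ab, tolerance = 1e-9)
  expect_true(res$interaction_estimable)
  # Tukey mean differences match direct group means
  m2s <- mean(tab$abs_error[tab$config_class == "2s"])
  m3s <- mean(tab$abs_error[tab$config_class == "3s"])
  row <- res$tukey_table[(res$tukey_table$group_a == "3s" &
                            res$tukey_table$group_b == "2s") |
                           (res$tukey_table$group_a == "2s" &
                              res$tukey_table$group_b == "3s"), ]
  expect_equal(abs(row$mean_difference), abs(m3s - m2s), tolerance = 1e-9)
})

test_that("config_anova drops the interaction when the design has empty cells", {
  set.seed(63)
  # include the full rig's class: camera_number 4 exists only with bottom
  tab <- simulate_error_table(40, c("2s" = 2, "1s+b" = 2, "3s" = 2,
                                    "2s+b" = 2, "3s+b" = 2))
  expect_warning(res <- config_anova(tab), "empty cells")
  expect_true(is.na(res$F_interaction))
  expect_false(res$interaction_estimable)
  expect_false(is.na(res$F_camera_number))
})

test_that("a planted camera-number shift is detected by ANOVA and Tukey", {
  set.seed(65)
  tab <- simulate_error_table(200, c("2s" = 12, "1s+b" = 12,
                                     "3s" = 2, "2s+b" = 2), sd = 2)
  res <- config_anova(tab)
  expect_gt(res$F_camera_number, 100)
  expect_lt(res$p_camera_number, 1e-6)
  two_vs_three <- res$tukey_table[
    xor(res$tukey_table$group_a %in% c("2s", "1s+b"),
        res$tukey_table$group_b %in% c("2s", "1s+b")), ]
  expect_true(all(two_vs_three$adjusted_p < 0.001))
  expect_true(all(abs(two_vs_three$mean_difference) > 5))
})

test_that("report statistics are invariant to frame relabeling and keypoint order", {
  spec <- make_xyz_object()
  set.seed(67)
  W <- place_object(spec, rigid_pose())
  frames <- lapply(1:8, function(i) W + matrix(rnorm(length(W), 0, 0.3),
                                               nrow(W)))
  s <- series_from_points(frames)
  e1 <- interkeypoint_error(s, spec)
  # permute rows (keypoint order within frames, frame order globally)
  s2 <- s[sample(nrow(s)), ]
  e2 <- interkeypoint_error(s2, spec)
  expect_equal(sort(e1$abs_error), sort(e2$abs_error))
  b1 <- boxplot_stats(e1$abs_error)
  b2 <- boxplot_stats(e2$abs_error)
  expect_equal(b1, b2)
  # relabeling frames shifts nothing
  s3 <- s
  s3$frame <- s3$frame + 1000L
  e3 <- interkeypoint_error(s3, spec)
  expect_equal(sort(e1$abs_error), sort(e3$abs_error))
})
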