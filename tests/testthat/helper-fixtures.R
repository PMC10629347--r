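# Shared fixtures and independent brute-force oracles for the test suite.

# Simple unit-focal test camera: focal 1000, principal (640, 400), no skew.
simple_camera <- function(distortion = c(0, 0, 0, 0, 0),
                          rotation = diag(3), translation = c(0, 0, 0),
                          id = "test_cam") {
  camera(id,
         camera_intrinsics(focal_u = 1000, focal_v = 1000,
                           principal_u = 640, principal_v = 400,
                           distortion = distortion,
                           image_width = 1280, image_height = 800),
         camera_pose(rotation, translation))
}

# Two-camera stereo pair with a baseline along x, both looking down +z.
stereo_pair <- function(baseline = 100) {
  list(simple_camera(id = "left"),
       simple_camera(id = "right", translation = c(-baseline, 0, 0)))
}

random_rotation <- function() {
  nearest_rotation(matrix(stats::rnorm(9), 3))
}

# --- independent oracles ---

# Dense 2D grid search inverting the distortion map: finds the normalized
# (x, y) whose distorted image is closest to (xd, yd).
grid_search_undistort <- function(xd, yd, distortion, lim = 0.6, step = 1e-3) {
  g <- seq(-lim, lim, by = step)
  gx <- rep(g, times = length(g))
  gy <- rep(g, each = length(g))
  r2 <- gx^2 + gy^2
  d <- distortion
  radial <- 1 + d[1] * r2 + d[2] * r2^2 + d[5] * r2^3
  dx <- gx * radial + 2 * d[3] * gx * gy + d[4] * (r2 + 2 * gx^2)
  dy <- gy * radial + d[3] * (r2 + 2 * gy^2) + 2 * d[4] * gx * gy
  i <- which.min((dx - xd)^2 + (dy - yd)^2)
  c(gx[i], gy[i])
}

# Brute-force grid search for the 3D point minimising total squared pixel
# reprojection error around a centre point.
grid_search_triangulation <- function(cameras, uv, center, half = 3,
                                      step = 0.5) {
  g <- seq(-half, half, by = step)
  best <- NULL
  best_cost <- Inf
  for (dx in g) for (dy in g) for (dz in g) {
    X <- center + c(dx, dy, dz)
    cost <- 0
    for (i in seq_along(cameras)) {
      p <- project(cameras[[i]], X, on_behind = "na")
      if (anyNA(p)) { cost <- Inf; break }
      cost <- cost + sum((p - uv[i, ])^2)
    }
    if (cost < best_cost) { best_cost <- cost; best <- X }
  }
  list(point = best, cost = best_cost)
}

# Sorted linear-interpolation quartile oracle (matches the definition
# "linear interpolation between order statistics").
quartile_oracle <- function(values, p) {
  s <- sort(values)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Rank-then-Pearson Spearman oracle with tie-averaged ranks.
spearman_oracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Type-II two-way ANOVA F statistics from explicit nested-model residual
# sums of squares (independent of car).
type2_anova_oracle <- function(abs_error, camera_number, bottom,
                               interaction = TRUE) {
  d <- data.frame(y = abs_error, a = factor(camera_number), b = factor(bottom))
  rss <- function(formula) sum(stats::resid(stats::lm(formula, data = d))^2)
  full <- if (interaction) y ~ a * b else y ~ a + b
  rss_full <- rss(full)
  df_full <- nrow(d) - length(stats::coef(stats::lm(full, data = d)))
  mse <- rss_full / df_full
  # type II: each main effect adjusted for the other main effect
  F_a <- ((rss(y ~ b) - rss(y ~ a + b)) / (nlevels(d$a) - 1)) / mse
  F_b <- ((rss(y ~ a) - rss(y ~ a + b)) / (nlevels(d$b) - 1)) / mse
  out <- list(F_a = F_a, F_b = F_b)
  if (interaction) {
    df_int <- (nlevels(d$a) - 1) * (nlevels(d$b) - 1)
    out$F_ab <- ((rss(y ~ a + b) - rss_full) / df_int) / mse
  }
  out
}

# Small noiseless simulated session shared by several tests.
noiseless_session <- function(n_frames = 20, seed = 42) {
  simulate_session(n_frames = n_frames,
                   noise = noise_model(pixel_sigma = 0, p_miss = 0),
                   seed = seed)
}
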