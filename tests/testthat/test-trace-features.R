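# Feature extraction: depth correction, interpolation, smoothing, plane fit,
# and the four exploratory parameters on analytic paths.

test_that("depth correction recovers the calibration line", {
  # two-point exact line
  two <- data.frame(z_air_cm = c(0, 10), z_water_cm = c(0, 8))
  fit <- fit_depth_correction(two)
  expect_equal(fit$slope, 1.25)
  expect_equal(fit$intercept, 0)
  # noiseless pairs are recovered exactly
  cal <- generate_calibration(0.75, 1.0, n_points = 100, noise_sd = 0, seed = 2)
  fit <- fit_depth_correction(cal)
  expect_equal(fit$slope, 0.75, tolerance = 1e-12)
  expect_equal(fit$intercept, 1.0, tolerance = 1e-12)
  # identity map leaves z unchanged
  tr <- swim_trace(0:9, rep(1, 10), rep(1, 10), 1:10)
  id <- fit_depth_correction(generate_calibration(1, 0, 10, 0, seed = 1))
  expect_equal(apply_depth_correction(tr, id)$z, tr$z)
  # degenerate predictor
  expect_error(fit_depth_correction(data.frame(z_air_cm = c(1, 2), z_water_cm = c(3, 3))),
               "zero variance")
  expect_error(fit_depth_correction(data.frame(z_air_cm = 1, z_water_cm = 1)),
               "at least 2")
})

test_that("noisy calibration recovers the slope within OLS sampling error", {
  hits <- vapply(1:40, function(s) {
    cal <- generate_calibration(0.75, 1.0, n_points = 100, noise_sd = 0.1, seed = s)
    abs(fit_depth_correction(cal)$slope - 0.75) <= 0.02
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("missing z is interpolated linearly with nearest-value ends", {
  tr <- swim_trace(0:2, rep(0, 3), rep(0, 3), c(1, NA, 3))
  expect_equal(interpolate_missing_z(tr)$z, c(1, 2, 3))
  tr <- swim_trace(0:3, rep(0, 4), rep(0, 4), c(0, NA, NA, 3))
  expect_equal(interpolate_missing_z(tr)$z, c(0, 1, 2, 3))
  # ends take the nearest available value
  tr <- swim_trace(0:3, rep(0, 4), rep(0, 4), c(NA, 5, NA, NA))
  expect_equal(interpolate_missing_z(tr)$z, c(5, 5, 5, 5))
  # complete traces pass through unchanged
  tr <- swim_trace(0:2, 1:3, 1:3, 1:3)
  expect_identical(interpolate_missing_z(tr)$z, tr$z)
  expect_error(interpolate_missing_z(swim_trace(0:1, 0:1, 0:1, c(NA, NA))),
               "all z")
})

test_that("Savitzky-Golay smoothing preserves cubics and shrinks noise", {
  t <- seq(0, 1, length.out = 101)
  cubic <- 2 + 3 * t - t^2 + 0.5 * t^3
  tr <- swim_trace(t, cubic, cubic, cubic)
  sm <- smooth_trace(tr, window = 7, order = 3)
  interior <- 4:98
  expect_equal(sm$x[interior], cubic[interior], tolerance = 1e-10)
  # constant trace unchanged
  tr <- swim_trace(t, rep(1, 101), rep(2, 101), rep(3, 101))
  sm <- smooth_trace(tr)
  expect_equal(sm$x, rep(1, 101))
  expect_equal(sm$z, rep(3, 101))
  # white noise variance strictly reduced
  noisy <- fishclust:::with_seed(5, rnorm(500))
  tr <- swim_trace(seq_len(500), noisy, noisy, noisy)
  expect_lt(var(smooth_trace(tr)$x[4:497]), var(noisy[4:497]))
  expect_error(smooth_trace(swim_trace(1:5, 1:5, 1:5, 1:5), window = 7), "frames")
  expect_error(smooth_trace(tr, window = 6), "odd")
})

test_that("bottom plane fit is exact on noiseless planes and errors on degenerate input", {
  pts <- expand.grid(x = seq(0, 15, length.out = 20), y = seq(0, 15, length.out = 20))
  pts$z <- 0
  expect_equal(fit_bottom_plane(pts), c(0, 0, 1, 0), tolerance = 1e-12)
  pts$z <- 0.1 * pts$x + 0.2 * pts$y + 1
  pl <- fit_bottom_plane(pts)
  truth <- c(-0.1, -0.2, 1, -1) / sqrt(0.1^2 + 0.2^2 + 1)
  expect_equal(pl, truth, tolerance = 1e-12)
  # noisy plane: recovered normal within 1 degree
  set.seed(42)
  pts$z <- 0.1 * pts$x + 0.2 * pts$y + 1 + rnorm(400, 0, 0.05)
  pl <- fit_bottom_plane(pts)
  angle <- acos(sum(pl[1:3] * truth[1:3])) * 180 / pi
  expect_lt(angle, 1)
  line_pts <- cbind(x = 1:5, y = 2 * (1:5), z = 1:5)
  expect_error(fit_bottom_plane(line_pts), "collinear|degenerate")
})

test_that("bottom and center distance match plane and line geometry", {
  geom <- geom15()
  t <- 0:99 / 30
  tr <- swim_trace(t, rep(7.5, 100), rep(7.5, 100), rep(5, 100))
  expect_equal(bottom_distance(tr, geom), 5)
  expect_equal(center_distance(tr, geom), 0)
  # half at z=2, half at z=4
  tr <- swim_trace(t, rep(1, 100), rep(1, 100), rep(c(2, 4), each = 50))
  expect_equal(bottom_distance(tr, geom), 3)
  # corner edge is at sqrt(7.5^2 + 7.5^2)
  tr <- swim_trace(t, rep(0, 100), rep(0, 100), seq(0, 10, length.out = 100))
  expect_equal(center_distance(tr, geom), sqrt(2 * 7.5^2), tolerance = 1e-12)
  # tilted plane: distances match |ax + by + cz + d| analytically
  plane <- c(0.1, 0.2, 1, -0.5) / sqrt(0.1^2 + 0.2^2 + 1)
  geom_t <- tank_geometry(bottom_plane = c(0.1, 0.2, 1, -0.5))
  set.seed(3)
  xyz <- cbind(runif(50, 0, 15), runif(50, 0, 15), runif(50, 1, 11))
  tr <- swim_trace(seq_len(50), xyz[, 1], xyz[, 2], xyz[, 3])
  expected <- mean(abs(xyz %*% plane[1:3] + plane[4]))
  expect_equal(bottom_distance(tr, geom_t), expected, tolerance = 1e-12)
  # circle of radius 3 about the center line
  th <- seq(0, 2 * pi, length.out = 200)
  tr <- swim_trace(seq_along(th), 7.5 + 3 * cos(th), 7.5 + 3 * sin(th), rep(5, 200))
  expect_equal(center_distance(tr, geom), 3, tolerance = 1e-12)
})

test_that("distance travelled sums successive Euclidean steps", {
  tr <- swim_trace(0:1, c(0, 3), c(0, 4), c(0, 0))
  expect_equal(distance_travelled(tr), 5)
  # closed square of side 2 sampled at corners
  tr <- swim_trace(0:4, c(0, 2, 2, 0, 0), c(0, 0, 2, 2, 0), rep(0, 5))
  expect_equal(distance_travelled(tr), 8)
  tr <- swim_trace(0:9, rep(1, 10), rep(1, 10), rep(1, 10))
  expect_equal(distance_travelled(tr), 0)
})

test_that("percent explored counts unique voxels out of the configured grid", {
  geom <- geom15()
  tr <- swim_trace(0:9, rep(7.5, 10), rep(7.5, 10), rep(5, 10))
  expect_equal(percent_explored(tr, geom), 0.1)
  # visiting all 1000 voxel centers
  centers <- seq(0.75, 14.25, by = 1.5)
  grid <- expand.grid(x = centers, y = centers, z = centers)
  tr <- swim_trace(seq_len(1000), grid$x, grid$y, grid$z)
  expect_equal(percent_explored(tr, geom), 100)
  # 250 distinct voxel centers -> 25%
  tr <- swim_trace(seq_len(250), grid$x[1:250], grid$y[1:250], grid$z[1:250])
  expect_equal(percent_explored(tr, geom), 25)
  # out-of-bounds frames are clamped with a warning
  tr <- swim_trace(0:1, c(-1, 7.5), c(0, 7.5), c(0, 5))
  expect_warning(e <- percent_explored(tr, geom), "clamped")
  expect_equal(e, 0.2)
})

test_that("percent explored is invariant to upsampling an axis-aligned path", {
  geom <- geom15()
  # lawnmower scan along voxel centers
  x <- c(seq(0.75, 14.25, by = 1.5), rep(14.25, 3), seq(14.25, 0.75, by = -1.5))
  y <- c(rep(0.75, 10), 0.75, 1.5, 2.25, rep(2.25, 10))
  z <- rep(5, length(x))
  tr <- swim_trace(seq_along(x), x, y, z)
  e1 <- percent_explored(tr, geom)
  # upsample 4x by linear interpolation along the same path
  tt <- seq(1, length(x), by = 0.25)
  tr_up <- swim_trace(tt, approx(seq_along(x), x, tt)$y,
                      approx(seq_along(y), y, tt)$y, approx(seq_along(z), z, tt)$y)
  expect_equal(percent_explored(tr_up, geom), e1)
})

test_that("distance travelled dominates displacement and grows with refinement", {
  set.seed(7)
  for (r in 1:5) {
    n <- 60
    xyz <- apply(matrix(rnorm(n * 3, sd = 0.3), n, 3), 2, cumsum) + 7
    tr <- swim_trace(seq_len(n), xyz[, 1], xyz[, 2], xyz[, 3])
    L <- distance_travelled(tr)
    disp <- sqrt(sum((xyz[n, ] - xyz[1, ])^2))
    expect_gte(L, disp)
    # dropping every other frame cannot increase path length
    tr2 <- swim_trace(seq(1, n, by = 2), xyz[seq(1, n, 2), 1],
                      xyz[seq(1, n, 2), 2], xyz[seq(1, n, 2), 3])
    expect_lte(distance_travelled(tr2), L)
  }
})

test_that("extract_features composes the stages and respects geometric bounds", {
  geom <- geom15()
  t <- 0:199 / 30
  tr <- swim_trace(t, rep(7.5, 200), rep(7.5, 200), rep(5, 200),
                   fish_id = "f1", session = "1")
  fv <- extract_features(tr, geom)
  expect_equal(fv$bottom_cm, 5)
  expect_equal(fv$center_cm, 0)
  expect_equal(fv$distance_cm, 0)
  expect_equal(fv$percent_explored, 0.1)
  # deterministic
  expect_identical(fv, extract_features(tr, geom))
  # cubic path through the tank: smoothing is transparent, closed forms hold
  s <- seq(0, 1, length.out = 301)
  x <- 3 + 9 * s; y <- 3 + 9 * s^2; z <- 2 + 6 * s^3
  tr <- swim_trace(s * 10, x, y, z)
  fv <- extract_features(tr, geom)
  expect_equal(fv$bottom_cm, mean(z), tolerance = 1e-9)
  expect_equal(fv$center_cm, mean(sqrt((x - 7.5)^2 + (y - 7.5)^2)), tolerance = 1e-9)
  expect_equal(fv$distance_cm, sum(sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2)),
               tolerance = 1e-9)
  # bounds on random archetype traces
  for (a in default_archetypes()) {
    tr <- generate_trace(a, geom, duration = 20, fps = 15, seed = 3)
    fv <- extract_features(tr, geom)
    expect_gte(fv$bottom_cm, 0); expect_lte(fv$bottom_cm, geom$side)
    expect_gte(fv$center_cm, 0); expect_lte(fv$center_cm, geom$side * sqrt(2) / 2)
    expect_gte(fv$distance_cm, 0)
    expect_gt(fv$percent_explored, 0); expect_lte(fv$percent_explored, 100)
  }
})

test_that("binned features partition the trial and distance sums across bins", {
  geom <- geom15()
  tr <- generate_trace(default_archetypes()$active_explorer, geom,
                       duration = 60, fps = 30, seed = 9)
  bf <- binned_features(tr, geom, n_bins = 6)
  expect_equal(nrow(bf), 6)
  expect_equal(bf$bin, 1:6)
  whole <- extract_features(tr, geom)
  expect_equal(sum(bf$distance_cm), whole$distance_cm, tolerance = 1e-9)
  # constant-position trace: every bin explores exactly one voxel, zero path
  tr <- swim_trace(0:359 / 6, rep(3, 360), rep(3, 360), rep(3, 360))
  bf <- binned_features(tr, geom, n_bins = 6)
  expect_equal(bf$percent_explored, rep(0.1, 6))
  expect_equal(bf$distance_cm, rep(0, 6))
  expect_error(binned_features(tr, geom, n_bins = 0), ">= 1")
})
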