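test_that("total-least-squares plane fit recovers exact planes", {
  set.seed(51)
  xy <- matrix(runif(200, -10, 10), 100, 2)
  flat <- colored_point_cloud(cbind(xy, 5), matrix(0.5, 100, 3))
  pf <- fit_plane(flat)
  expect_equal(pf$normal, c(0, 0, 1), tolerance = 1e-12)
  expect_lt(pf$residual, 1e-12)
  ## plane x + z = 0, sign-fixed unit normal (1,0,1)/sqrt(2)
  tilted <- colored_point_cloud(cbind(xy[, 1], xy[, 2], -xy[, 1]),
                                matrix(0.5, 100, 3))
  pf2 <- fit_plane(tilted)
  expect_lt(max(abs(pf2$normal - c(1, 0, 1) / sqrt(2))), 1e-9)
  expect_lt(pf2$residual, 1e-9)
})

test_that("plane fit is consistent under Gaussian jitter", {
  set.seed(52)
  n <- 1000
  pts <- cbind(runif(n, -50, 50), runif(n, -50, 50), rnorm(n, sd = 0.1))
  pf <- fit_plane(colored_point_cloud(pts, matrix(0.5, n, 3)))
  expect_lt(abs(pf$residual - 0.1) / 0.1, 0.2)
  expect_lt(acos(min(1, pf$normal[3])), 1 * pi / 180)
})

test_that("degenerate plane fits raise errors", {
  line <- colored_point_cloud(cbind(1:10, 0, 0), matrix(0.5, 10, 3))
  expect_error(fit_plane(line), class = "trayphen_degenerate_geometry")
  expect_error(fit_plane(subset_cloud(line, 1:2)),
               class = "trayphen_degenerate_geometry")
})

test_that("rotation_to_z is the minimal Rodrigues rotation", {
  expect_identical(rotation_to_z(c(0, 0, 1)), diag(3))
  r <- rotation_to_z(c(1, 0, 0))
  expect_lt(max(abs(r %*% c(1, 0, 0) - c(0, 0, 1))), 1e-9)
  expect_equal(r, rodrigues_rotation(c(0, -1, 0), pi / 2), tolerance = 1e-12)
  rdown <- rotation_to_z(c(0, 0, -1))
  expect_lt(max(abs(rdown %*% c(0, 0, -1) - c(0, 0, 1))), 1e-12)
  expect_equal(rdown %*% rdown, diag(3), tolerance = 1e-12)
  set.seed(53)
  for (i in 1:20) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    expect_lt(max(abs(rotation_to_z(n) %*% n - c(0, 0, 1))), 1e-9)
  }
  expect_error(rotation_to_z(c(1, 1, 1)), class = "trayphen_invalid_param")
})

rect_cloud <- function(theta = 0, l = 600, w = 300, n = 40) {
  g <- as.matrix(expand.grid(x = seq(-l / 2, l / 2, length.out = n),
                             y = seq(-w / 2, w / 2, length.out = n)))
  r <- rodrigues_rotation(c(0, 0, 1), theta)
  pts <- cbind(g, 0) %*% t(r)
  colored_point_cloud(pts, matrix(0.06, nrow(pts), 3))
}

test_that("long-axis rotation recovers the rectangle orientation", {
  lar0 <- long_axis_rotation(rect_cloud(0))
  expect_equal(lar0$theta, 0, tolerance = 1e-9)
  expect_equal(lar0$r_z, diag(3), tolerance = 1e-9)
  lar30 <- long_axis_rotation(rect_cloud(30 * pi / 180))
  expect_equal(abs(lar30$theta), 30 * pi / 180, tolerance = 1e-9)
  restored <- rect_cloud(30 * pi / 180)$points %*% t(lar30$r_z)
  expect_equal(diff(range(restored[, 1])), 600, tolerance = 1e-6)
  expect_equal(diff(range(restored[, 2])), 300, tolerance = 1e-6)
  lar90 <- long_axis_rotation(rect_cloud(pi / 2))
  r90 <- rect_cloud(pi / 2)$points %*% t(lar90$r_z)
  expect_equal(diff(range(r90[, 1])), 600, tolerance = 1e-6)
  expect_equal(diff(range(r90[, 2])), 300, tolerance = 1e-6)
  expect_error(long_axis_rotation(colored_point_cloud(cbind(1:5, 1, 0),
                                                      matrix(0.5, 5, 3))),
               class = "trayphen_degenerate_geometry")
})

test_that("scale factors follow the tray prior ratios", {
  s <- compute_scale_factors(c(2, 1, 1 / 12), tray_prior(), use_height = TRUE)
  expect_equal(unlist(s), c(s_l = 300, s_w = 300, s_h = 300, s_mean = 300))
  s2 <- compute_scale_factors(c(600, 300, 25), tray_prior(),
                              use_height = TRUE)
  expect_equal(s2$s_mean, 1)
  s3 <- compute_scale_factors(c(3, 1.6, 0.1), tray_prior(),
                              use_height = FALSE)
  expect_equal(s3$s_mean, 193.75)
  expect_error(compute_scale_factors(c(0, 1, 1), tray_prior()),
               class = "trayphen_degenerate_extent")
  expect_error(tray_prior(width_mm = 700), class = "trayphen_invalid_prior")
})

test_that("an already canonical metric tray calibrates to the identity", {
  tray <- ideal_tray_cloud(spacing_mm = 4)
  cal <- calibrate_cloud(tray)
  expect_equal(cal$result$scale_factors$s_mean, 1, tolerance = 1e-9)
  expect_equal(cal$result$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(cal$result$theta, 0, tolerance = 1e-9)
  expect_lt(max(abs(cal$calibrated$points - tray$points)), 1e-6)
})

test_that("calibration round-trips random similarities on the ideal tray", {
  set.seed(54)
  tray <- ideal_tray_cloud(spacing_mm = 4)
  for (i in 1:8) {
    tr <- rand_similarity()
    cal <- calibrate_cloud(apply_similarity(tray, tr))
    expect_lt(max(abs(cal$result$tray_extents_mm / c(600, 300, 25) - 1)),
              1e-6)
    ## recovered scale undoes the true scale
    expect_equal(cal$result$transform$scale * tr$scale, 1, tolerance = 1e-6)
    ## composed rotation is a symmetry of the tray box
    comp <- cal$result$transform$rotation %*% tr$rotation
    syms <- list(diag(3), diag(c(-1, -1, 1)), diag(c(1, -1, -1)),
                 diag(c(-1, 1, -1)))
    expect_lt(min(vapply(syms, function(s) max(abs(comp - s)), numeric(1))),
              1e-6)
    ## the refitted tray plane normal is Z
    top <- subset_cloud(cal$calibrated, cal$calibrated$points[, 3] > -1)
    expect_lt(acos(min(1, abs(fit_plane(top)$normal[3]))), 1e-6)
    ## calibration changes neither N nor colors
    expect_identical(n_points(cal$calibrated), n_points(tray))
    expect_identical(cal$calibrated$colors, tray$colors)
  }
})

test_that("calibration survives millimetre coordinate noise", {
  set.seed(55)
  tray <- ideal_tray_cloud(spacing_mm = 4)
  for (i in 1:5) {
    noisy <- colored_point_cloud(
      tray$points + matrix(rnorm(3 * n_points(tray)), ncol = 3), tray$colors)
    cal <- calibrate_cloud(apply_similarity(noisy, rand_similarity()))
    expect_lt(max(abs(cal$result$tray_extents_mm / c(600, 300, 25) - 1)),
              0.02)
  }
})

test_that("a full noisy scene calibrates to millimetre accuracy", {
  set.seed(56)
  cfg <- scene_config(rng_seed = 8, coordinate_noise_sigma_mm = 1,
                      applied_transform = rand_similarity())
  sim <- generate_scene(cfg)
  cal <- calibrate_cloud(sim$cloud)
  expect_lt(max(abs(cal$result$tray_extents_mm[1:2] / c(600, 300) - 1)), 0.02)
  ## plant heights land within 2 mm of their canonical values
  idx <- sim$ground_truth$labels == "plant"
  canon <- generate_scene(scene_config(rng_seed = 8,
                                       coordinate_noise_sigma_mm = 1))
  got_z <- cal$calibrated$points[idx, 3]
  want_z <- canon$cloud$points[canon$ground_truth$labels == "plant", 3]
  expect_lt(stats::median(abs(got_z - want_z)), 2)
  expect_false(cal$result$flipped)
})

test_that("clouds without a tray region fail with a stage-specific error", {
  green <- colored_point_cloud(matrix(rnorm(300), 100),
                               matrix(rep(c(0, 1, 0), each = 100), 100))
  expect_error(calibrate_cloud(green), class = "trayphen_tray_extraction")
})
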