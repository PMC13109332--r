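#' Synthetic tray-scene configuration
#'
#' Parameters of the deterministic scene generator that emulates a densely
#' sown rice seedling tray as seen by a photogrammetric reconstruction: a
#' black 600 x 300 x 25 mm tray, a dark-brown soil surface a few millimetres
#' below the tray rim, green curved leaf blades of known apex heights,
#' near-white reflection speckles hugging the canopy, and far-away background
#' clutter -- the whole scene finally mapped by an arbitrary similarity
#' transform, exactly the unknown the calibration stage must undo.
#'
#' Defaults emulate a three-leaf-stage tray: 252 blades (14 per 100 cm^2 over
#' the 1800 cm^2 tray), apex heights 180 +/- 15 mm, coordinate noise 0.5 mm.
#'
#' @param tray_length_mm,tray_width_mm,tray_height_mm tray dimensions
#'   (defaults 600, 300, 25).
#' @param n_blades number of leaf blades.
#' @param blade_height_mean_mm,blade_height_sd_mm apex height distribution
#'   above the tray top, in mm.
#' @param blade_curvature lateral arc of a blade as a fraction of its height
#'   (0 = straight vertical).
#' @param points_per_blade samples per blade (the default matches the common
#'   0.25 points per mm^2 surface density over a blade's ribbon area).
#' @param soil_point_density surface sampling density for soil and tray,
#'   points per mm^2.
#' @param n_reflection_noise near-white specular speckles near the canopy.
#' @param n_background_noise clutter points far outside the tray.
#' @param coordinate_noise_sigma_mm isotropic Gaussian coordinate noise, mm.
#' @param applied_transform a [similarity_transform()] applied to the whole
#'   scene (ground truth stays in the canonical frame).
#' @param rng_seed integer seed; the generator is bit-reproducible given it.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(tray_length_mm = 600, tray_width_mm = 300,
                         tray_height_mm = 25,
                         n_blades = 252L,
                         blade_height_mean_mm = 180,
                         blade_height_sd_mm = 15,
                         blade_curvature = 0.35,
                         points_per_blade = 240L,
                         soil_point_density = 0.25,
                         n_reflection_noise = 1500L,
                         n_background_noise = 800L,
                         coordinate_noise_sigma_mm = 0.5,
                         applied_transform = similarity_transform(),
                         rng_seed = 1L) {
  if (tray_length_mm <= 0 || tray_width_mm <= 0 || tray_height_mm <= 0) {
    stop_trayphen("tray dimensions must be positive",
                  class = "trayphen_invalid_config")
  }
  counts <- c(n_blades, points_per_blade, n_reflection_noise,
              n_background_noise)
  if (any(counts < 0) || soil_point_density < 0 ||
      coordinate_noise_sigma_mm < 0 || blade_curvature < 0) {
    stop_trayphen("counts, densities, noise and curvature must be >= 0",
                  class = "trayphen_invalid_config")
  }
  stopifnot(inherits(applied_transform, "similarity_transform"))
  structure(list(tray_length_mm = tray_length_mm,
                 tray_width_mm = tray_width_mm,
                 tray_height_mm = tray_height_mm,
                 n_blades = as.integer(n_blades),
                 blade_height_mean_mm = blade_height_mean_mm,
                 blade_height_sd_mm = blade_height_sd_mm,
                 blade_curvature = blade_curvature,
                 points_per_blade = as.integer(points_per_blade),
                 soil_point_density = soil_point_density,
                 n_reflection_noise = as.integer(n_reflection_noise),
                 n_background_noise = as.integer(n_background_noise),
                 coordinate_noise_sigma_mm = coordinate_noise_sigma_mm,
                 applied_transform = applied_transform,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

## rim width of the tray frame, mm (fixed geometry detail of the scene)
TRAY_RIM_WIDTH <- 15
## soil surface depth below the tray top, mm
SOIL_DEPTH <- 5

## Uniform surface sampling helpers (canonical frame: tray top z = 0,
## footprint centered at the origin, long side along X).

sample_tray_surface <- function(cfg) {
  hl <- cfg$tray_length_mm / 2
  hw <- cfg$tray_width_mm / 2
  h <- cfg$tray_height_mm
  rim_w <- min(TRAY_RIM_WIDTH, hw / 2)
  dens <- cfg$soil_point_density
  rim_area <- cfg$tray_length_mm * cfg$tray_width_mm -
    (cfg$tray_length_mm - 2 * rim_w) * (cfg$tray_width_mm - 2 * rim_w)
  wall_area <- 2 * (cfg$tray_length_mm + cfg$tray_width_mm) * h
  n_rim <- max(4L, round(rim_area * dens))
  n_wall <- max(4L, round(wall_area * dens))
  ## rim: uniform over the frame between outer and inner rectangle, z = 0
  frac <- rim_area / (cfg$tray_length_mm * cfg$tray_width_mm)
  rx <- numeric(0); ry <- numeric(0)
  while (length(rx) < n_rim) {
    ncand <- ceiling((n_rim - length(rx)) / frac * 1.3) + 16L
    cx <- runif(ncand, -hl, hl)
    cy <- runif(ncand, -hw, hw)
    on_rim <- abs(cx) > hl - rim_w | abs(cy) > hw - rim_w
    rx <- c(rx, cx[on_rim])
    ry <- c(ry, cy[on_rim])
  }
  rim <- cbind(rx[seq_len(n_rim)], ry[seq_len(n_rim)], 0)
  ## walls: four outer faces, z in [-h, 0]
  per <- 2 * (cfg$tray_length_mm + cfg$tray_width_mm)
  u <- runif(n_wall, 0, per)
  wz <- runif(n_wall, -h, 0)
  wx <- numeric(n_wall); wy <- numeric(n_wall)
  L <- cfg$tray_length_mm; W <- cfg$tray_width_mm
  s1 <- u < L
  s2 <- !s1 & u < L + W
  s3 <- !s1 & !s2 & u < 2 * L + W
  s4 <- !(s1 | s2 | s3)
  wx[s1] <- u[s1] - hl;                 wy[s1] <- -hw
  wx[s2] <- hl;                         wy[s2] <- u[s2] - L - hw
  wx[s3] <- hl - (u[s3] - L - W);       wy[s3] <- hw
  wx[s4] <- -hl;                        wy[s4] <- hw - (u[s4] - 2 * L - W)
  pts <- rbind(rim, cbind(wx, wy, wz))
  v <- runif(nrow(pts), 0.02, 0.12)              # near-black gray plastic
  list(points = pts, colors = cbind(v, v, v))
}

sample_soil <- function(cfg) {
  hl <- cfg$tray_length_mm / 2
  hw <- cfg$tray_width_mm / 2
  rim_w <- min(TRAY_RIM_WIDTH, hw / 2)
  area <- (cfg$tray_length_mm - 2 * rim_w) * (cfg$tray_width_mm - 2 * rim_w)
  n <- max(4L, round(area * cfg$soil_point_density))
  x <- runif(n, -(hl - rim_w), hl - rim_w)
  y <- runif(n, -(hw - rim_w), hw - rim_w)
  z <- -SOIL_DEPTH + runif(n, -1, 1)
  cols <- t(grDevices::col2rgb(grDevices::hsv(runif(n, 25, 35) / 360,
                                              runif(n, 0.4, 0.7),
                                              runif(n, 0.2, 0.4)))) / 255
  list(points = cbind(x, y, z), colors = cols)
}

## Quadratic Bezier blades with the control point at apex height, so the
## blade arches over and flattens at the top (the leaf tip bends sideways, as
## curved rice blades do); z(t) = h - (1-t)^2 (h - z0) is monotone with a
## flat apex reached exactly at t = 1.  Each blade is a narrow tapering
## ribbon, not a line: multi-view reconstructions sample visible leaf
## surfaces at roughly the same area density as the soil and tray, and a
## line-sampled blade would make plant neighborhoods artificially sparse and
## mislead the statistical denoiser.
BLADE_WIDTH <- 6  # mm at the base, tapering toward the tip
sample_blades <- function(cfg) {
  nb <- cfg$n_blades
  if (nb == 0L || cfg$points_per_blade == 0L) {
    return(list(points = matrix(numeric(0), 0, 3),
                colors = matrix(numeric(0), 0, 3),
                apex = numeric(0), noiseless_z = numeric(0)))
  }
  hl <- cfg$tray_length_mm / 2
  hw <- cfg$tray_width_mm / 2
  rim_w <- min(TRAY_RIM_WIDTH, hw / 2)
  root_x <- runif(nb, -(hl - rim_w), hl - rim_w)
  root_y <- runif(nb, -(hw - rim_w), hw - rim_w)
  h <- rnorm(nb, cfg$blade_height_mean_mm, cfg$blade_height_sd_mm)
  h <- pmax(h, 20)
  az <- runif(nb, 0, 2 * pi)
  lean <- cfg$blade_curvature * h * runif(nb, 0.5, 1)
  apex_x <- root_x + lean * cos(az)
  apex_y <- root_y + lean * sin(az)
  ## control point: halfway in plan view, at apex height
  ctl_x <- (root_x + apex_x) / 2
  ctl_y <- (root_y + apex_y) / 2
  ppb <- cfg$points_per_blade
  ## t samples: uniform jittered, with the apex t = 1 always included
  tmat <- matrix(runif(nb * ppb), nb, ppb)
  tmat[, ppb] <- 1
  t1 <- (1 - tmat)^2
  t2 <- 2 * tmat * (1 - tmat)
  t3 <- tmat^2
  z0 <- -SOIL_DEPTH
  x <- t1 * root_x + t2 * ctl_x + t3 * apex_x
  y <- t1 * root_y + t2 * ctl_y + t3 * apex_y
  z <- t1 * z0 + (t2 + t3) * h
  ## lateral ribbon offset, horizontal and perpendicular to the lean
  ## direction; purely horizontal so blade z (and the apex) are untouched
  perp_x <- -sin(az); perp_y <- cos(az)
  width <- BLADE_WIDTH * (1 - 0.7 * tmat)
  u <- matrix(runif(nb * ppb, -0.5, 0.5), nb, ppb) * width
  u[, ppb] <- 0                       # the apex sample stays on the midline
  x <- x + u * perp_x
  y <- y + u * perp_y
  n <- nb * ppb
  cols <- t(grDevices::col2rgb(grDevices::hsv(runif(n, 95, 140) / 360,
                                              runif(n, 0.5, 0.9),
                                              runif(n, 0.35, 0.75)))) / 255
  list(points = cbind(as.vector(x), as.vector(y), as.vector(z)),
       colors = cols, apex = h, noiseless_z = as.vector(z))
}

sample_reflection_noise <- function(cfg, plant_pts) {
  n <- cfg$n_reflection_noise
  if (n == 0L || nrow(plant_pts) == 0L) {
    return(list(points = matrix(numeric(0), 0, 3),
                colors = matrix(numeric(0), 0, 3)))
  }
  anchor <- plant_pts[sample.int(nrow(plant_pts), n, replace = TRUE), ,
                      drop = FALSE]
  pts <- anchor + matrix(rnorm(3 * n, sd = 8), n, 3)
  v <- runif(n, 0.92, 1)
  s <- runif(n, 0, 0.05)
  cols <- t(grDevices::col2rgb(grDevices::hsv(runif(n), s, v))) / 255
  list(points = pts, colors = cols)
}

sample_background_noise <- function(cfg) {
  n <- cfg$n_background_noise
  if (n == 0L) {
    return(list(points = matrix(numeric(0), 0, 3),
                colors = matrix(numeric(0), 0, 3)))
  }
  hl <- cfg$tray_length_mm / 2
  hw <- cfg$tray_width_mm / 2
  ## ring outside the tray footprint
  side <- sample.int(4L, n, replace = TRUE)
  x <- numeric(n); y <- numeric(n)
  far <- 300
  x[side == 1] <- runif(sum(side == 1), hl + 50, hl + far)
  y[side == 1] <- runif(sum(side == 1), -hw - far, hw + far)
  x[side == 2] <- runif(sum(side == 2), -hl - far, -hl - 50)
  y[side == 2] <- runif(sum(side == 2), -hw - far, hw + far)
  x[side == 3] <- runif(sum(side == 3), -hl, hl)
  y[side == 3] <- runif(sum(side == 3), hw + 50, hw + far)
  x[side == 4] <- runif(sum(side == 4), -hl, hl)
  y[side == 4] <- runif(sum(side == 4), -hw - far, -hw - 50)
  z <- runif(n, -30, 250)
  v <- runif(n, 0.4, 0.7)                      # gray mid-tone clutter
  s <- runif(n, 0, 0.05)
  cols <- t(grDevices::col2rgb(grDevices::hsv(runif(n), s, v))) / 255
  list(points = cbind(x, y, z), colors = cols)
}

#' Generate a synthetic tray-seedling scene with ground truth
#'
#' Deterministic given `rng_seed`.  The scene is built in the canonical frame
#' (tray top at `z = 0`, long side along X, footprint centered), ground truth
#' is recorded there, isotropic Gaussian coordinate noise is added to the
#' structural points, and the whole cloud is finally mapped by
#' `config$applied_transform`.
#'
#' @param config a [scene_config()].
#' @return list with `cloud` (a [colored_point_cloud()]) and `ground_truth`,
#'   a `scene_ground_truth` list holding per-point `labels` (factor with
#'   levels plant/tray/soil/reflection_noise/background_noise),
#'   `true_mean_height_mm` (mean apex height), `true_top5_apex_mm` (mean of
#'   the top 5 percent of the noiseless blade apex heights),
#'   `true_top5_point_mm` (mean of the top 5 percent of the noiseless plant
#'   point heights -- the population statistic the point-cloud height
#'   estimator defines), `true_voxel_volume_mm3` and `voxel_size_mm`,
#'   `true_canopy_area_mm2` (1 mm occupancy raster of the noiseless plant
#'   points), `apex_heights_mm`, and `applied_transform`.
#' @export
generate_scene <- function(config = scene_config()) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$rng_seed, {
    tray <- sample_tray_surface(config)
    soil <- sample_soil(config)
    blades <- sample_blades(config)
    refl <- sample_reflection_noise(config, blades$points)
    bg <- sample_background_noise(config)

    pts <- rbind(blades$points, tray$points, soil$points, refl$points,
                 bg$points)
    cols <- rbind(blades$colors, tray$colors, soil$colors, refl$colors,
                  bg$colors)
    labels <- factor(
      rep(c("plant", "tray", "soil", "reflection_noise", "background_noise"),
          times = c(nrow(blades$points), nrow(tray$points), nrow(soil$points),
                    nrow(refl$points), nrow(bg$points))),
      levels = c("plant", "tray", "soil", "reflection_noise",
                 "background_noise"))

    noiseless_plant <- blades$points
    if (config$coordinate_noise_sigma_mm > 0 && nrow(pts) > 0L) {
      pts <- pts + matrix(rnorm(length(pts),
                                sd = config$coordinate_noise_sigma_mm),
                          nrow(pts), 3L)
    }
    cloud <- colored_point_cloud(pts, cols)
    cloud <- apply_similarity(cloud, config$applied_transform)

    nb <- length(blades$apex)
    top5_apex <- if (nb) {
      mean(sort(blades$apex, decreasing = TRUE)[seq_len(max(1L,
        ceiling(0.05 * nb)))])
    } else {
      NA_real_
    }
    npz <- blades$noiseless_z
    top5_point <- if (length(npz)) {
      mean(sort(npz, decreasing = TRUE)[seq_len(max(1L,
        ceiling(0.05 * length(npz))))])
    } else {
      NA_real_
    }
    voxel_size <- 5
    vox <- if (nrow(noiseless_plant)) {
      count_unique_cells(floor(noiseless_plant / voxel_size)) * voxel_size^3
    } else {
      0
    }
    canopy <- if (nrow(noiseless_plant)) {
      count_unique_cells(floor(noiseless_plant[, 1:2, drop = FALSE]))
    } else {
      0
    }
    gt <- structure(
      list(labels = labels,
           true_mean_height_mm = if (nb) mean(blades$apex) else NA_real_,
           true_top5_apex_mm = top5_apex,
           true_top5_point_mm = top5_point,
           true_voxel_volume_mm3 = vox,
           voxel_size_mm = voxel_size,
           true_canopy_area_mm2 = canopy,
           apex_heights_mm = blades$apex,
           applied_transform = config$applied_transform),
      class = "scene_ground_truth")
    list(cloud = cloud, ground_truth = gt)
  })
}

#' Noiseless tray shell sampled on a regular grid
#'
#' Calibration fixture: the tray's top rim and four side faces sampled on a
#' grid that includes the exact extreme coordinates, so the canonical-frame
#' extents are exactly `(length, width, height)`.  Colors are tray black.
#'
#' @param config a [scene_config()] (only the tray dimensions are used).
#' @param spacing_mm grid spacing, `0 < spacing_mm <` tray width.
#' @return a [colored_point_cloud()] in the canonical frame.
#' @export
ideal_tray_cloud <- function(config = scene_config(), spacing_mm = 4) {
  if (spacing_mm <= 0) {
    stop_trayphen("spacing must be positive", class = "trayphen_invalid_param")
  }
  if (spacing_mm >= config$tray_width_mm) {
    stop_trayphen("degenerate sampling: spacing exceeds the tray width",
                  class = "trayphen_degenerate_sampling")
  }
  L <- config$tray_length_mm; W <- config$tray_width_mm
  H <- config$tray_height_mm
  hl <- L / 2; hw <- W / 2
  rim_w <- min(TRAY_RIM_WIDTH, hw / 2)
  gx <- seq(-hl, hl, length.out = max(2L, round(L / spacing_mm) + 1L))
  gy <- seq(-hw, hw, length.out = max(2L, round(W / spacing_mm) + 1L))
  gz <- seq(-H, 0, length.out = max(2L, round(H / spacing_mm) + 1L))
  rim <- expand.grid(x = gx, y = gy)
  rim <- rim[abs(rim$x) > hl - rim_w | abs(rim$y) > hw - rim_w, ]
  rim <- cbind(rim$x, rim$y, 0)
  wall_x <- expand.grid(x = gx, z = gz)
  wall_y <- expand.grid(y = gy, z = gz)
  walls <- rbind(cbind(wall_x$x, -hw, wall_x$z),
                 cbind(wall_x$x, hw, wall_x$z),
                 cbind(-hl, wall_y$y, wall_y$z),
                 cbind(hl, wall_y$y, wall_y$z))
  pts <- rbind(rim, walls)
  colored_point_cloud(pts, matrix(0.06, nrow(pts), 3L))
}
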