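#' Seedling tray prior
#'
#' The known physical dimensions of the seedling tray used to restore metric
#' scale; defaults are the standard 60 x 30 x 2.5 cm tray, in millimetres.
#'
#' @param length_mm tray length (long side), default 600.
#' @param width_mm tray width, default 300; must satisfy
#'   `length_mm >= width_mm > 0`.
#' @param height_mm tray height, default 25.
#' @return an object of class `tray_prior`.
#' @export
tray_prior <- function(length_mm = 600, width_mm = 300, height_mm = 25) {
  if (!(length_mm >= width_mm && width_mm > 0 && height_mm > 0)) {
    stop_trayphen("tray prior needs length >= width > 0 and height > 0",
                  class = "trayphen_invalid_prior")
  }
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 height_mm = height_mm),
            class = "tray_prior")
}

#' Total-least-squares plane fit
#'
#' Fits the plane through the centroid whose normal is the eigenvector of the
#' centered covariance with the smallest eigenvalue (the PCA plane).  The
#' normal sign is fixed to a positive Z component (positive X if the Z
#' component is zero, then positive Y).
#'
#' @param cloud a [colored_point_cloud()] with at least 3 non-collinear
#'   points.
#' @return object of class `plane_fit`: unit `normal`, `centroid`, RMS
#'   `residual` in cloud units.
#' @export
fit_plane <- function(cloud) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  p <- cloud$points
  if (nrow(p) < 3L) {
    stop_trayphen("plane fit needs at least 3 points",
                  class = "trayphen_degenerate_geometry")
  }
  centroid <- colMeans(p)
  cc <- sweep(p, 2L, centroid)
  cv <- crossprod(cc) / nrow(cc)
  ev <- eigen(cv, symmetric = TRUE)
  if (ev$values[2] <= 1e-12 * max(ev$values[1], .Machine$double.xmin)) {
    stop_trayphen("degenerate geometry: points are (near-)collinear",
                  class = "trayphen_degenerate_geometry")
  }
  n <- ev$vectors[, 3]
  if (n[3] < 0 ||
      (n[3] == 0 && (n[1] < 0 || (n[1] == 0 && n[2] < 0)))) {
    n <- -n
  }
  structure(list(normal = n, centroid = centroid,
                 residual = sqrt(mean((cc %*% n)^2))),
            class = "plane_fit")
}

#' Minimal rotation taking a unit vector to the Z axis
#'
#' Rodrigues rotation about the axis `n x z`.  `n = z` returns the identity;
#' `n = -z` returns the half-turn about X (the degenerate axis fixed by
#' convention).
#'
#' @param n unit 3-vector (to 1e-6).
#' @return 3x3 rotation matrix `R` with `R n = (0,0,1)` to 1e-9.
#' @export
rotation_to_z <- function(n) {
  n <- as.numeric(n)
  if (length(n) != 3L || abs(sqrt(sum(n^2)) - 1) > 1e-6) {
    stop_trayphen("n must be a unit 3-vector",
                  class = "trayphen_invalid_param")
  }
  axis <- c(n[2], -n[1], 0)
  s <- sqrt(sum(axis^2))
  if (s < 1e-12) {
    return(if (n[3] > 0) diag(3) else diag(c(1, -1, -1)))
  }
  rodrigues_rotation(axis, atan2(s, n[3]))
}

#' Long-axis rotation about Z from the projected tray outline
#'
#' Projects a normal-aligned tray cloud to the XY plane and returns the
#' signed angle `theta` between the first principal direction of the
#' projection (the tray's long side, sign-fixed to non-negative X, ties to
#' non-negative Y) and the X axis, together with the rotation by `-theta`
#' about Z that lands the long side on +X.  The 2-D convex hull of the
#' projection guards against degenerate (collinear) input.
#'
#' PCA is run over the full projected point set rather than the convex-hull
#' vertices alone: for a rectangular outline the full-projection covariance
#' has the rectangle axes as exact eigenvectors by symmetry, and isotropic
#' coordinate noise only adds a multiple of the identity, leaving them
#' unbiased -- whereas the hull-vertex subset weights corners unevenly (any
#' floating-point or measurement jitter changes which collinear boundary
#' points surface as vertices) and can tilt the recovered axis by several
#' degrees.
#'
#' @param cloud a [colored_point_cloud()] whose fitted plane normal is within
#'   5 degrees of Z.
#' @return list with `theta` (signed radians) and `r_z` (3x3 rotation).
#' @export
long_axis_rotation <- function(cloud) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  xy <- cloud$points[, 1:2, drop = FALSE]
  if (nrow(unique(xy)) < 3L) {
    stop_trayphen("degenerate hull: fewer than 3 distinct projected points",
                  class = "trayphen_degenerate_geometry")
  }
  pl <- fit_plane(cloud)
  if (acos(min(1, abs(pl$normal[3]))) > 5 * pi / 180) {
    stop_trayphen("cloud is not normal-aligned (plane normal > 5 deg from Z)",
                  class = "trayphen_not_aligned")
  }
  hull <- unique(xy[grDevices::chull(xy[, 1], xy[, 2]), , drop = FALSE])
  if (nrow(hull) < 3L) {
    stop_trayphen("degenerate hull: fewer than 3 distinct hull vertices",
                  class = "trayphen_degenerate_geometry")
  }
  hc <- sweep(xy, 2L, colMeans(xy))
  ev <- eigen(crossprod(hc) / nrow(hc), symmetric = TRUE)
  v1 <- ev$vectors[, 1]
  if (v1[1] < 0 || (v1[1] == 0 && v1[2] < 0)) v1 <- -v1
  theta <- atan2(v1[2], v1[1])
  r_z <- rodrigues_rotation(c(0, 0, 1), -theta)
  list(theta = theta, r_z = r_z)
}

#' Scale factors from tray extents and the physical prior
#'
#' `s_L = length_mm / L_cloud`, `s_W = width_mm / W_cloud`,
#' `s_H = height_mm / H_cloud`; the restored scale `S` is the arithmetic mean
#' of the included factors.  The height factor is excluded by default because
#' the tray height is the thinnest, noisiest dimension.
#'
#' @param extents an `axis_aligned_bounds`, a cloud, or a numeric 3-vector of
#'   extents (x, y, z) in cloud units.
#' @param prior a [tray_prior()].
#' @param use_height include `s_H` in the mean (default `FALSE`).
#' @return list with `s_l`, `s_w`, `s_h`, `s_mean`.
#' @export
compute_scale_factors <- function(extents, prior = tray_prior(),
                                  use_height = FALSE) {
  if (!is.numeric(extents)) extents <- bounds_extents(extents)
  used <- if (use_height) 1:3 else 1:2
  if (any(extents[used] <= 0)) {
    stop_trayphen("degenerate extent: zero length on a used axis",
                  class = "trayphen_degenerate_extent")
  }
  s <- c(prior$length_mm, prior$width_mm, prior$height_mm) / extents
  list(s_l = s[[1]], s_w = s[[2]], s_h = s[[3]], s_mean = mean(s[used]))
}

## ---- robust boundary estimation under coordinate noise -------------------
## A tray face perpendicular to an axis puts a planar cluster ("atom") exactly
## at the boundary value, on top of a one-sided uniform background (points of
## the other faces), both convolved with isotropic coordinate noise.  The
## boundary is recovered by maximum likelihood under that two-component model,
## with the noise scale estimated from rim-plane residuals.  In the noiseless
## regime the plain minimum/maximum is exact and is used directly.

edge_locate_upper <- function(v, sigma) {
  m0 <- max(v)
  if (sigma <= 1e-9 * max(1, diff(range(v)))) return(m0)
  w0 <- m0 - 12 * sigma
  x <- v[v >= w0]
  if (length(x) < 50L) return(m0)
  nll <- function(par) {
    b <- par[1]
    a <- stats::plogis(par[2])
    t0 <- (w0 - b) / sigma
    atom_mass <- stats::pnorm((b - w0) / sigma)
    g <- stats::dnorm(t0) - t0 * (1 - stats::pnorm(t0))
    cc <- sigma * g
    f <- a * stats::dnorm(x, b, sigma) / atom_mass +
      (1 - a) * stats::pnorm((b - x) / sigma) / cc
    -sum(log(pmax(f, 1e-300)))
  }
  starts <- list(c(m0 - 3.3 * sigma, 0),
                 c(stats::median(x), 0),
                 c(stats::quantile(x, 0.9, names = FALSE), -2))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = c(w0 + 2 * sigma, -8),
                   upper = c(m0 + sigma, 8)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) return(m0)
  best$par[1]
}

edge_locate <- function(v, sigma, side = c("upper", "lower")) {
  side <- match.arg(side)
  if (side == "upper") edge_locate_upper(v, sigma)
  else -edge_locate_upper(-v, sigma)
}

## Noise scale from the residuals of a plane fitted to the tray's rim band.
## The rim is the dominant planar structure; it sits at the top of the z
## range, or at the bottom if the cloud is upside down, so both bands are
## tried and the more planar one wins.
band_plane_sigma <- function(sub) {
  if (nrow(sub) < 10L) return(Inf)
  ## successively tighter trims pull the band onto the rim plane proper;
  ## without them the wall tops contaminate the scale estimate upward
  for (thr in c(3, 2.5, 2.5)) {
    res <- stats::lm.fit(cbind(1, sub[, 1], sub[, 2]), sub[, 3])$residuals
    keep <- abs(res) <= max(thr * stats::mad(res), 1e-12)
    if (sum(keep) < 10L) break
    sub <- sub[keep, , drop = FALSE]
  }
  stats::mad(stats::lm.fit(cbind(1, sub[, 1], sub[, 2]), sub[, 3])$residuals)
}

estimate_noise_sigma <- function(pts_rot) {
  z <- pts_rot[, 3]
  zr <- range(z)
  w <- 0.3 * max(zr[2] - zr[1], .Machine$double.eps)
  s_top <- band_plane_sigma(pts_rot[z > zr[2] - w, , drop = FALSE])
  s_bot <- band_plane_sigma(pts_rot[z < zr[1] + w, , drop = FALSE])
  s <- min(s_top, s_bot)
  if (is.finite(s)) s else 0
}

tray_boundaries <- function(pts_rot, sigma) {
  lo <- hi <- numeric(3)
  for (ax in 1:3) {
    v <- pts_rot[, ax]
    hi[ax] <- edge_locate(v, sigma, "upper")
    lo[ax] <- edge_locate(v, sigma, "lower")
  }
  list(lo = lo, hi = hi, extents = hi - lo)
}

#' Calibrate a cloud from the seedling-tray prior
#'
#' Full orientation and metric-scale calibration: the black tray region is
#' extracted by color, denoised by statistical outlier removal, its PCA plane
#' normal is aligned with Z (Rodrigues rotation), the long side of the tray
#' (first principal direction of its projected convex hull) is aligned with
#' X, the scale factor is restored from the physical tray dimensions, and the
#' composed similarity is applied to the full cloud.  The output frame puts
#' the tray top plane at `z = 0` and the tray footprint center at `(0, 0)`;
#' heights are then millimetres above the tray top.
#'
#' If the cloud arrives upside down (the fitted normal cannot distinguish the
#' two plane sides), the plant region's mean height relative to the tray
#' resolves the flip; the remaining 180-degree ambiguity about Z is harmless
#' for every phenotype and is left unresolved.
#'
#' Tray extents are measured exactly (min/max) when the estimated coordinate
#' noise is negligible, and otherwise by a model-based boundary estimator
#' (planar-face atom plus uniform background, convolved with the estimated
#' noise) that stays unbiased where a plain min/max would inflate the thin
#' tray height by several noise standard deviations.
#'
#' @param cloud the full scene [colored_point_cloud()]; must contain at least
#'   100 tray-colored points.
#' @param ranges per-region HSV ranges, see [default_region_ranges()].
#' @param prior a [tray_prior()].
#' @param sor_m,sor_k statistical-outlier-removal parameters for the tray
#'   region (defaults 16 and 1).
#' @param use_height_scale include the height scale factor in the mean scale
#'   (default `FALSE`).
#' @return list with `calibrated` (the transformed full cloud) and `result`,
#'   a `calibration_result` holding `plane`, `r_align`, `theta`, `r_z`,
#'   `flipped`, `scale_factors`, `transform` (the composed
#'   [similarity_transform()]), `sigma_hat` (estimated coordinate noise, cloud
#'   units), `tray_extents_mm` (robust extents after calibration, L/W/H),
#'   `tray_bounds_before`, `tray_bounds_after` and `n_tray_points`.
#' @export
calibrate_cloud <- function(cloud, ranges = default_region_ranges(),
                            prior = tray_prior(), sor_m = 16L, sor_k = 1.0,
                            use_height_scale = FALSE) {
  tray_raw <- extract_region(cloud, ranges, "tray")
  if (n_points(tray_raw) < 100L) {
    stop_trayphen("tray extraction failed: only ", n_points(tray_raw),
                  " tray-colored points (need >= 100)",
                  class = "trayphen_tray_extraction")
  }
  tray_clean <- if (n_points(tray_raw) > sor_m + 1L) {
    remove_statistical_outliers(tray_raw, m = sor_m, k = sor_k)$kept
  } else {
    tray_raw
  }
  plane <- fit_plane(tray_clean)
  r_align <- rotation_to_z(plane$normal)
  tray1 <- colored_point_cloud(tray_clean$points %*% t(r_align),
                               tray_clean$colors, tray_clean$ids)
  lar <- long_axis_rotation(tray1)
  rot <- lar$r_z %*% r_align

  ## flip disambiguation: plants grow above the tray top; failing plants,
  ## the dense planar rim (vs the sparse bottom edge row) marks the top side
  flipped <- FALSE
  plant <- extract_region(cloud, ranges, "plant")
  tz <- (tray_clean$points %*% t(rot))[, 3]
  if (n_points(plant) > 0L) {
    pz <- mean((plant$points %*% t(rot))[, 3])
    flipped <- pz < mean(range(tz))
  } else {
    zr <- range(tz)
    slab <- 0.1 * max(zr[2] - zr[1], .Machine$double.eps)
    flipped <- sum(tz < zr[1] + slab) > sum(tz > zr[2] - slab)
  }
  if (flipped) rot <- diag(c(1, -1, -1)) %*% rot

  tray2 <- tray_clean$points %*% t(rot)
  sigma_hat <- estimate_noise_sigma(tray2)
  edges <- tray_boundaries(tray2, sigma_hat)

  ## refine the in-plane angle from the long-wall bands: the PCA angle is
  ## limited by sampling fluctuation (~1/sqrt(N) rad), while a line fit along
  ## the two long walls pins the orientation to a fraction of a milliradian,
  ## which matters because a tilt delta inflates the measured width by
  ## ~L * delta.  No-op in the noiseless regime where the PCA angle is exact.
  if (sigma_hat > 0) {
    for (it in 1:2) {
      w <- 5 * sigma_hat
      hi_band <- tray2[tray2[, 2] > edges$hi[2] - w, , drop = FALSE]
      lo_band <- tray2[tray2[, 2] < edges$lo[2] + w, , drop = FALSE]
      if (nrow(hi_band) < 30L || nrow(lo_band) < 30L) break
      b_hi <- stats::lm.fit(cbind(1, hi_band[, 1]), hi_band[, 2])$coefficients[2]
      b_lo <- stats::lm.fit(cbind(1, lo_band[, 1]), lo_band[, 2])$coefficients[2]
      delta <- atan(mean(c(b_hi, b_lo)))
      if (!is.finite(delta) || abs(delta) < 1e-10) break
      rot <- rodrigues_rotation(c(0, 0, 1), -delta) %*% rot
      tray2 <- tray_clean$points %*% t(rot)
      sigma_hat <- estimate_noise_sigma(tray2)
      edges <- tray_boundaries(tray2, sigma_hat)
    }
  }
  sf <- compute_scale_factors(edges$extents, prior,
                              use_height = use_height_scale)
  s <- sf$s_mean
  translation <- c(-s * (edges$lo[1] + edges$hi[1]) / 2,
                   -s * (edges$lo[2] + edges$hi[2]) / 2,
                   -s * edges$hi[3])
  transform <- similarity_transform(rot, translation, s)
  calibrated <- apply_similarity(cloud, transform)
  tray_after <- apply_similarity(tray_clean, transform)
  result <- structure(
    list(plane = plane, r_align = r_align, theta = lar$theta, r_z = lar$r_z,
         flipped = flipped, scale_factors = sf, transform = transform,
         sigma_hat = sigma_hat,
         tray_extents_mm = edges$extents * s,
         tray_bounds_before = cloud_bounds(tray_clean),
         tray_bounds_after = cloud_bounds(tray_after),
         n_tray_points = n_points(tray_clean)),
    class = "calibration_result")
  list(calibrated = calibrated, result = result)
}
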