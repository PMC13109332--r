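#' Colored point cloud
#'
#' The container every stage of the pipeline transforms: `N` 3-D points with
#' RGB colors and stable integer ids.  Coordinates are unit-free before tray
#' calibration and millimetres after; colors are reals in `[0, 1]`.
#'
#' @param points numeric matrix `N x 3` of finite coordinates.
#' @param colors numeric matrix `N x 3` of red, green, blue in `[0, 1]`.
#' @param ids optional integer vector of unique per-point ids, kept stable
#'   across filtering so removed sets are auditable.  Defaults to `0:(N-1)`.
#' @return an object of class `colored_point_cloud` with elements `points`,
#'   `colors`, `ids`.
#' @examples
#' pc <- colored_point_cloud(matrix(rnorm(30), 10), matrix(runif(30), 10))
#' n_points(pc)
#' @export
colored_point_cloud <- function(points, colors, ids = NULL) {
  points <- as_coord_matrix(points, "points")
  colors <- as_coord_matrix(colors, "colors")
  if (nrow(points) != nrow(colors)) {
    stop_trayphen("points and colors must have the same number of rows (",
                  nrow(points), " vs ", nrow(colors), ")",
                  class = "trayphen_invalid_cloud")
  }
  if (nrow(points) && !all(is.finite(points))) {
    stop_trayphen("point coordinates must be finite",
                  class = "trayphen_invalid_cloud")
  }
  if (nrow(colors) &&
      (min(colors) < 0 || max(colors) > 1 || !all(is.finite(colors)))) {
    stop_trayphen("colors must lie in [0, 1]", class = "trayphen_invalid_cloud")
  }
  if (is.null(ids)) {
    ids <- if (nrow(points)) 0:(nrow(points) - 1L) else integer(0)
  }
  ids <- as.integer(ids)
  if (length(ids) != nrow(points)) {
    stop_trayphen("ids length must equal the number of points",
                  class = "trayphen_invalid_cloud")
  }
  if (anyDuplicated(ids)) {
    stop_trayphen("ids must be unique", class = "trayphen_invalid_cloud")
  }
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  dimnames(colors) <- list(NULL, c("r", "g", "b"))
  structure(list(points = points, colors = colors, ids = ids),
            class = "colored_point_cloud")
}

as_coord_matrix <- function(m, what) {
  m <- as.matrix(m)
  if (length(m) == 0L) m <- matrix(numeric(0), 0L, 3L)
  if (ncol(m) != 3L) {
    stop_trayphen(what, " must be an N x 3 matrix",
                  class = "trayphen_invalid_cloud")
  }
  storage.mode(m) <- "double"
  m
}

#' @export
print.colored_point_cloud <- function(x, ...) {
  cat("<colored_point_cloud>", n_points(x), "points\n")
  if (n_points(x)) {
    b <- cloud_bounds(x)
    cat(sprintf("  x [%.3f, %.3f]  y [%.3f, %.3f]  z [%.3f, %.3f]\n",
                b$xmin, b$xmax, b$ymin, b$ymax, b$zmin, b$zmax))
  }
  invisible(x)
}

#' Number of points in a cloud
#' @param cloud a [colored_point_cloud()].
#' @return integer point count.
#' @export
n_points <- function(cloud) nrow(cloud$points)

#' Subset a cloud by row index, keeping ids
#' @param cloud a [colored_point_cloud()].
#' @param i logical or integer row index.
#' @return a [colored_point_cloud()].
#' @export
subset_cloud <- function(cloud, i) {
  colored_point_cloud(cloud$points[i, , drop = FALSE],
                      cloud$colors[i, , drop = FALSE],
                      cloud$ids[i])
}

#' Similarity transform (rotation, translation, uniform scale)
#'
#' Maps a point `p` to `scale * rotation %*% p + translation`.  This is the
#' transform class tray calibration estimates: the reconstructed cloud differs
#' from the physical scene by exactly such a map.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1 (to 1e-9).
#' @param translation numeric 3-vector.
#' @param scale positive scalar.
#' @return an object of class `similarity_transform`.
#' @export
similarity_transform <- function(rotation = diag(3),
                                 translation = c(0, 0, 0),
                                 scale = 1) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  if (length(translation) != 3L) {
    stop_trayphen("translation must have length 3",
                  class = "trayphen_invalid_transform")
  }
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0) {
    stop_trayphen("scale must be a positive number",
                  class = "trayphen_invalid_transform")
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9) {
    stop_trayphen("rotation must be orthonormal with determinant +1",
                  class = "trayphen_invalid_transform")
  }
  structure(list(rotation = rotation, translation = translation,
                 scale = scale),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform> scale", format(x$scale), "\n")
  print(round(x$rotation, 6))
  cat("translation:", paste(format(x$translation), collapse = ", "), "\n")
  invisible(x)
}

#' Apply a similarity transform to a cloud
#'
#' Each point `p` maps to `scale * R p + t`; colors and ids are unchanged.
#'
#' @param cloud a [colored_point_cloud()].
#' @param transform a [similarity_transform()].
#' @return the transformed [colored_point_cloud()].
#' @export
apply_similarity <- function(cloud, transform) {
  stopifnot(inherits(cloud, "colored_point_cloud"),
            inherits(transform, "similarity_transform"))
  p <- cloud$points %*% t(transform$rotation) * transform$scale
  p <- sweep(p, 2L, transform$translation, "+")
  colored_point_cloud(p, cloud$colors, cloud$ids)
}

#' Compose two similarity transforms
#'
#' `compose_similarity(t2, t1)` is the transform equivalent to applying `t1`
#' first and `t2` second.
#' @param t2,t1 [similarity_transform()] objects.
#' @return a [similarity_transform()].
#' @export
compose_similarity <- function(t2, t1) {
  similarity_transform(
    rotation = t2$rotation %*% t1$rotation,
    translation = t2$scale * as.numeric(t2$rotation %*% t1$translation) +
      t2$translation,
    scale = t2$scale * t1$scale
  )
}

#' Invert a similarity transform
#' @param transform a [similarity_transform()].
#' @return the inverse [similarity_transform()].
#' @export
invert_similarity <- function(transform) {
  rt <- t(transform$rotation)
  similarity_transform(
    rotation = rt,
    translation = -as.numeric(rt %*% transform$translation) / transform$scale,
    scale = 1 / transform$scale
  )
}

#' Rodrigues rotation matrix from axis and angle
#'
#' Closed-form rotation by `angle` radians about the (not necessarily unit)
#' `axis`, via the Rodrigues formula `R = I + sin(a) K + (1 - cos(a)) K^2`.
#'
#' @param axis numeric 3-vector, nonzero.
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
rodrigues_rotation <- function(axis, angle) {
  axis <- as.numeric(axis)
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-15) {
    stop_trayphen("rotation axis must be nonzero",
                  class = "trayphen_invalid_transform")
  }
  a <- axis / nrm
  k <- matrix(c(0, a[3], -a[2],
                -a[3], 0, a[1],
                a[2], -a[1], 0), 3L, 3L)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' Axis-aligned bounds of a cloud
#'
#' Componentwise minimum and maximum of the coordinates; the rotated-frame
#' extents `L = xmax - xmin`, `W = ymax - ymin`, `H = zmax - zmin` feed scale
#' restoration.
#'
#' @param cloud a [colored_point_cloud()] with at least one point.
#' @return object of class `axis_aligned_bounds` with fields `xmin`..`zmax`.
#' @export
cloud_bounds <- function(cloud) {
  if (n_points(cloud) < 1L) {
    stop_trayphen("cannot compute bounds of an empty cloud",
                  class = "trayphen_empty_cloud")
  }
  p <- cloud$points
  structure(list(xmin = min(p[, 1]), xmax = max(p[, 1]),
                 ymin = min(p[, 2]), ymax = max(p[, 2]),
                 zmin = min(p[, 3]), zmax = max(p[, 3])),
            class = "axis_aligned_bounds")
}

#' Extents (lengths per axis) of bounds
#' @param bounds an `axis_aligned_bounds` object (or a cloud).
#' @return numeric 3-vector `c(x, y, z)` of `max - min` per axis.
#' @export
bounds_extents <- function(bounds) {
  if (inherits(bounds, "colored_point_cloud")) bounds <- cloud_bounds(bounds)
  c(x = bounds$xmax - bounds$xmin,
    y = bounds$ymax - bounds$ymin,
    z = bounds$zmax - bounds$zmin)
}

#' Export a cloud as CSV (x,y,z,r,g,b)
#' @param cloud a [colored_point_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cloud_csv <- function(cloud, path) {
  df <- data.frame(cloud$points, cloud$colors)
  names(df) <- c("x", "y", "z", "r", "g", "b")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
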