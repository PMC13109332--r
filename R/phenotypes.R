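#' Population plant height from the top fraction of heights
#'
#' Under dense sowing the single highest point is dominated by noise and by
#' individual outlier seedlings, so the population height is estimated
#' robustly as the mean of the top fraction (default 5 percent) of the
#' Z coordinates: with `n_top = max(1, ceiling(top_fraction * N))`, the
#' estimate is the mean of the `n_top` largest z values minus
#' `reference_z_mm`.
#'
#' @param plant_cloud [colored_point_cloud()] of plant-classified points
#'   (calibrated, so z is millimetres above the tray top).
#' @param top_fraction fraction in `(0, 1]` (default 0.05); 1 gives the plain
#'   mean.
#' @param reference_z_mm height datum (default 0, the calibrated tray top).
#' @return height in mm.
#' @export
estimate_plant_height <- function(plant_cloud, top_fraction = 0.05,
                                  reference_z_mm = 0) {
  stopifnot(inherits(plant_cloud, "colored_point_cloud"))
  n <- n_points(plant_cloud)
  if (n < 1L) {
    stop_trayphen("cannot estimate height of an empty cloud",
                  class = "trayphen_empty_cloud")
  }
  if (!(top_fraction > 0 && top_fraction <= 1)) {
    stop_trayphen("top_fraction must lie in (0, 1]",
                  class = "trayphen_invalid_param")
  }
  n_top <- max(1L, as.integer(ceiling(top_fraction * n)))
  z <- sort(plant_cloud$points[, 3], decreasing = TRUE)
  mean(z[seq_len(n_top)]) - reference_z_mm
}

#' Projected canopy area by occupancy rasterization
#'
#' Points are projected vertically onto the horizontal plane and binned into
#' square cells (`cell index = floor(coord / cell)`, grid anchored at the
#' calibrated origin); the area is the occupied-cell count times the cell
#' area.  This mirrors the pixel-counting validation against top-view images.
#'
#' @param plant_cloud a [colored_point_cloud()].
#' @param cell_mm cell side in mm (default 1).
#' @return area in mm^2 (0 with a warning for an empty cloud).
#' @export
projected_canopy_area <- function(plant_cloud, cell_mm = 1.0) {
  stopifnot(inherits(plant_cloud, "colored_point_cloud"))
  if (cell_mm <= 0) {
    stop_trayphen("cell_mm must be positive", class = "trayphen_invalid_param")
  }
  if (n_points(plant_cloud) == 0L) {
    warning("empty cloud: projected canopy area is 0")
    return(0)
  }
  idx <- floor(plant_cloud$points[, 1:2, drop = FALSE] / cell_mm)
  count_unique_cells(idx) * cell_mm^2
}

#' Canopy area from green pixels of a top-view image
#'
#' Counts pixels whose HSV triplet falls in the plant color range (same
#' inclusive-interval semantics as the point-cloud color filter) and converts
#' the count to physical area via the image scale.
#'
#' @param top_view_image an `H x W x 3` RGB array in `[0,1]`, or the path to
#'   a PNG file.
#' @param plant_range an [hsv_range()] for green plant tissue.
#' @param mm_per_pixel physical size of one pixel, mm.
#' @return area in mm^2.
#' @export
green_pixel_area <- function(top_view_image,
                             plant_range = default_region_ranges()$plant,
                             mm_per_pixel) {
  if (is.character(top_view_image)) {
    top_view_image <- png::readPNG(top_view_image)
  }
  if (mm_per_pixel <= 0) {
    stop_trayphen("mm_per_pixel must be positive",
                  class = "trayphen_invalid_param")
  }
  d <- dim(top_view_image)
  if (length(d) != 3L || d[3] < 3L) {
    stop_trayphen("top-view image must be an H x W x 3 RGB array",
                  class = "trayphen_invalid_image")
  }
  cols <- cbind(as.vector(top_view_image[, , 1]),
                as.vector(top_view_image[, , 2]),
                as.vector(top_view_image[, , 3]))
  inside <- hsv_in_range(rgb_to_hsv_deg(cols), plant_range)
  sum(inside) * mm_per_pixel^2
}

#' Horizontal cross-section slab of the canopy
#'
#' Extracts the points with `z` in `[z_center - half_width, z_center +
#' half_width]` (inclusive) and rasterizes their footprint.  The defaults
#' select the representative canopy layer at 163 +/- 5 mm.
#'
#' @param cloud a [colored_point_cloud()].
#' @param z_center_mm slab center height (default 163).
#' @param half_width_mm slab half thickness (default 5), positive.
#' @param cell_mm raster cell for the slab area (default 1).
#' @return list with `slab` (a [colored_point_cloud()], possibly empty) and
#'   `area_mm2`.
#' @export
cross_section <- function(cloud, z_center_mm = 163, half_width_mm = 5,
                          cell_mm = 1.0) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  if (half_width_mm <= 0) {
    stop_trayphen("half_width_mm must be positive",
                  class = "trayphen_invalid_param")
  }
  z <- cloud$points[, 3]
  inside <- z >= z_center_mm - half_width_mm & z <= z_center_mm + half_width_mm
  slab <- subset_cloud(cloud, inside)
  area <- if (n_points(slab)) projected_canopy_area(slab, cell_mm) else 0
  list(slab = slab, area_mm2 = area)
}

#' Axis-aligned bounding-box volume
#'
#' Product of the axis-aligned extents; after tray calibration the cloud is
#' axis-aligned by construction.  Canopy gaps are included, so this estimate
#' upper-bounds the voxel estimate on sparse canopies.
#'
#' @param cloud a [colored_point_cloud()] with at least one point.
#' @return volume in mm^3.
#' @export
bbox_volume <- function(cloud) {
  prod(bounds_extents(cloud_bounds(cloud)))
}

#' Voxel-occupancy volume
#'
#' The cloud is voxelized on a grid anchored at the origin
#' (`index = floor(coord / voxel)`); the volume is the number of distinct
#' occupied voxels times the voxel volume.  The default 5 mm voxel matches
#' the scale at which a seedling canopy is compact but inter-plant gaps are
#' excluded.
#'
#' @param cloud a [colored_point_cloud()] with at least one point.
#' @param voxel_mm voxel edge length in mm (default 5).
#' @return volume in mm^3.
#' @export
voxel_volume <- function(cloud, voxel_mm = 5.0) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  if (voxel_mm <= 0) {
    stop_trayphen("voxel_mm must be positive", class = "trayphen_invalid_param")
  }
  if (n_points(cloud) == 0L) {
    stop_trayphen("cannot voxelize an empty cloud",
                  class = "trayphen_empty_cloud")
  }
  count_unique_cells(floor(cloud$points / voxel_mm)) * voxel_mm^3
}

#' Closed-mesh volume via the divergence theorem
#'
#' For a watertight, consistently oriented triangle mesh the enclosed volume
#' equals the absolute value of the signed sum of origin tetrahedra,
#' \eqn{|\sum_f \det(v_1, v_2, v_3)| / 6}.  Watertightness is verified first:
#' every edge must be shared by exactly two faces with opposite orientation.
#'
#' @param mesh a [triangle_mesh()].
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  if (nrow(f) < 4L) {
    stop_trayphen("mesh topology error: too few faces to close a surface",
                  class = "trayphen_mesh_topology")
  }
  nv <- nrow(mesh$vertices)
  enc <- function(a, b) (a - 1) * nv + b   # directed edge code, exact
  edges <- c(enc(f[, 1], f[, 2]), enc(f[, 2], f[, 3]), enc(f[, 3], f[, 1]))
  rev_edges <- c(enc(f[, 2], f[, 1]), enc(f[, 3], f[, 2]), enc(f[, 1], f[, 3]))
  if (anyDuplicated(edges)) {
    bad <- edges[duplicated(edges)][1]
    stop_trayphen("mesh topology error: directed edge (",
                  floor((bad - 1) / nv) + 1, " -> ",
                  (bad - 1) %% nv + 1,
                  ") appears more than once (inconsistent orientation)",
                  class = "trayphen_mesh_topology")
  }
  missing <- !(edges %in% rev_edges)
  if (any(missing)) {
    bad <- edges[missing][1]
    stop_trayphen("mesh topology error: edge (",
                  floor((bad - 1) / nv) + 1, " -> ",
                  (bad - 1) %% nv + 1,
                  ") has no opposite-facing twin (not watertight)",
                  class = "trayphen_mesh_topology")
  }
  v1 <- mesh$vertices[f[, 1], , drop = FALSE]
  v2 <- mesh$vertices[f[, 2], , drop = FALSE]
  v3 <- mesh$vertices[f[, 3], , drop = FALSE]
  det_sum <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2]) -
                 v1[, 2] * (v2[, 1] * v3[, 3] - v2[, 3] * v3[, 1]) +
                 v1[, 3] * (v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]))
  abs(det_sum) / 6
}

#' Full phenotype report for one calibrated scene
#'
#' Runs every phenotype estimator on the plant-classified points of a
#' calibrated cloud and returns them in one structure.
#'
#' @param plant_cloud calibrated plant-point [colored_point_cloud()].
#' @param prior a [tray_prior()] (for the canopy cover fraction).
#' @param top_fraction,cell_mm,voxel_mm,crosssection_z_mm,crosssection_hw_mm
#'   estimator parameters, see the individual functions.
#' @param mesh optional watertight [triangle_mesh()] for the closed-mesh
#'   volume.
#' @return object of class `phenotype_report`: a list with `height_mm`,
#'   `canopy_area_mm2`, `canopy_cover_fraction`, `crosssection_z_mm`,
#'   `crosssection_area_mm2`, `bbox_volume_mm3`, `voxel_volume_mm3`,
#'   `voxel_size_mm`, `mesh_volume_mm3` (or `NULL`), `n_points`.
#' @export
phenotype_report <- function(plant_cloud, prior = tray_prior(),
                             top_fraction = 0.05, cell_mm = 1.0,
                             voxel_mm = 5.0, crosssection_z_mm = 163,
                             crosssection_hw_mm = 5, mesh = NULL) {
  area <- projected_canopy_area(plant_cloud, cell_mm)
  cs <- cross_section(plant_cloud, crosssection_z_mm, crosssection_hw_mm,
                      cell_mm)
  structure(list(
    height_mm = estimate_plant_height(plant_cloud, top_fraction),
    canopy_area_mm2 = area,
    canopy_cover_fraction = area / (prior$length_mm * prior$width_mm),
    crosssection_z_mm = crosssection_z_mm,
    crosssection_area_mm2 = cs$area_mm2,
    crosssection_n_points = n_points(cs$slab),
    bbox_volume_mm3 = bbox_volume(plant_cloud),
    voxel_volume_mm3 = voxel_volume(plant_cloud, voxel_mm),
    voxel_size_mm = voxel_mm,
    mesh_volume_mm3 = if (!is.null(mesh)) mesh_volume(mesh) else NULL,
    n_points = n_points(plant_cloud)),
    class = "phenotype_report")
}
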