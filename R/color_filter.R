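#' Convert RGB colors to HSV with hue in degrees
#'
#' Standard hexcone conversion via [grDevices::rgb2hsv()], with hue rescaled
#' from `[0,1]` to degrees `[0,360)`.  Achromatic colors get hue 0.
#'
#' @param colors numeric `N x 3` matrix of red, green, blue in `[0,1]`.
#' @return numeric `N x 3` matrix with columns `h` (degrees), `s`, `v`.
#' @examples
#' rgb_to_hsv_deg(rbind(c(1, 0, 0), c(0, 0, 1)))
#' @export
rgb_to_hsv_deg <- function(colors) {
  colors <- as_coord_matrix(colors, "colors")
  if (nrow(colors) == 0L) {
    return(matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("h", "s", "v"))))
  }
  if (min(colors) < 0 || max(colors) > 1 || !all(is.finite(colors))) {
    stop_trayphen("colors must lie in [0, 1]", class = "trayphen_invalid_color")
  }
  hsv <- t(grDevices::rgb2hsv(t(colors), maxColorValue = 1))
  hsv[, 1] <- hsv[, 1] * 360
  hsv[hsv[, 1] >= 360, 1] <- 0
  dimnames(hsv) <- list(NULL, c("h", "s", "v"))
  hsv
}

#' HSV interval for range-based color classification
#'
#' Bounds are inclusive on both ends.  Hue is in degrees; `hue_min > hue_max`
#' denotes a wrap-around interval crossing 0 degrees (e.g. 350..10 keeps reds).
#'
#' @param hue_min,hue_max hue bounds in degrees, in `[0, 360]`.
#' @param sat_min,sat_max saturation bounds in `[0, 1]`, `min <= max`.
#' @param val_min,val_max value bounds in `[0, 1]`, `min <= max`.
#' @return an object of class `hsv_range`.
#' @export
hsv_range <- function(hue_min = 0, hue_max = 360,
                      sat_min = 0, sat_max = 1,
                      val_min = 0, val_max = 1) {
  vals <- c(hue_min, hue_max, sat_min, sat_max, val_min, val_max)
  if (!all(is.finite(vals))) {
    stop_trayphen("HSV bounds must be finite", class = "trayphen_invalid_range")
  }
  if (hue_min < 0 || hue_min > 360 || hue_max < 0 || hue_max > 360) {
    stop_trayphen("hue bounds must lie in [0, 360]",
                  class = "trayphen_invalid_range")
  }
  if (sat_min > sat_max || val_min > val_max ||
      min(sat_min, val_min) < 0 || max(sat_max, val_max) > 1) {
    stop_trayphen("saturation/value bounds must be ordered and in [0, 1]",
                  class = "trayphen_invalid_range")
  }
  structure(list(hue_min = hue_min, hue_max = hue_max,
                 sat_min = sat_min, sat_max = sat_max,
                 val_min = val_min, val_max = val_max),
            class = "hsv_range")
}

#' Default per-region HSV ranges
#'
#' Fixed engineering defaults for the four color roles of a tray scene:
#' green plant tissue, near-black tray plastic, dark-brown soil, and
#' near-white specular reflection noise.  All tunable via [hsv_range()].
#'
#' @return named list of [hsv_range()] objects
#'   (`plant`, `tray`, `soil`, `reflection`).
#' @export
default_region_ranges <- function() {
  list(
    plant      = hsv_range(60, 180, sat_min = 0.2, val_min = 0.15),
    tray       = hsv_range(val_min = 0, val_max = 0.15),
    soil       = hsv_range(10, 45, sat_min = 0.2, val_min = 0.1,
                           val_max = 0.5),
    reflection = hsv_range(sat_min = 0, sat_max = 0.1, val_min = 0.9)
  )
}

#' Test HSV triplets against a range
#' @param hsv numeric `N x 3` matrix (hue degrees, saturation, value).
#' @param range an [hsv_range()].
#' @return logical vector of length `N` (inclusive bounds, hue wrap-aware).
#' @export
hsv_in_range <- function(hsv, range) {
  h <- hsv[, 1]; s <- hsv[, 2]; v <- hsv[, 3]
  hue_ok <- if (range$hue_min <= range$hue_max) {
    h >= range$hue_min & h <= range$hue_max
  } else {
    h >= range$hue_min | h <= range$hue_max
  }
  hue_ok & s >= range$sat_min & s <= range$sat_max &
    v >= range$val_min & v <= range$val_max
}

#' Partition a cloud by an HSV range
#'
#' A point is kept iff its HSV triplet lies inside all three intervals of
#' `keep`; `kept` and `removed` partition the input and preserve ids.
#'
#' @param cloud a [colored_point_cloud()].
#' @param keep an [hsv_range()].
#' @return list with [colored_point_cloud()] elements `kept` and `removed`.
#' @export
filter_by_hsv <- function(cloud, keep) {
  stopifnot(inherits(cloud, "colored_point_cloud"),
            inherits(keep, "hsv_range"))
  inside <- hsv_in_range(rgb_to_hsv_deg(cloud$colors), keep)
  list(kept = subset_cloud(cloud, inside),
       removed = subset_cloud(cloud, !inside))
}

#' Extract a named color region from a cloud
#'
#' Color-based region isolation, e.g. pulling the black seedling-tray points
#' out of a full scene before calibration.
#'
#' @param cloud a [colored_point_cloud()].
#' @param ranges named list of [hsv_range()] (see [default_region_ranges()]).
#' @param label region name present in `ranges`.
#' @return the kept [colored_point_cloud()].
#' @export
extract_region <- function(cloud, ranges = default_region_ranges(), label) {
  if (!label %in% names(ranges)) {
    stop_trayphen("unknown region label '", label, "'",
                  class = "trayphen_unknown_region")
  }
  filter_by_hsv(cloud, ranges[[label]])$kept
}
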