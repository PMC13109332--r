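#' Per-point k-nearest-neighbor distance statistics
#'
#' For every point `p`, its `m` exact nearest neighbors (the query point
#' itself excluded) define a neighborhood; the returned statistics are the
#' mean Euclidean neighbor distance
#' \deqn{\bar d_p = \frac1m \sum_{j=1}^m \|p - q_j\|_2}
#' and the population standard deviation of those distances
#' \deqn{\sigma_p = \sqrt{\frac1m \sum_{j=1}^m (d_{p,q_j} - \bar d_p)^2}.}
#' Neighbors are found with a kd-tree; results are independent of point order
#' (equal-distance ties can swap which neighbor is chosen but never change
#' the distance multiset, hence never the statistics).
#'
#' @param cloud a [colored_point_cloud()] with at least `m + 1` points.
#' @param m number of neighbors (default 16).
#' @return object of class `neighborhood_stats`: list with numeric vectors
#'   `mean_dist`, `sd_dist` (length `N`) and the integer `m`.
#' @export
neighborhood_stats <- function(cloud, m = 16L) {
  stopifnot(inherits(cloud, "colored_point_cloud"))
  m <- as.integer(m)
  if (m < 1L) {
    stop_trayphen("m must be >= 1", class = "trayphen_invalid_param")
  }
  if (n_points(cloud) <= m) {
    stop_trayphen("too few points (", n_points(cloud),
                  ") for m = ", m, " neighbors",
                  class = "trayphen_too_few_points")
  }
  res <- knn_stats_cpp(cloud$points, m)
  structure(list(mean_dist = res$mean, sd_dist = res$sd, m = m),
            class = "neighborhood_stats")
}

#' Statistical outlier removal
#'
#' The per-point mean neighbor distances are pooled into a global mean
#' \eqn{\bar D} and a global dispersion \eqn{\Sigma} (the mean of the
#' per-point \eqn{\sigma_p} -- note this is the mean dispersion, not the
#' standard deviation of the \eqn{\bar d_p} values), and a point is removed
#' iff
#' \deqn{\bar d_p > \bar D + k \Sigma.}
#' Points whose neighborhoods are anomalously sparse -- reconstruction
#' outliers, floating reflection speckles -- exceed the threshold and are
#' dropped; the dense canopy/tray/soil structure passes through.
#'
#' @param cloud a [colored_point_cloud()].
#' @param m neighbors per point (default 16).
#' @param k threshold multiplier (default 1); larger keeps more points.
#' @return list with `kept` and `removed` ([colored_point_cloud()]s that
#'   partition the input with preserved ids) and `stats`, a
#'   `global_outlier_stats` list holding `mean_distance` (\eqn{\bar D}),
#'   `dispersion` (\eqn{\Sigma}), `k`, `threshold` and the per-point
#'   `neighborhood` statistics.
#' @export
remove_statistical_outliers <- function(cloud, m = 16L, k = 1.0) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0) {
    stop_trayphen("k must be a non-negative number",
                  class = "trayphen_invalid_param")
  }
  ns <- neighborhood_stats(cloud, m)
  d_bar <- mean(ns$mean_dist)
  sigma <- mean(ns$sd_dist)
  threshold <- d_bar + k * sigma
  out <- ns$mean_dist > threshold
  stats <- structure(list(mean_distance = d_bar, dispersion = sigma,
                          k = k, threshold = threshold, neighborhood = ns),
                     class = "global_outlier_stats")
  list(kept = subset_cloud(cloud, !out),
       removed = subset_cloud(cloud, out),
       stats = stats)
}
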