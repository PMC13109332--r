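#' Keypoint set
#'
#' `K x 2` pixel coordinates in image convention (origin top-left, x
#' rightward, y downward).
#'
#' @param xy numeric `K x 2` matrix or data frame with columns x, y.
#' @return a numeric matrix of class `keypoint_set`.
#' @export
keypoint_set <- function(xy) {
  xy <- as.matrix(xy)
  if (ncol(xy) != 2L || (nrow(xy) && !all(is.finite(xy)))) {
    stop_trayphen("keypoints must be a finite K x 2 matrix",
                  class = "trayphen_invalid_keypoints")
  }
  storage.mode(xy) <- "double"
  dimnames(xy) <- list(NULL, c("x", "y"))
  structure(xy, class = c("keypoint_set", class(xy)))
}

## projective application of a homography; rows mapped to infinity get NA
apply_homography <- function(h, xy) {
  p <- cbind(xy[, 1], xy[, 2], 1) %*% t(h)
  w <- p[, 3]
  bad <- abs(w) < 1e-12
  out <- p[, 1:2, drop = FALSE] / w
  out[bad, ] <- NA_real_
  out
}

min_dist_to_set <- function(from, to) {
  ## rows of `from` -> min Euclidean distance to any row of `to`
  d2 <- outer(from[, 1], to[, 1], "-")^2 + outer(from[, 2], to[, 2], "-")^2
  sqrt(apply(d2, 1L, min))
}

#' Keypoint repeatability under a homography
#'
#' A point of set A counts as repeatable if its projective mapping under
#' `h_ab` lies within `epsilon_px` (inclusive) of some point of B, and
#' symmetrically for B under the inverse homography.  Repeatability is the
#' repeated-point total over `N + M`:
#' \deqn{Rep = \frac{1}{N+M}\Big(\sum_i corr(x_i) + \sum_j corr(x_j)\Big).}
#' Points mapped to infinity count as non-repeatable.
#'
#' @param kps_a,kps_b [keypoint_set()]s, both nonempty.
#' @param h_ab 3x3 nonsingular homography taking image-A pixels to image B.
#' @param epsilon_px pixel distance threshold, positive.
#' @return object of class `match_eval_result`: list with `rep`, `corr_a`,
#'   `corr_b`, `n_a`, `n_b`, `epsilon_px`.
#' @export
repeatability <- function(kps_a, kps_b, h_ab, epsilon_px) {
  kps_a <- keypoint_set(kps_a); kps_b <- keypoint_set(kps_b)
  if (nrow(kps_a) == 0L || nrow(kps_b) == 0L) {
    stop_trayphen("repeatability is undefined for empty keypoint sets",
                  class = "trayphen_undefined_metric")
  }
  if (!is.numeric(epsilon_px) || epsilon_px <= 0) {
    stop_trayphen("epsilon_px must be positive",
                  class = "trayphen_invalid_param")
  }
  h_ab <- matrix(as.numeric(h_ab), 3L, 3L)
  if (abs(det(h_ab)) <= 1e-12) {
    stop_trayphen("homography is singular", class = "trayphen_invalid_param")
  }
  proj_a <- apply_homography(h_ab, kps_a)
  ok_a <- stats::complete.cases(proj_a)
  corr_a <- sum(min_dist_to_set(proj_a[ok_a, , drop = FALSE], kps_b) <=
                  epsilon_px)
  proj_b <- apply_homography(solve(h_ab), kps_b)
  ok_b <- stats::complete.cases(proj_b)
  corr_b <- sum(min_dist_to_set(proj_b[ok_b, , drop = FALSE], kps_a) <=
                  epsilon_px)
  structure(list(rep = (corr_a + corr_b) / (nrow(kps_a) + nrow(kps_b)),
                 corr_a = corr_a, corr_b = corr_b,
                 n_a = nrow(kps_a), n_b = nrow(kps_b),
                 epsilon_px = epsilon_px),
            class = "match_eval_result")
}

#' Keypoint localization error
#'
#' Mean over the detected points of the minimum Euclidean pixel distance to
#' any reference point,
#' \deqn{LE = \frac1N \sum_i \min_j \|x_i - \hat x_j\|.}
#' The symmetric variant averages the detected-to-reference and
#' reference-to-detected means.
#'
#' @param detected,reference nonempty [keypoint_set()]s.
#' @param symmetric average both directions (default `FALSE`).
#' @return localization error in pixels.
#' @export
localization_error <- function(detected, reference, symmetric = FALSE) {
  detected <- keypoint_set(detected); reference <- keypoint_set(reference)
  if (nrow(detected) == 0L || nrow(reference) == 0L) {
    stop_trayphen("localization error is undefined for empty keypoint sets",
                  class = "trayphen_undefined_metric")
  }
  le <- mean(min_dist_to_set(detected, reference))
  if (symmetric) {
    le <- (le + mean(min_dist_to_set(reference, detected))) / 2
  }
  le
}

#' Pixelwise confusion counts from binary masks
#'
#' @param predicted,truth logical or 0/1 matrices of identical shape; nonzero
#'   means foreground.
#' @return object of class `confusion_counts` with integers `tp`, `fp`,
#'   `tn`, `fn` summing to the pixel count.
#' @export
confusion_from_masks <- function(predicted, truth) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!identical(dim(predicted), dim(truth))) {
    stop_trayphen("mask shapes differ", class = "trayphen_invalid_param")
  }
  p <- predicted != 0; t_ <- truth != 0
  confusion_counts(tp = sum(p & t_), fp = sum(p & !t_),
                   tn = sum(!p & !t_), fn = sum(!p & t_))
}

#' Construct confusion counts directly
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop_trayphen("confusion counts must be non-negative integers",
                  class = "trayphen_invalid_param")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' Segmentation scores from confusion counts
#'
#' \deqn{IoU = \frac{TP}{TP+FP+FN},\quad
#'       Precision = \frac{TP}{TP+FP},\quad
#'       Recall = \frac{TP}{TP+FN}.}
#'
#' @param counts a `confusion_counts` object (see [confusion_from_masks()]).
#' @return object of class `segmentation_scores`: list with `iou`,
#'   `precision`, `recall`.
#' @export
segmentation_scores <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp + fp + fn == 0) {
    stop_trayphen("IoU undefined: TP + FP + FN = 0",
                  class = "trayphen_undefined_metric")
  }
  if (tp + fp == 0) {
    stop_trayphen("precision undefined: TP + FP = 0",
                  class = "trayphen_undefined_metric")
  }
  if (tp + fn == 0) {
    stop_trayphen("recall undefined: TP + FN = 0",
                  class = "trayphen_undefined_metric")
  }
  structure(list(iou = tp / (tp + fp + fn),
                 precision = tp / (tp + fp),
                 recall = tp / (tp + fn)),
            class = "segmentation_scores")
}

#' Regression agreement scores (RMSE, R-squared, relative RMSE)
#'
#' \deqn{RMSE = \sqrt{\tfrac1N \sum_i (H_p^i - H_{actual}^i)^2},\qquad
#'       R^2 = 1 - \frac{\sum_i (H_{actual}^i - H_p^i)^2}
#'                      {\sum_i (H_{actual}^i - \bar H_{actual})^2},}
#' and `rRMSE = 100 * RMSE / mean(actual)` percent.
#'
#' @param predicted,actual numeric vectors of equal length `N >= 2`; `actual`
#'   must not be constant.
#' @return object of class `regression_scores`: list with `rmse`,
#'   `r_squared`, `rrmse_percent`, `n`.
#' @export
regression_scores <- function(predicted, actual) {
  predicted <- as.numeric(predicted); actual <- as.numeric(actual)
  if (length(predicted) != length(actual)) {
    stop_trayphen("predicted and actual lengths differ",
                  class = "trayphen_invalid_param")
  }
  n <- length(actual)
  if (n < 2L) {
    stop_trayphen("need at least 2 observations",
                  class = "trayphen_invalid_param")
  }
  ss_tot <- sum((actual - mean(actual))^2)
  if (ss_tot == 0) {
    stop_trayphen("R-squared undefined: actual values are constant",
                  class = "trayphen_undefined_metric")
  }
  ss_res <- sum((actual - predicted)^2)
  rmse <- sqrt(ss_res / n)
  structure(list(rmse = rmse,
                 r_squared = 1 - ss_res / ss_tot,
                 rrmse_percent = 100 * rmse / mean(actual),
                 n = n),
            class = "regression_scores")
}
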