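test_that("repeatability reproduces hand-enumerated counts", {
  a <- keypoint_set(rbind(c(0, 0), c(10, 10)))
  b <- keypoint_set(rbind(c(0.5, 0), c(100, 100)))
  res <- repeatability(a, b, diag(3), epsilon_px = 1)
  expect_equal(res$corr_a, 1)
  expect_equal(res$corr_b, 1)
  expect_equal(res$rep, 0.5)

  same <- keypoint_set(matrix(runif(20), 10, 2))
  expect_equal(repeatability(same, same, diag(3), 1)$rep, 1)

  far <- keypoint_set(matrix(runif(10) + 1000, 5, 2))
  expect_equal(repeatability(same, far, diag(3), 1)$rep, 0)
})

test_that("repeatability is symmetric and monotone in epsilon", {
  set.seed(71)
  for (i in 1:20) {
    a <- keypoint_set(matrix(runif(2 * sample(3:15, 1), 0, 100), ncol = 2))
    b <- keypoint_set(matrix(runif(2 * sample(3:15, 1), 0, 100), ncol = 2))
    h <- diag(3) + matrix(rnorm(9, sd = 0.01), 3)
    eps <- sort(runif(3, 1, 40))
    reps <- vapply(eps, function(e) repeatability(a, b, h, e)$rep, numeric(1))
    expect_true(all(diff(reps) >= 0))
    expect_identical(repeatability(a, b, h, eps[2])$rep,
                     repeatability(b, a, solve(h), eps[2])$rep)
  }
})

test_that("repeatability validates its inputs", {
  a <- keypoint_set(matrix(runif(10), 5, 2))
  none <- keypoint_set(matrix(numeric(0), 0, 2))
  expect_error(repeatability(a, none, diag(3), 1),
               class = "trayphen_undefined_metric")
  expect_error(repeatability(a, a, matrix(1, 3, 3), 1),
               class = "trayphen_invalid_param")
  expect_error(repeatability(a, a, diag(3), 0),
               class = "trayphen_invalid_param")
})

test_that("localization error averages per-point minimum distances", {
  p <- keypoint_set(rbind(c(3, 4)))
  q <- keypoint_set(rbind(c(0, 0)))
  expect_equal(localization_error(p, q), 5)
  expect_equal(localization_error(p, p), 0)
  d <- keypoint_set(rbind(c(1, 0), c(0, 2)))
  r <- keypoint_set(rbind(c(0, 0), c(0, 1)))
  expect_equal(localization_error(d, r), 1)
  ## invariance under a common rigid motion
  set.seed(72)
  ang <- runif(1, 0, 2 * pi); shift <- rnorm(2, 0, 50)
  rot2 <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  expect_equal(localization_error(keypoint_set(d %*% t(rot2) +
                                                 rep(shift, each = 2)),
                                  keypoint_set(r %*% t(rot2) +
                                                 rep(shift, each = 2))),
               1, tolerance = 1e-9)
  expect_equal(localization_error(d, r, symmetric = TRUE),
               (1 + mean(c(1, 1))) / 2)
})

test_that("confusion counts agree with a per-pixel loop oracle", {
  truth <- matrix(0L, 10, 10); truth[1, 1:10] <- 1L
  cc <- confusion_from_masks(truth, truth)
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]),
               c(tp = 10, tn = 90, fp = 0, fn = 0))
  all_fg <- matrix(1L, 10, 10); all_bg <- matrix(0L, 10, 10)
  cc2 <- confusion_from_masks(all_fg, all_bg)
  expect_equal(unlist(cc2[c("tp", "fp", "tn", "fn")]),
               c(tp = 0, fp = 100, tn = 0, fn = 0))
  set.seed(73)
  p <- matrix(rbinom(400, 1, 0.4), 20)
  t_ <- matrix(rbinom(400, 1, 0.4), 20)
  cc3 <- confusion_from_masks(p, t_)
  tp <- fp <- tn <- fn <- 0
  for (i in 1:20) for (j in 1:20) {
    if (p[i, j] && t_[i, j]) tp <- tp + 1
    else if (p[i, j]) fp <- fp + 1
    else if (t_[i, j]) fn <- fn + 1
    else tn <- tn + 1
  }
  expect_equal(unlist(cc3[c("tp", "fp", "tn", "fn")]),
               c(tp = tp, fp = fp, tn = tn, fn = fn))
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 400)
  expect_error(confusion_from_masks(p, t_[1:10, ]),
               class = "trayphen_invalid_param")
})

test_that("segmentation scores follow the IoU/precision/recall formulas", {
  sc <- segmentation_scores(confusion_counts(8, 1, 90, 1))
  expect_equal(sc$iou, 0.8)
  expect_equal(sc$precision, 8 / 9)
  expect_equal(sc$recall, 8 / 9)
  perfect <- segmentation_scores(confusion_counts(10, 0, 90, 0))
  expect_equal(unlist(perfect), c(iou = 1, precision = 1, recall = 1))
  zero <- segmentation_scores(confusion_counts(0, 5, 90, 5))
  expect_equal(zero$iou, 0)
  expect_error(segmentation_scores(confusion_counts(0, 0, 100, 0)),
               class = "trayphen_undefined_metric")
  ## IoU is dominated by both precision and recall when TP > 0
  set.seed(74)
  for (i in 1:20) {
    sc <- segmentation_scores(confusion_counts(sample(1:50, 1),
                                               sample(0:50, 1), 10,
                                               sample(0:50, 1)))
    expect_lte(sc$iou, sc$precision)
    expect_lte(sc$iou, sc$recall)
  }
})

test_that("regression scores follow the RMSE and R-squared formulas", {
  exact <- regression_scores(c(1, 2, 3), c(1, 2, 3))
  expect_equal(exact$rmse, 0)
  expect_equal(exact$r_squared, 1)
  rs <- regression_scores(c(2, 4), c(1, 5))
  expect_equal(rs$rmse, 1)
  expect_equal(rs$r_squared, 0.75)
  expect_equal(rs$rrmse_percent, 100 / 3)
  flatline <- regression_scores(rep(mean(c(1, 5)), 2), c(1, 5))
  expect_equal(flatline$r_squared, 0)
  expect_error(regression_scores(c(1, 2), c(3, 3)),
               class = "trayphen_undefined_metric")
  expect_error(regression_scores(1:3, 1:4), class = "trayphen_invalid_param")
  ## closed form on arbitrary 2-point inputs
  set.seed(75)
  for (i in 1:10) {
    p <- rnorm(2); a <- rnorm(2)
    if (a[1] == a[2]) next
    rs <- regression_scores(p, a)
    expect_equal(rs$rmse, sqrt(sum((p - a)^2) / 2))
    expect_equal(rs$r_squared, 1 - sum((a - p)^2) / sum((a - mean(a))^2))
  }
})

test_that("points mapped to infinity count as non-repeatable", {
  h <- rbind(c(1, 0, 0), c(0, 1, 0), c(-1, 0, 1))   # sends x = 1 to infinity
  a <- keypoint_set(rbind(c(1, 0), c(0, 0)))
  b <- keypoint_set(rbind(c(0, 0)))
  res <- repeatability(a, b, h, 1)
  expect_equal(res$corr_a, 1)
})
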