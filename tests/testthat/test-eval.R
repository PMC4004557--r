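test_that("confusion counts and rates match hand arithmetic", {
  # constructed 10-pixel field: tp=3 fp=1 tn=5 fn=1
  pred <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
                 2, 5)
  gold <- matrix(c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
                 2, 5)
  m <- confusion(pred, gold)
  expect_equal(c(m$tp, m$fp, m$tn, m$fn), c(3, 1, 5, 1))
  expect_equal(m$tpr, 0.75)
  expect_equal(m$fpr, 1 / 6)
  expect_equal(m$acc, 0.8)

  # perfect agreement
  p <- matrix(stats::runif(64) < 0.4, 8)
  mm <- confusion(p, p)
  expect_equal(c(mm$tpr, mm$fpr, mm$acc), c(1, 0, 1))

  # swapping pred and gold swaps fn and fp, accuracy unchanged
  ms <- confusion(gold, pred)
  expect_equal(c(ms$fp, ms$fn), c(m$fn, m$fp))
  expect_equal(ms$acc, m$acc)

  # FOV restriction: counts sum to the FOV size
  fov <- matrix(c(rep(TRUE, 6), rep(FALSE, 4)), 2, 5)
  mf <- confusion(pred, gold, fov)
  expect_equal(mf$tp + mf$fp + mf$tn + mf$fn, 6)
  expect_error(confusion(pred, gold, matrix(FALSE, 2, 5)),
               class = "retseg_validation_error")
})

test_that("improvement percentages reproduce the published comparisons", {
  expect_equal(round(improvement(0.7556, 0.6220), 1), 21.5)
  expect_equal(round(improvement(0.0344, 0.0318), 2), 8.18)
  expect_equal(improvement(0.42, 0.42), 0)
  expect_true(improvement(0.8, 0.6) > 0 && improvement(0.6, 0.8) < 0)
  expect_error(improvement(0.5, 0), class = "retseg_validation_error")
})

test_that("overlay colours encode the confusion classes consistently", {
  set.seed(11)
  for (i in 1:10) {
    pred <- matrix(stats::runif(64 * 64) < 0.3, 64)
    gold <- matrix(stats::runif(64 * 64) < 0.3, 64)
    ov <- overlay_masks(pred, gold)$pixels
    blue <- ov[, , 3] == 1
    yellow <- ov[, , 1] == 1 & ov[, , 2] == 1
    green <- ov[, , 2] == 1 & ov[, , 1] == 0
    m <- confusion(pred, gold)
    expect_equal(sum(blue), m$tp)
    expect_equal(sum(yellow), m$fp)
    expect_equal(sum(green), m$fn)
  }
  # pred == gold: only blue and black
  p <- matrix(stats::runif(1024) < 0.4, 32)
  ov <- overlay_masks(p, p)$pixels
  expect_false(any(ov[, , 1] == 1 & ov[, , 2] == 1))
  # empty prediction: gold appears green
  ov2 <- overlay_masks(matrix(FALSE, 32, 32), p)$pixels
  expect_equal(sum(ov2[, , 2] == 1), sum(p))
})

test_that("edge-point closing connects segments and stops early when possible", {
  # two points 2 px apart connect with the initial s = 3
  pts <- data.frame(x = c(5, 7), y = c(5, 5))
  cm <- close_gt_edges(pts, s = 3, size = c(12, 12))
  expect_equal(count_components8(cm), 1L)
  expect_equal(attr(cm, "s"), 3)
  expect_true(cm[5, 5] && cm[5, 7])

  # an already 8-connected chain keeps its initial s
  chain <- data.frame(x = 3:10, y = rep(4, 8))
  cc <- close_gt_edges(chain, s = 3, size = c(12, 14))
  expect_equal(attr(cc, "s"), 3)
  expect_false(attr(cc, "unconnected"))
})

test_that("phantom edge points close into the true vessel band", {
  ph <- generate_phantom(phantom_spec(seed = 12, n_vessels = 2,
                                      pathology_blobs = 0))
  ep <- ph$truth$edge_points
  cm <- close_gt_edges(data.frame(x = c(ep$x1, ep$x2), y = c(ep$y1, ep$y2)),
                       size = c(256, 256), n_vessels = 2)
  gm <- ph$truth$gold_mask
  jac <- sum(cm & gm) / sum(cm | gm)
  expect_gte(jac, 0.85)
})

test_that("width protocol scores exact and perturbed predictions sensibly", {
  bar <- generate_bar(7, 0, 100, c(128, 128))
  recs <- profile_vessel(bar$mask)
  gx <- seq(18, 110, by = 3)
  gt <- data.frame(x1 = gx, y1 = 64 - 3, x2 = gx, y2 = 64 + 3)
  we <- width_protocol(recs, gt, size = c(128, 128))
  expect_equal(we$success_pct, 100)
  expect_equal(we$error_std, 0)
  # mean width = closed-segment pixels / centreline pixels; thinning
  # shortens the centreline at the bar ends, biasing the ratio slightly up
  expect_lt(abs(we$mean_width - 7), 0.75)

  # uniformly +2 px dilated prediction: wider mean, nonzero error std
  recs2 <- recs
  recs2$edge_ay <- recs2$edge_ay - 1
  recs2$edge_by <- recs2$edge_by + 1
  we2 <- width_protocol(recs2, gt, size = c(128, 128))
  expect_gt(we2$error_std, 0)
  expect_gt(we2$mean_width, we$mean_width + 1)
  expect_lt(abs(we2$mean_width - (we$mean_width + 2)), 1)

  expect_error(width_protocol(recs[0, ], gt, size = c(128, 128)),
               class = "retseg_validation_error")
})
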