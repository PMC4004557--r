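test_that("centreline thins a bar to a single mid-row line", {
  m <- matrix(FALSE, 24, 30); m[10:14, 6:25] <- TRUE
  cl <- centreline(m)
  pts <- which(cl, arr.ind = TRUE)
  expect_equal(unique(pts[, 1]), 12)        # the bar's middle row
  expect_gte(nrow(pts), 12)                 # ~20 px minus thinning end loss
  expect_equal(count_components8(cl), 1L)
  expect_true(all(cl[m]) || all(m[cl]))     # centreline subset of the mask

  # single pixel is already thin; empty mask stays empty
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_identical(centreline(one), one)
  expect_false(any(centreline(matrix(FALSE, 5, 5))))
})

test_that("centreline preserves 8-connected component counts and thinness", {
  set.seed(9)
  for (i in 1:20) {
    m <- matrix(stats::runif(40 * 40) < 0.3, 40, 40)
    m <- retseg:::dilate_binary(m, retseg:::disk_brush(1))
    cl <- centreline(m)
    expect_equal(count_components8(cl), count_components8(m))
    # no 2x2 all-true block survives
    blocks <- cl[-40, -40] & cl[-1, -40] & cl[-40, -1] & cl[-1, -1]
    expect_false(any(blocks))
  }
})

test_that("window enumeration matches the exhaustive pair oracle", {
  wc <- enumerate_window_configs()
  expect_equal(nrow(wc), 14)

  # oracle: all C(8,2) pairs of distinct 8-neighbour offsets, keeping those
  # whose 3-pixel path is coordinate-distinct along exactly one axis
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  n_valid <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    xd <- length(unique(c(offs$dx[i], 0, offs$dx[j]))) == 3
    yd <- length(unique(c(offs$dy[i], 0, offs$dy[j]))) == 3
    if (xor(xd, yd)) n_valid <- n_valid + 1
  }
  expect_equal(nrow(wc), n_valid)

  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  keys <- key(paste(wc$dx1, wc$dy1), paste(wc$dx2, wc$dy2))
  expect_true(key("-1 0", "1 0") %in% keys)          # straight vertical-x path
  expect_false(key("-1 -1", "1 1") %in% keys)        # both axes distinct
})

test_that("candidate detection walks straight lines and rejects branches", {
  l <- matrix(FALSE, 10, 20); l[5, 6:15] <- TRUE
  cand <- detect_candidates(l)
  expect_equal(nrow(cand), 8)                        # interior pixels only
  expect_true(all(abs(cand$dir_x) == 1 & cand$dir_y == 0))

  iso <- matrix(FALSE, 7, 7); iso[4, 4] <- TRUE
  expect_equal(nrow(detect_candidates(iso)), 0)

  # Y junction: the branch pixel (3 neighbours) is rejected
  yj <- matrix(FALSE, 15, 15)
  yj[8, 3:8] <- TRUE
  for (k in 1:5) { yj[8 - k, 8 + k] <- TRUE; yj[8 + k, 8 + k] <- TRUE }
  cand2 <- detect_candidates(yj)
  expect_false(any(cand2$x == 8 & cand2$y == 8))
})

test_that("width measurement is exact on axis-aligned bars", {
  bar <- generate_bar(5, 0, 40, c(64, 64))
  cx <- 32
  rec <- measure_width(bar$mask, c(cx, 32), c(1, 0))
  expect_equal(rec$width, 5)
  expect_equal(abs(rec$edge_ay - rec$edge_by), 4)
  expect_false(rec$clipped)

  # 1-px line measured perpendicular: width 1
  l <- matrix(FALSE, 11, 11); l[6, 2:10] <- TRUE
  expect_equal(measure_width(l, c(6, 6), c(1, 0))$width, 1)

  expect_error(measure_width(l, c(6, 1), c(1, 0)),
               class = "retseg_validation_error")
})

test_that("width recovery is accurate across widths and orientations", {
  errs <- c()
  for (w in c(3, 5, 7, 9, 11)) for (a in c(0, 30, 45, 60, 90)) {
    bar <- generate_bar(w, a, 44, c(72, 72))
    recs <- profile_vessel(bar$mask)
    expect_gt(nrow(recs), 0)
    errs <- c(errs, abs(recs$width - w))
    if (a %in% c(0, 90)) expect_true(all(recs$width == w))
  }
  expect_lte(mean(errs), 1.5)
})

test_that("profile_vessel returns constant widths on a bar and handles taper", {
  bar <- generate_bar(7, 0, 40, c(64, 64))
  recs <- profile_vessel(bar$mask)
  cl <- centreline(bar$mask)
  expect_equal(nrow(recs), nrow(detect_candidates(cl)))
  expect_lt(max(recs$width) - min(recs$width), 0.5 + 1e-9)

  expect_equal(nrow(profile_vessel(matrix(FALSE, 10, 10))), 0)

  # tapering bar 9 -> 3: widths non-increasing after a 5-record moving median
  n <- 80
  xs <- matrix(rep(1:n, each = n), n); ys <- t(xs)
  wline <- 9 - 6 * (xs - 10) / 60                   # width 9 at x=10, 3 at x=70
  taper <- abs(ys - 40) <= wline / 2 & xs >= 10 & xs <= 70
  recs_t <- profile_vessel(taper)
  recs_t <- recs_t[order(recs_t$x), ]
  med5 <- stats::runmed(recs_t$width, 5)
  inner <- 3:(length(med5) - 2)
  expect_true(all(diff(med5[inner]) <= 1e-9))
})

test_that("profiles crossing the image edge are flagged as clipped", {
  m <- matrix(TRUE, 9, 9)
  rec <- measure_width(m, c(5, 5), c(1, 0))
  expect_true(rec$clipped)
  expect_equal(rec$width, 9)
})
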