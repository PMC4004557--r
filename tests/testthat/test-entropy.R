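test_that("quantization maps [0,1] to integer levels with bounded error", {
  q <- quantize(matrix(1, 4, 4), 255)
  expect_true(all(q$levels == 255L))
  expect_equal(quantize(matrix(0.5, 4, 4), 16)$levels[1, 1], 8L)

  set.seed(5)
  g <- matrix(stats::runif(32 * 32), 32)
  for (L in c(15, 63, 255)) {
    err <- abs(dequantize(quantize(g, L)) - g)
    expect_lte(max(err), 1 / L + 1e-12)
  }
  expect_error(quantize(g, 10), class = "retseg_validation_error")
})

test_that("co-occurrence counts right and below transitions", {
  m <- structure(list(levels = matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE),
                      L = 15L), class = "quantized_image")
  C <- cooccurrence(m)
  expect_equal(C$counts[1, 2], 2L)   # t_{0,1}
  expect_equal(C$counts[2, 2], 2L)   # t_{1,1}
  expect_equal(sum(C$counts), 4L)
  expect_equal(sort(unique(as.vector(C$probs))), c(0, 0.5))

  # constant image: single diagonal entry holds every transition
  cc <- cooccurrence(quantize(matrix(0.5, 6, 6), 15))
  expect_equal(cc$counts[8, 8], 6 * 5 + 5 * 6)
  expect_equal(sum(cc$counts > 0), 1L)

  # total transition count formula on a 5 x 7 image
  c57 <- cooccurrence(quantize(matrix(stats::runif(35), 5, 7), 15))
  expect_equal(sum(c57$counts), 5 * 6 + 4 * 7)
})

test_that("entropy curve equals the naive quadrant-loop oracle", {
  set.seed(5)
  worst <- 0
  for (i in 1:20) {
    q <- quantize(matrix(stats::runif(32 * 32), 32), 15)
    C <- cooccurrence(q)
    E <- entropy_curve(C)
    worst <- max(worst, max(abs(E$h_total - naive_entropy_curve(C$probs, 15))))
    expect_equal(E$h_total, E$h_object + E$h_background, tolerance = 1e-12)
    expect_true(all(E$h_object >= 0 & E$h_background >= 0 & E$h_cross >= 0))
  }
  expect_lt(worst, 1e-9)
})

test_that("degenerate co-occurrence matrices give zero entropies", {
  # all mass at (0,0)
  C <- structure(list(counts = diag(c(10, rep(0, 15))),
                      probs = diag(c(1, rep(0, 15))), L = 15L),
                 class = "cooccurrence_matrix")
  E <- entropy_curve(C)
  expect_true(all(E$h_total == 0))

  # two deltas at (2,2) and (12,12): both quadrant entropies vanish between
  P <- matrix(0, 16, 16); P[3, 3] <- 0.5; P[13, 13] <- 0.5
  C2 <- structure(list(counts = P * 2, probs = P, L = 15L),
                  class = "cooccurrence_matrix")
  E2 <- entropy_curve(C2)
  mid <- E2$t >= 2 & E2$t < 12
  expect_true(all(E2$h_object[mid] == 0 & E2$h_background[mid] == 0))
})

test_that("optimal threshold takes the first argmax and survives transforms", {
  prof <- data.frame(t = 0:3, h_object = 0, h_background = 0,
                     h_total = c(0, 1, 3, 1), h_cross = 0)
  expect_equal(optimal_threshold(prof), 2)
  tie <- data.frame(t = 0:1, h_object = 0, h_background = 0,
                    h_total = c(2, 2), h_cross = 0)
  expect_warning(expect_equal(optimal_threshold(tie), 0), "flat")

  # invariance under a strictly increasing transform of the maximised total
  set.seed(5)
  q <- quantize(matrix(stats::runif(24 * 24), 24), 15)
  E <- entropy_curve(cooccurrence(q))
  t0 <- optimal_threshold(E, include_cross = FALSE)
  E2 <- E; E2$h_total <- exp(3 * E$h_total) - 0.5
  expect_equal(optimal_threshold(E2, include_cross = FALSE), t0)
})

test_that("bimodal image thresholds between the modes", {
  img <- bimodal_image(seed = 6)
  q <- quantize(img, 15)
  t_opt <- optimal_threshold(entropy_curve(cooccurrence(q)))
  expect_gt(t_opt, 3)
  expect_lt(t_opt, 12)

  b <- binarize(q, t_opt, scale = 1.0)
  expect_lt(mean(b != (q$levels >= 12)), 0.05)
})

test_that("binarize respects the FOV, scale monotonicity and regimes", {
  img <- bimodal_image(seed = 6)
  q <- quantize(img, 15)
  fov <- matrix(FALSE, 32, 32); fov[5:28, 5:28] <- TRUE
  expect_identical(binarize(q, 0, scale = 0.5, fov = fov), fov)

  t_opt <- optimal_threshold(entropy_curve(cooccurrence(q)))
  prev <- Inf
  for (s in c(0.3, 0.5, 0.8, 1.5, 3)) {
    n <- sum(binarize(q, t_opt, scale = s, fov = fov))
    expect_lte(n, prev)
    prev <- n
  }
  # mask regime is a superset of the reflex regime
  expect_true(all(binarize(q, t_opt, 1.5, fov) <= binarize(q, t_opt, 0.5, fov)))

  expect_warning(empty <- binarize(q, 15, scale = 3), "exceeds")
  expect_false(any(empty))
})
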