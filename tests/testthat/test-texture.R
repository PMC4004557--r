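test_that("subbands have image shape and no energy on constants", {
  sb <- texture_subbands(matrix(0.4, 48, 48), levels = 2, pool_sigma = 0)
  expect_length(sb$subbands, 2 * 6)
  expect_true(all(vapply(sb$subbands, function(m) max(abs(m)), 1) < 1e-8))
  expect_true(all(vapply(sb$subbands, function(m) identical(dim(m), c(48L, 48L)),
                         TRUE)))
  expect_error(texture_subbands(matrix(0, 6, 6), levels = 3),
               class = "retseg_validation_error")
})

test_that("fine and coarse textures separate by subband frequency", {
  set.seed(2)
  n <- 64
  img <- matrix(0, n, n)
  # left: fine checkerboard (2-px blocks); right: smooth blobs of period 16
  ch <- outer(1:n, 1:(n / 2), function(y, x) ((y - 1) %/% 2 + (x - 1) %/% 2) %% 2)
  img[, 1:(n / 2)] <- 0.4 + 0.3 * ch
  xs <- matrix(rep(1:(n / 2), each = n), n); ys <- matrix(rep(1:n, n / 2), n)
  img[, (n / 2 + 1):n] <- 0.55 + 0.25 * sin(2 * pi * ys / 16) * sin(2 * pi * xs / 16)
  sb <- texture_subbands(img, levels = 3, pool_sigma = 0)
  hi <- Reduce(`+`, sb$subbands[1:6])     # level 1 = highest frequency
  lo <- Reduce(`+`, sb$subbands[13:18])   # level 3 = lowest
  left <- cbind(rep(TRUE, n)) %*% rbind(1:n <= n / 2) > 0
  inner <- matrix(FALSE, n, n); inner[17:48, ] <- TRUE
  expect_gt(mean(hi[left & inner]), mean(hi[!left & inner]))
  expect_gt(mean(lo[!left & inner]), mean(lo[left & inner]))
})

test_that("watershed basin counts follow the gradient topology", {
  r1 <- watershed_oversegment(matrix(0.5, 30, 30), h = 0.05)
  expect_equal(r1$n_regions, 1L)        # constant gradient: no basins
  expect_true(all(r1$labels == 1L))
  expect_warning(watershed_oversegment(matrix(0.5, 30, 30), h = 0.6),
                 "single region")       # h above the gradient range

  n <- 40
  xs <- matrix(rep(1:n, each = n), n); ys <- t(xs)
  g <- 1 - 0.5 * exp(-((ys - 20)^2 + (xs - 12)^2) / 20) -
           0.5 * exp(-((ys - 20)^2 + (xs - 28)^2) / 20)
  g <- g - min(g)
  expect_equal(watershed_oversegment(g, h = 0.05)$n_regions, 2L)

  # increasing h never increases the region count
  prev <- Inf
  for (h in c(0.01, 0.05, 0.2, 0.45)) {
    nr <- watershed_oversegment(g, h = h)$n_regions
    expect_lte(nr, prev)
    prev <- nr
  }
})

test_that("watershed labels tile the FOV and ignore intensity offsets", {
  ph <- generate_phantom(phantom_spec(seed = 2, n_vessels = 0,
                                      pathology_blobs = 0, illum_gradient = 0))
  th <- tophat_preprocess(extract_green(ph$image), 30)
  fov <- ph$truth$fov
  feats <- texture_subbands(th)
  grad <- subband_gradient(feats)
  r <- watershed_oversegment(grad, fov = fov)
  expect_true(all(r$labels[fov] >= 1L))
  expect_true(all(r$labels[!fov] == 0L))
  expect_equal(sort(unique(as.vector(r$labels[fov]))), seq_len(r$n_regions))

  # subbands are zero-mean filters and the gradient is range-normalised:
  # an affine intensity transform changes nothing
  feats2 <- texture_subbands(th * 0.8 + 0.1)
  grad2 <- subband_gradient(feats2)
  r2 <- watershed_oversegment(grad2, fov = fov)
  expect_equal(r2$n_regions, r$n_regions)
})

test_that("region similarity graph weights behave", {
  # two regions with identical texture -> weight 1
  lab <- matrix(1L, 20, 20); lab[, 11:20] <- 2L
  regions <- structure(list(labels = lab, n_regions = 2L),
                       class = "region_label_image")
  feats <- texture_subbands(matrix(0.5, 20, 20), levels = 2, pool_sigma = 0)
  g <- build_rsg(regions, feats, matrix(0.5, 20, 20))
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$weight, 1, tolerance = 1e-9)

  # single region -> no edges
  one <- structure(list(labels = matrix(1L, 10, 10), n_regions = 1L),
                   class = "region_label_image")
  g1 <- build_rsg(one, texture_subbands(matrix(0.2, 10, 10), 2, pool_sigma = 0),
                  matrix(0.2, 10, 10))
  expect_equal(g1$n, 1)
  expect_equal(nrow(g1$edges), 0)
})

test_that("rsg weights are symmetric on a multi-region fixture", {
  set.seed(2)
  ph <- generate_phantom(phantom_spec(seed = 2, n_vessels = 0, pathology_blobs = 0))
  th <- tophat_preprocess(extract_green(ph$image), 30)
  feats <- texture_subbands(th)
  r <- watershed_oversegment(subband_gradient(feats), fov = ph$truth$fov)
  g <- build_rsg(r, feats, th)
  # stored once per unordered pair, a < b, no self-edges
  expect_true(all(g$edges$a < g$edges$b))
  expect_true(all(g$edges$weight > 0 & g$edges$weight <= 1))
  expect_equal(anyDuplicated(g$edges[, c("a", "b")]), 0L)
})

test_that("spectral partition recovers the two cliques exactly", {
  g <- two_clique_graph()
  cl <- spectral_partition(g, 2)
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_true(cl[1] != cl[10])

  # brute-force minimum normalized cut over all 2-partitions agrees
  W <- matrix(0, 10, 10)
  W[cbind(g$edges$a, g$edges$b)] <- g$edges$weight
  W <- W + t(W)
  best <- NULL; bestv <- Inf
  for (m in 1:(2^9 - 1)) {
    S <- which(bitwAnd(m, 2^(0:9)) > 0)
    if (length(S) < 1 || length(S) > 9) next
    Sb <- setdiff(1:10, S)
    cut <- sum(W[S, Sb, drop = FALSE])
    v <- cut / sum(W[S, ]) + cut / sum(W[Sb, ])
    if (v < bestv) { bestv <- v; best <- S }
  }
  expect_setequal(best, which(cl == cl[1]))

  expect_equal(spectral_partition(g, 1), rep(1L, 10))
})

test_that("spectral partition is invariant to node permutation", {
  set.seed(3)
  g <- two_clique_graph(weak = 0.05)
  # make features mildly informative so ties cannot occur
  g$features_std <- matrix(c(rep(0, 5), rep(1, 5)) + stats::rnorm(10, 0, 0.01), 10, 1)
  cl <- spectral_partition(g, 2)
  for (rep in 1:5) {
    perm <- sample(10)
    gp <- permute_graph(g, perm)
    clp <- spectral_partition(gp, 2)
    # clp at position perm[i] should match cl at i up to label swap
    back <- clp[perm]
    agreement <- mean(back == cl)
    expect_true(agreement == 1 || agreement == 0 ||
                all((back == back[1]) == (cl == cl[1])))
  }
})

test_that("merge_to_two separates the two noise textures and honours overrides", {
  ph <- generate_phantom(phantom_spec(seed = 2, n_vessels = 0,
                                      pathology_blobs = 0, illum_gradient = 0))
  th <- tophat_preprocess(extract_green(ph$image), 30)
  fov <- ph$truth$fov
  part <- partition_texture(th, fov)
  truth <- ph$truth$partition_truth
  infov <- truth > 0
  agree <- mean(part$labels[infov] == truth[infov])
  expect_gte(max(agree, 1 - agree), 0.85)
  expect_setequal(unique(as.vector(part$labels[infov])), c(1L, 2L))
  expect_true(all(part$labels[!infov] == 0L))
  expect_lt(part$connectivity_threshold["fine"],
            part$connectivity_threshold["coarse"])

  # one cluster -> single label with a warning
  lab <- matrix(0L, 32, 32); lab[9:24, 9:24] <- 1L
  regions <- structure(list(labels = lab, n_regions = 1L),
                       class = "region_label_image")
  expect_warning(p1 <- merge_to_two(1L, regions, matrix(0.5, 32, 32)), "single")
  expect_setequal(unique(as.vector(p1$labels[lab > 0])), 1L)

  # override forces a cluster to coarse
  lab2 <- matrix(0L, 32, 32); lab2[, 1:16] <- 1L; lab2[, 17:32] <- 2L
  regions2 <- structure(list(labels = lab2, n_regions = 2L),
                        class = "region_label_image")
  p2 <- suppressWarnings(
    merge_to_two(c(1L, 2L), regions2, matrix(0.5, 32, 32),
                 override = list(`2` = "coarse")))
  expect_true(all(p2$labels[, 17:32] == 2L))
})
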