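# Texture partition: oriented complex wavelet features, H-minima watershed
# over-segmentation, region similarity graph, spectral clustering, and the
# final merge into the two-label fine/coarse texture map that drives the
# texture-adaptive connectivity constraint.

#' Oriented complex wavelet texture subbands
#'
#' Complex (Gabor) wavelet filter bank: 6 orientations (0, 30, ..., 150
#' degrees) at `levels` dyadic scales.  Subband magnitudes are
#' median-filtered and returned at the source image resolution, ready for
#' per-region texture features.  A constant image has (numerically) zero
#' energy in every subband.
#'
#' Magnitudes are pooled with a Gaussian window (`pool_sigma`) so that
#' every pixel carries an estimate of the local texture energy rather than
#' the raw, granule-localised response; without pooling, flat background
#' pixels between noise granules are indistinguishable across texture
#' regions.
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param levels Number of dyadic scales, 2-5 (default 3).
#' @param median_size Odd median-filter window (default 3).
#' @param pool_sigma Gaussian texture-energy pooling scale in pixels
#'   (default 8, about the coarse-granule radius); 0 disables pooling.
#' @return A `subband_set` list: `subbands` (list of `H x W` magnitude
#'   matrices, orientation-major within level), `levels`, `orientations`.
#' @export
texture_subbands <- function(gray, levels = 3, median_size = 3, pool_sigma = 8) {
  assert_gray(gray)
  if (levels < 2 || levels > 5) validation_error("levels must lie in 2..5")
  if (median_size %% 2 != 1) validation_error("median_size must be odd")
  if (min(dim(gray)) < 2^levels)
    validation_error("image too small for the requested number of levels")
  half <- (median_size - 1) / 2
  orientations <- seq(0, 150, by = 30)
  subbands <- list()
  for (lev in seq_len(levels)) {
    lambda <- 3 * 2^(lev - 1)
    sigma <- 0.56 * lambda
    r <- as.integer(ceiling(2.5 * sigma))
    xs <- matrix(rep(-r:r, each = 2 * r + 1), 2 * r + 1)
    ys <- t(xs)
    for (th_deg in orientations) {
      th <- th_deg * pi / 180
      xr <- xs * cos(th) + ys * sin(th)
      yr <- -xs * sin(th) + ys * cos(th)
      env <- exp(-(xr^2 + 0.25 * yr^2) / (2 * sigma^2))
      kre <- env * cos(2 * pi * xr / lambda)
      kim <- env * sin(2 * pi * xr / lambda)
      kre <- kre - env * sum(kre) / sum(env)    # zero-mean real part (no DC)
      mag <- sqrt(filter_same(gray, kre)^2 + filter_same(gray, kim)^2)
      if (half >= 1) {
        hi <- max(mag)
        if (hi > 0)
          mag <- mat_from_eb(EBImage::medianFilter(eb_from_mat(mag / hi), half)) * hi
      }
      if (pool_sigma > 0)
        mag <- mat_from_eb(EBImage::gblur(eb_from_mat(mag), sigma = pool_sigma))
      subbands[[length(subbands) + 1L]] <- mag
    }
  }
  structure(list(subbands = subbands, levels = levels,
                 orientations = length(orientations)),
            class = "subband_set")
}

#' Texture gradient for watershed flooding
#'
#' Magnitude of the spatial (Sobel) gradient of the summed median-filtered
#' subband magnitudes, normalised to `[0, 1]`, then smoothed with a disk
#' closing (the structuring element that controls the H-minima transform).
#'
#' @param feats A `subband_set`.
#' @param closing_radius Disk radius of the pre-smoothing closing
#'   (default 4; up to 8 for smoother gradients); 0 disables it.
#' @return Gray matrix in `[0, 1]`.
#' @export
subband_gradient <- function(feats, closing_radius = 4) {
  if (!inherits(feats, "subband_set")) validation_error("feats must be a subband_set")
  total <- Reduce(`+`, feats$subbands)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  g <- sqrt(filter_same(total, kx)^2 + filter_same(total, t(kx))^2)
  g <- rescale01(g)
  if (closing_radius >= 1) g <- pmin(pmax(close_gray(g, disk_brush(closing_radius)), 0), 1)
  g
}

#' H-minima-controlled watershed over-segmentation
#'
#' Floods the inverted gradient with minima shallower than `h` suppressed,
#' producing an over-segmented tiling of the FOV into atomic regions.
#'
#' @param gradient Gradient magnitude in `[0, 1]`.
#' @param h Minima depth in `(0, 1]` (default 0.02).
#' @param fov Logical FOV mask.
#' @return A `region_label_image` list: `labels` (integer matrix, 0 outside
#'   the FOV), `n_regions`.
#' @export
watershed_oversegment <- function(gradient, h = 0.02, fov = NULL) {
  assert_unit_range(gradient, "gradient")
  if (h <= 0) validation_error("h must be > 0")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(gradient), ncol(gradient))
  assert_mask(fov, "fov")
  if (h >= max(gradient)) {
    warning("h exceeds the gradient range: single region")
    lab <- matrix(0L, nrow(gradient), ncol(gradient))
    lab[fov] <- 1L
    return(structure(list(labels = lab, n_regions = 1L), class = "region_label_image"))
  }
  inv <- (max(gradient) - gradient) + 1e-3
  inv[!fov] <- 0
  lab <- mat_from_eb(EBImage::watershed(eb_from_mat(inv), tolerance = h, ext = 1))
  lab <- matrix(as.integer(round(lab)), nrow(gradient), ncol(gradient))
  lab[!fov] <- 0L
  # assign any stray unlabelled FOV pixels to the nearest labelled neighbour
  for (it in 1:8) {
    holes <- fov & lab == 0L
    if (!any(holes)) break
    for (off in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      sh <- shift_mat(lab, off[1], off[2], fill = 0L)
      fill <- fov & lab == 0L & sh > 0L
      lab[fill] <- sh[fill]
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  lab[lab > 0L] <- match(lab[lab > 0L], ids)
  structure(list(labels = lab, n_regions = length(ids)), class = "region_label_image")
}

#' Region similarity graph
#'
#' Nodes are watershed regions carrying per-region mean feature vectors
#' (mean subband magnitudes, mean intensity, region area); edges connect
#' spatially adjacent regions with Gaussian-kernel similarity
#' `w = exp(-||f_a - f_b||^2 / (2 sigma_f^2))`, where `sigma_f` is the
#' median pairwise feature distance over the edges (features are
#' standardised across regions first).
#'
#' @param regions A `region_label_image`.
#' @param feats A `subband_set`.
#' @param gray Gray matrix (intensity feature source).
#' @return A `region_graph` list: `features` (region x feature matrix),
#'   `edges` (data.frame `a, b, weight`), `n`.
#' @export
build_rsg <- function(regions, feats, gray) {
  if (!inherits(regions, "region_label_image"))
    validation_error("regions must be a region_label_image")
  lab <- regions$labels
  n <- regions$n_regions
  idx <- lab[lab > 0L]
  area <- tabulate(idx, nbins = n)
  fmat <- vapply(feats$subbands,
                 function(s) tabulate_sum(idx, s[lab > 0L], n) / area,
                 numeric(n))
  if (n == 1) fmat <- matrix(fmat, nrow = 1)   # vapply drops to a vector
  fmat <- cbind(fmat,
                intensity = tabulate_sum(idx, gray[lab > 0L], n) / area,
                area = area)
  # similarity features: subband energy proportions (scale-invariant
  # spectral shape -- raw magnitudes track local contrast, not texture),
  # mean intensity, log area; standardised across regions
  ns <- length(feats$subbands)
  tot <- rowSums(fmat[, seq_len(ns), drop = FALSE])
  # regions with (numerically) no texture energy get zero proportions
  # rather than ratios of float noise
  tot[tot < 1e-8] <- Inf
  fsim <- cbind(fmat[, seq_len(ns), drop = FALSE] / tot,
                intensity = fmat[, "intensity"], area = log(fmat[, "area"]))
  fstd <- apply(fsim, 2, function(col) {
    s <- stats::sd(col)
    if (is.na(s) || s < 1e-12) rep(0, length(col)) else (col - mean(col)) / s
  })
  if (n == 1) fstd <- matrix(fstd, nrow = 1)

  pairs <- NULL
  for (off in list(c(0, 1), c(1, 0))) {
    sh <- shift_mat(lab, off[1], off[2], fill = 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) pairs <- rbind(pairs, cbind(pmin(lab[sel], sh[sel]),
                                              pmax(lab[sel], sh[sel])))
  }
  if (is.null(pairs) || nrow(pairs) == 0) {
    edges <- data.frame(a = integer(0), b = integer(0), weight = numeric(0))
  } else {
    pairs <- unique(pairs)
    d <- sqrt(rowSums((fstd[pairs[, 1], , drop = FALSE] -
                       fstd[pairs[, 2], , drop = FALSE])^2))
    pos <- d[d > 0]
    sigma_f <- if (length(pos)) stats::median(pos) else 1
    w <- exp(-d^2 / (2 * sigma_f^2))
    edges <- data.frame(a = pairs[, 1], b = pairs[, 2], weight = w)
  }
  structure(list(features = fmat, features_std = fstd, edges = edges, n = n),
            class = "region_graph")
}

# sum of `values` grouped by integer index 1..n
tabulate_sum <- function(idx, values, n) {
  as.numeric(rowsum(values, idx, reorder = TRUE)[match(seq_len(n), sort(unique(idx))), 1])
}

# Deterministic k-means: farthest-first seeding with lexicographic
# tie-breaks on the feature values, then Lloyd iterations.  Depends only on
# the set of row vectors, so the result is invariant to row permutation
# (up to cluster relabelling).
det_kmeans <- function(X, k) {
  n <- nrow(X)
  if (k >= n) return(seq_len(n))
  lex_order <- do.call(order, c(as.data.frame(-X), list(decreasing = FALSE)))
  ctr_mean <- colMeans(X)
  d0 <- sqrt(rowSums((X - matrix(ctr_mean, n, ncol(X), byrow = TRUE))^2))
  pick <- function(score) {
    best <- max(score)
    cand <- which(score >= best - 1e-12)
    cand[order(match(cand, lex_order))][1]
  }
  centres <- matrix(X[pick(d0), ], 1)
  while (nrow(centres) < k) {
    dmin <- apply(X, 1, function(p) min(sqrt(colSums((t(centres) - p)^2))))
    centres <- rbind(centres, X[pick(dmin), ])
  }
  assign <- rep(1L, n)
  for (it in 1:100) {
    dmat <- vapply(seq_len(nrow(centres)),
                   function(j) rowSums((X - matrix(centres[j, ], n, ncol(X), byrow = TRUE))^2),
                   numeric(n))
    new_assign <- max.col(-dmat, ties.method = "first")
    if (all(new_assign == assign) && it > 1) break
    assign <- new_assign
    for (j in seq_len(nrow(centres)))
      if (any(assign == j)) centres[j, ] <- colMeans(X[assign == j, , drop = FALSE])
  }
  assign
}

#' Normalized-cut spectral clustering of the region graph
#'
#' Row-normalised leading eigenvectors of the symmetric normalized
#' affinity `D^-1/2 W D^-1/2`, grouped with a deterministic centre-based
#' clustering.  Disconnected graphs are clustered per connected component
#' (cluster budget allocated proportionally to component size, at least one
#' each, never fewer than `k` clusters in total).
#'
#' @param graph A `region_graph`.
#' @param k Number of clusters (default 8), `1 <= k <= n`.
#' @return Integer cluster assignment per region (length `n`).
#' @export
spectral_partition <- function(graph, k = 8) {
  if (!inherits(graph, "region_graph")) validation_error("graph must be a region_graph")
  n <- graph$n
  if (k < 1 || k > n) validation_error("k must lie in 1..n")
  if (k == 1) return(rep(1L, n))
  W <- matrix(0, n, n)
  if (nrow(graph$edges)) {
    W[cbind(graph$edges$a, graph$edges$b)] <- graph$edges$weight
    W[cbind(graph$edges$b, graph$edges$a)] <- graph$edges$weight
  }
  # connected components (via adjacency reachability)
  comp <- integer(n); cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    frontier <- s; comp[s] <- cur
    while (length(frontier)) {
      nb <- which(colSums(W[frontier, , drop = FALSE] > 0) > 0)
      nb <- nb[comp[nb] == 0L]
      comp[nb] <- cur
      frontier <- nb
    }
  }
  ncomp <- max(comp)
  sizes <- tabulate(comp)
  total_k <- max(k, ncomp)
  alloc <- pmax(1L, floor(total_k * sizes / n))
  alloc <- pmin(alloc, sizes)
  while (sum(alloc) < total_k) {           # hand out remaining budget
    room <- which(alloc < sizes)
    if (!length(room)) break
    j <- room[which.max(sizes[room] / alloc[room])]
    alloc[j] <- alloc[j] + 1L
  }
  while (sum(alloc) > total_k) {
    j <- which(alloc > 1L)[which.max(alloc[alloc > 1L])]
    alloc[j] <- alloc[j] - 1L
  }

  out <- integer(n); offset <- 0L
  for (cc in seq_len(ncomp)) {
    members <- which(comp == cc)
    kk <- alloc[cc]
    if (kk == 1 || length(members) == 1) {
      out[members] <- offset + 1L
      offset <- offset + 1L
      next
    }
    Wc <- W[members, members, drop = FALSE]
    d <- rowSums(Wc)
    dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
    A <- Wc * outer(dinv, dinv)
    ev <- eigen(A, symmetric = TRUE)
    U <- ev$vectors[, seq_len(kk), drop = FALSE]
    rn <- sqrt(rowSums(U^2))
    U <- U / ifelse(rn > 0, rn, 1)
    cl <- det_kmeans(U, kk)
    out[members] <- offset + cl
    offset <- offset + max(cl)
  }
  match(out, sort(unique(out)))
}

#' Merge spectral clusters into the two-label texture partition
#'
#' Each cluster's texture granularity is summarised by the median area of
#' its above-threshold (Otsu) bright connected components ("granules");
#' an exact 1-D two-means split on the log granule sizes separates the
#' fine-grained clusters (label 1) from the coarse-grained ones (label 2).
#' An explicit override map forces chosen clusters to a label.
#'
#' @param clusters Integer cluster assignment per region.
#' @param regions The `region_label_image` the clusters refer to.
#' @param gray Gray image used to find bright granules.
#' Clusters whose bright-granule support is too small to size reliably
#' (fewer than 2% of their pixels above threshold) are assigned by
#' feature-space proximity to the granule-labelled groups when per-cluster
#' feature vectors are supplied.
#'
#' @param min_fine,min_coarse Connectivity thresholds (pixels) attached to
#'   the fine and coarse labels (defaults 5 and 16).
#' @param override Optional named list/vector mapping cluster id to
#'   `"fine"` or `"coarse"`.
#' @param features Optional cluster x feature matrix (e.g. mean
#'   standardised region features per cluster) used to place
#'   low-granule-support clusters.
#' @return A `texture_partition` list: `labels` (0 = outside FOV, 1 = fine,
#'   2 = coarse), `connectivity_threshold` (named vector).
#' @export
merge_to_two <- function(clusters, regions, gray, min_fine = 5, min_coarse = 16,
                         override = NULL, features = NULL) {
  if (!inherits(regions, "region_label_image"))
    validation_error("regions must be a region_label_image")
  lab <- regions$labels
  fov <- lab > 0L
  ncl <- max(clusters)
  pixel_cluster <- matrix(0L, nrow(lab), ncol(lab))
  pixel_cluster[fov] <- clusters[lab[fov]]

  cluster_label <- rep(1L, ncl)
  if (ncl == 1) {
    warning("single cluster: whole FOV labelled fine")
  } else {
    thr <- otsu_values(gray[fov])         # in-FOV histogram: the tophat
    granules <- label8(gray > thr & fov)  # response of the rim lies outside
    gsize <- rep(NA_real_, ncl)
    if (max(granules) > 0) {
      comp_area <- tabulate(granules[granules > 0], nbins = max(granules))
      # per-pixel granule size, summarised per cluster as the median over
      # the cluster's bright pixels.  This weights granules by the area
      # they actually contribute inside the cluster, so a cluster is not
      # tipped by a single large blob straddling its boundary, nor do many
      # small speckles outvote the blobs that cover most of the area.
      sel <- granules > 0 & pixel_cluster > 0
      px_area <- comp_area[granules[sel]]
      px_cl <- pixel_cluster[sel]
      cl_area <- tabulate(pixel_cluster[pixel_cluster > 0], nbins = ncl)
      support <- tabulate(px_cl, nbins = ncl)
      for (cl in seq_len(ncl))
        if (support[cl] >= 0.02 * cl_area[cl] && support[cl] > 0)
          gsize[cl] <- stats::median(px_area[px_cl == cl])
    }
    sized <- which(is.finite(gsize))
    if (length(sized) < 2 || diff(range(gsize[sized])) < 1e-12) {
      warning("all clusters have identical granule size: everything labelled fine")
    } else {
      # exact 1-D two-means split of the log granule sizes
      lg <- log(gsize[sized])
      ord <- order(lg); ns <- length(lg)
      best_sse <- Inf; best_split <- 1L
      for (s in seq_len(ns - 1)) {
        g1 <- lg[ord[1:s]]; g2 <- lg[ord[(s + 1):ns]]
        sse <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
        if (sse < best_sse) { best_sse <- sse; best_split <- s }
      }
      cluster_label[sized[ord[(best_split + 1):ns]]] <- 2L
      # clusters without reliable granule support: nearest labelled group in
      # feature space if available, otherwise fine
      unsized <- setdiff(seq_len(ncl), sized)
      if (length(unsized) && !is.null(features)) {
        for (grp_lab in c(1L, 2L)) assign(paste0("c", grp_lab),
          colMeans(features[sized[cluster_label[sized] == grp_lab], , drop = FALSE]))
        for (cl in unsized) {
          d1 <- sum((features[cl, ] - get("c1"))^2)
          d2 <- sum((features[cl, ] - get("c2"))^2)
          cluster_label[cl] <- if (d2 < d1) 2L else 1L
        }
      }
    }
  }
  if (!is.null(override)) {
    for (nm in names(override)) {
      cl <- as.integer(nm)
      cluster_label[cl] <- if (identical(override[[nm]], "coarse") ||
                               identical(override[[nm]], 2) ||
                               identical(override[[nm]], 2L)) 2L else 1L
    }
  }
  labels <- matrix(0L, nrow(lab), ncol(lab))
  labels[fov] <- cluster_label[pixel_cluster[fov]]
  structure(list(labels = labels,
                 connectivity_threshold = c(fine = min_fine, coarse = min_coarse)),
            class = "texture_partition")
}

#' Full texture partition of a preprocessed image
#'
#' Composes [texture_subbands()], [subband_gradient()],
#' [watershed_oversegment()], [build_rsg()], [spectral_partition()] and
#' [merge_to_two()].
#'
#' @param gray Preprocessed gray image (vessels/noise bright).
#' @param fov Logical FOV mask.
#' @param levels,k,hminima,hminima_radius,median_size See the stage
#'   functions.
#' @param min_fine,min_coarse,override Passed to [merge_to_two()].
#' @return A `texture_partition`.
#' @export
partition_texture <- function(gray, fov = NULL, levels = 3, k = 8,
                              hminima = 0.02, hminima_radius = 4,
                              median_size = 3, pool_sigma = 8,
                              min_fine = 5, min_coarse = 16,
                              override = NULL) {
  feats <- texture_subbands(gray, levels = levels, median_size = median_size,
                            pool_sigma = pool_sigma)
  grad <- subband_gradient(feats, closing_radius = hminima_radius)
  regions <- watershed_oversegment(grad, h = hminima, fov = fov)
  graph <- build_rsg(regions, feats, gray)
  kk <- min(k, regions$n_regions)
  clusters <- spectral_partition(graph, k = kk)
  # per-cluster mean similarity features (area-weighted over regions)
  areas <- graph$features[, "area"]
  cfeat <- do.call(rbind, lapply(seq_len(max(clusters)), function(cl) {
    sel <- clusters == cl
    colSums(graph$features_std[sel, , drop = FALSE] * areas[sel]) / sum(areas[sel])
  }))
  merge_to_two(clusters, regions, gray, min_fine = min_fine,
               min_coarse = min_coarse, override = override, features = cfeat)
}
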