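# Synthetic fundus phantom generator.
#
# The phantom emulates the properties of real fundus photographs that the
# segmentation pipeline is sensitive to: a bright circular field of view,
# curvilinear vessels of known width that are darker than the background in
# the green channel, an optional brighter core line simulating the central
# light reflex, a multiplicative illumination gradient, fine-grained noise
# confined to one image half and coarse-grained noise to the other (so the
# texture partition has an unambiguous ground truth), and optional bright
# pathology blobs.

#' Phantom specification
#'
#' Parameters of the synthetic fundus generator, with defaults representing
#' a DRIVE-like class-3 image (non-uniform illumination, pathology present,
#' vessel widths spanning the 3-9 px caliber range).
#'
#' @param size Image size `c(H, W)`.
#' @param n_vessels Number of vessels.
#' @param width_range Vessel width range `c(min, max)` in pixels.
#' @param tortuosity Curvature scale of the vessel paths (0 = straight),
#'   as a fraction of the chord length.
#' @param reflex Draw a central light reflex core line?
#' @param reflex_depth Reflex brightness relative to the vessel contrast.
#' @param reflex_core Core line width in pixels.
#' @param vessel_depth Vessel contrast (intensity dip) in the green channel.
#' @param illum_gradient Amplitude of the multiplicative illumination
#'   gradient, in `[0, 0.5]`.
#' @param fine_noise `c(density, granule)`: dark speckle coverage fraction
#'   and granule diameter (<= 4 px), confined to the left half of the
#'   frame.  Coverage is the expected fraction of the half-frame area
#'   occupied by granules.
#' @param coarse_noise `c(density, granule)`: blob coverage fraction and
#'   diameter (8-20 px), confined to the right half.
#' @param pathology_blobs Number of bright pathology blobs.
#' @param pathology_radius Radius range of pathology blobs, in pixels.
#' @param taper Optional `c(from, to)` width multiplier along each vessel
#'   (e.g. `c(1, 1)` = constant width).
#' @param seed Integer seed; the generator is bit-reproducible from it.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(size = c(256, 256), n_vessels = 6,
                         width_range = c(3, 9), tortuosity = 0.15,
                         reflex = TRUE, reflex_depth = 0.5, reflex_core = 1,
                         vessel_depth = 0.35, illum_gradient = 0.2,
                         fine_noise = c(density = 0.04, granule = 2),
                         coarse_noise = c(density = 0.08, granule = 12),
                         pathology_blobs = 2, pathology_radius = c(8, 16),
                         taper = c(1, 1), seed = 1) {
  spec <- list(size = as.integer(size), n_vessels = as.integer(n_vessels),
               width_range = width_range, tortuosity = tortuosity,
               reflex = isTRUE(reflex), reflex_depth = reflex_depth,
               reflex_core = reflex_core, vessel_depth = vessel_depth,
               illum_gradient = illum_gradient,
               fine_noise = unname(fine_noise), coarse_noise = unname(coarse_noise),
               pathology_blobs = as.integer(pathology_blobs),
               pathology_radius = pathology_radius, taper = taper,
               seed = as.integer(seed))
  if (any(spec$width_range < 1)) validation_error("vessel widths must be >= 1")
  if (spec$width_range[2] > min(spec$size))
    validation_error("vessel width exceeds the image size")
  if (spec$illum_gradient < 0 || spec$illum_gradient > 0.5)
    validation_error("illum_gradient must lie in [0, 0.5]")
  if (any(c(spec$fine_noise[1], spec$coarse_noise[1]) < 0) ||
      any(c(spec$fine_noise[1], spec$coarse_noise[1]) > 1))
    validation_error("noise densities must lie in [0, 1]")
  class(spec) <- "phantom_spec"
  spec
}

# Quadratic Bezier sample points between p0 and p2 with control point p1.
bezier_points <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  x <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  y <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(x = x, y = y)
}

# Euclidean distance of every pixel centre to the nearest of a set of
# (x, y) sample points, via the distance transform of the rasterized set.
dist_to_points <- function(pts, h, w) {
  m <- matrix(1, h, w)
  xi <- pmin(pmax(round(pts[, 1]), 1), w)
  yi <- pmin(pmax(round(pts[, 2]), 1), h)
  m[cbind(yi, xi)] <- 0
  mat_from_eb(EBImage::distmap(eb_from_mat(m)))
}

disc_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Generate a synthetic fundus phantom with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (a `fundus_image`) and `truth`, a
#'   list holding `gold_mask` (logical), `centreline_widths`
#'   (data.frame `x, y, true_width`), `partition_truth` (0 = outside FOV,
#'   1 = fine half, 2 = coarse half), `edge_points` (data.frame
#'   `x1, y1, x2, y2` of edge-point pairs), and `fov` (logical disc).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec")) validation_error("spec must be a phantom_spec")
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(spec$seed)

  h <- spec$size[1]; w <- spec$size[2]
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  r_fov <- 0.45 * min(h, w)
  fov <- disc_mask(h, w, cx, cy, r_fov)

  green <- matrix(0.08, h, w)
  green[fov] <- 0.65
  dip <- matrix(0, h, w)            # vessel intensity dip (max over vessels)
  reflex_add <- matrix(0, h, w)
  gold <- matrix(FALSE, h, w)

  cl_x <- cl_y <- cl_w <- numeric(0)
  e_x1 <- e_y1 <- e_x2 <- e_y2 <- numeric(0)

  if (spec$n_vessels > 0) for (v in seq_len(spec$n_vessels)) {
    wv <- stats::runif(1, spec$width_range[1], spec$width_range[2])
    a1 <- stats::runif(1, 0, 2 * pi)
    a2 <- a1 + stats::runif(1, pi / 2, 3 * pi / 2)
    p0 <- c(cx + 0.92 * r_fov * cos(a1), cy + 0.92 * r_fov * sin(a1))
    p2 <- c(cx + 0.92 * r_fov * cos(a2), cy + 0.92 * r_fov * sin(a2))
    chord <- sqrt(sum((p2 - p0)^2))
    mid <- (p0 + p2) / 2
    nrm <- c(-(p2 - p0)[2], (p2 - p0)[1]) / chord
    p1 <- mid + nrm * chord * spec$tortuosity * stats::runif(1, -1, 1)
    n_samp <- max(16L, as.integer(round(3 * chord)))
    pts <- bezier_points(p0, p1, p2, n_samp)
    keep <- (pts[, 1] - cx)^2 + (pts[, 2] - cy)^2 <= (0.95 * r_fov)^2
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 4) next

    tt <- seq(0, 1, length.out = nrow(pts))
    wloc <- wv * (spec$taper[1] + tt * (spec$taper[2] - spec$taper[1]))

    d <- dist_to_points(pts, h, w)
    # width varies along the path only under taper; use per-pixel nearest width
    if (abs(spec$taper[2] - spec$taper[1]) > 1e-12) {
      # nearest sample index per pixel (coarse: rasterized sample lookup)
      wmap <- matrix(mean(wloc), h, w)
      xi <- pmin(pmax(round(pts[, 1]), 1), w); yi <- pmin(pmax(round(pts[, 2]), 1), h)
      wpt <- matrix(NA_real_, h, w); wpt[cbind(yi, xi)] <- wloc
      # propagate nearest width by successive dilation of defined values
      for (it in 1:max(8, ceiling(max(wloc)))) {
        na <- is.na(wpt)
        if (!any(na & d <= max(wloc) / 2 + 1)) break
        for (off in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
          sh <- shift_mat(ifelse(is.na(wpt), NA_real_, wpt), off[1], off[2], fill = NA_real_)
          fill <- is.na(wpt) & !is.na(sh)
          wpt[fill] <- sh[fill]
        }
      }
      wmap[!is.na(wpt)] <- wpt[!is.na(wpt)]
      half <- wmap / 2
    } else half <- wv / 2

    band <- d <= half & fov
    gold <- gold | band
    prof <- pmin(pmax(half + 0.5 - d, 0), 1)    # trapezoid, 1-px shoulders
    dip <- pmax(dip, spec$vessel_depth * prof)
    if (spec$reflex) {
      core <- pmin(pmax(spec$reflex_core / 2 + 0.5 - d, 0), 1)
      reflex_add <- pmax(reflex_add, spec$reflex_depth * spec$vessel_depth * core)
    }

    # centreline/width/edge-point tables every ~2 px of arc length (dense,
    # REVIEW-style profile marks: a 3x3 closing can connect them)
    step <- max(2L, as.integer(round(nrow(pts) / (chord / 2))))
    idx <- seq(2, nrow(pts) - 1, by = step)
    tang <- cbind(pts[pmin(idx + 1, nrow(pts)), 1] - pts[pmax(idx - 1, 1), 1],
                  pts[pmin(idx + 1, nrow(pts)), 2] - pts[pmax(idx - 1, 1), 2])
    tn <- sqrt(rowSums(tang^2)); tang <- tang / pmax(tn, 1e-12)
    nvec <- cbind(-tang[, 2], tang[, 1])
    cl_x <- c(cl_x, pts[idx, 1]); cl_y <- c(cl_y, pts[idx, 2])
    cl_w <- c(cl_w, wloc[idx])
    e_x1 <- c(e_x1, pts[idx, 1] + nvec[, 1] * wloc[idx] / 2)
    e_y1 <- c(e_y1, pts[idx, 2] + nvec[, 2] * wloc[idx] / 2)
    e_x2 <- c(e_x2, pts[idx, 1] - nvec[, 1] * wloc[idx] / 2)
    e_y2 <- c(e_y2, pts[idx, 2] - nvec[, 2] * wloc[idx] / 2)
  }

  green <- green - dip * fov + reflex_add * fov

  # noise: dark granules; fine speckle on the left half, coarse blobs right
  add_granules <- function(img, half, density, granule, depth) {
    xs_rng <- if (half == "left") c(1, floor(w / 2)) else c(ceiling(w / 2) + 1, w)
    area <- diff(xs_rng) * h
    n <- max(0L, as.integer(round(density * area / max(1, granule^2))))
    if (n == 0) return(img)
    px <- round(stats::runif(n, xs_rng[1], xs_rng[2]))
    py <- round(stats::runif(n, 1, h))
    pt <- matrix(1, h, w); pt[cbind(py, px)] <- 0
    d <- mat_from_eb(EBImage::distmap(eb_from_mat(pt)))
    img - depth * pmin(pmax(granule / 2 + 0.5 - d, 0), 1) * fov
  }
  green <- add_granules(green, "left", spec$fine_noise[1], spec$fine_noise[2], 0.12)
  green <- add_granules(green, "right", spec$coarse_noise[1], spec$coarse_noise[2], 0.10)

  if (spec$pathology_blobs > 0) for (b in seq_len(spec$pathology_blobs)) {
    rb <- stats::runif(1, spec$pathology_radius[1], spec$pathology_radius[2])
    ang <- stats::runif(1, 0, 2 * pi); rad <- stats::runif(1, 0, 0.7 * r_fov)
    bx <- cx + rad * cos(ang); by <- cy + rad * sin(ang)
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), w), h, w)
    db <- sqrt((xs - bx)^2 + (ys - by)^2)
    green <- green + 0.18 * pmin(pmax((rb - db) / 2 + 0.5, 0), 1) * fov
  }

  # multiplicative illumination gradient (diagonal)
  if (spec$illum_gradient > 0) {
    xs <- matrix(rep(seq_len(w), each = h), h, w)
    ys <- matrix(rep(seq_len(h), w), h, w)
    g <- 1 + spec$illum_gradient * ((xs - cx) / w + (ys - cy) / h)
    green <- green * g
  }
  green <- pmin(pmax(green, 0), 1)

  px <- array(0, c(h, w, 3))
  px[, , 1] <- pmin(pmax(green * 1.35 + 0.05 * fov, 0), 1)
  px[, , 2] <- green
  px[, , 3] <- pmin(pmax(green * 0.45, 0), 1)

  part <- matrix(0L, h, w)
  part[fov] <- ifelse(matrix(rep(seq_len(w), each = h), h, w)[fov] <= w / 2, 1L, 2L)

  keep <- is.finite(cl_w)
  list(image = fundus_image(px, source_path = sprintf("<phantom seed %d>", spec$seed)),
       truth = list(gold_mask = gold,
                    centreline_widths = data.frame(x = cl_x[keep], y = cl_y[keep],
                                                   true_width = cl_w[keep]),
                    partition_truth = part,
                    edge_points = data.frame(x1 = e_x1[keep], y1 = e_y1[keep],
                                             x2 = e_x2[keep], y2 = e_y2[keep]),
                    fov = fov),
       spec = spec)
}

#' Generate an oriented bar mask of known width
#'
#' Rasterizes a straight bar whose perpendicular thickness is the requested
#' width: a pixel is foreground when its perpendicular distance to the bar
#' axis is at most `width / 2` and its along-axis distance at most
#' `length / 2`.
#'
#' @param width Bar width (perpendicular thickness), pixels.
#' @param angle Bar orientation in degrees (0 = horizontal), measured from
#'   the x-axis with y increasing downward.
#' @param length Bar length in pixels.
#' @param size Image size `c(H, W)`.
#' @return A list with `mask` (logical `H x W`) and `true_width`.
#' @export
generate_bar <- function(width, angle = 0, length = 40, size = c(64, 64)) {
  if (width < 1) validation_error("bar width must be >= 1")
  h <- size[1]; w <- size[2]
  cx <- floor((w + 1) / 2); cy <- floor((h + 1) / 2)   # integer centre pixel
  th <- angle * pi / 180
  dvec <- c(cos(th), sin(th))
  nvec <- c(-sin(th), cos(th))
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), w), h, w)
  along <- (xs - cx) * dvec[1] + (ys - cy) * dvec[2]
  perp <- (xs - cx) * nvec[1] + (ys - cy) * nvec[2]
  list(mask = abs(perp) <= width / 2 & abs(along) <= length / 2,
       true_width = width)
}
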