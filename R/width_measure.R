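# Vessel centreline extraction and width measurement.
#
# The segmentation mask is thinned to a one-pixel centreline (Zhang-Suen
# thinning followed by pruning of short spurs).  Each centreline pixel
# whose 3x3 neighbourhood forms a three-pixel path with distinct
# coordinates along exactly one image axis becomes a measurement
# candidate; the local direction is rotated 90 degrees counter-clockwise
# and the perpendicular profile is walked outward to the first background
# pixel on each side.  The vessel width is the Euclidean distance between
# the two edge pixels plus one (pixel extent), which agrees with the
# pixel-count definition on axis-aligned bars.
#
# Coordinates are 1-based, (x = column, y = row), y increasing downward;
# rotation by 90 degrees CCW maps (dx, dy) -> (dy, -dx).

# 8-neighbour shifts of a logical matrix, in the Zhang-Suen order
# p2..p9 = N, NE, E, SE, S, SW, W, NW.
neighbour_stack <- function(m) {
  list(n  = shift_mat(m,  1,  0), ne = shift_mat(m,  1, -1),
       e  = shift_mat(m,  0, -1), se = shift_mat(m, -1, -1),
       s  = shift_mat(m, -1,  0), sw = shift_mat(m, -1,  1),
       w  = shift_mat(m,  0,  1), nw = shift_mat(m,  1,  1))
}

zhang_suen <- function(mask) {
  m <- mask * 1
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      nb <- neighbour_stack(m)
      p2 <- nb$n; p3 <- nb$ne; p4 <- nb$e; p5 <- nb$se
      p6 <- nb$s; p7 <- nb$sw; p8 <- nb$w; p9 <- nb$nw
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

neighbour_count <- function(mask) {
  Reduce(`+`, neighbour_stack(mask * 1))
}

# Remove spurs shorter than `max_len` pixels: walk from each endpoint; if a
# branch point is reached within max_len - 1 steps, delete the walked path.
prune_spurs <- function(cl, max_len = 3) {
  repeat {
    cnt <- neighbour_count(cl)
    ends <- which(cl & cnt == 1, arr.ind = TRUE)
    if (nrow(ends) == 0) break
    removed_any <- FALSE
    for (i in seq_len(nrow(ends))) {
      path <- list(ends[i, ])
      prev <- NULL
      cur <- ends[i, ]
      hit_branch <- FALSE
      while (length(path) < max_len) {
        ys <- max(1, cur[1] - 1):min(nrow(cl), cur[1] + 1)
        xs <- max(1, cur[2] - 1):min(ncol(cl), cur[2] + 1)
        nbrs <- which(cl[ys, xs, drop = FALSE], arr.ind = TRUE)
        nbrs <- cbind(ys[nbrs[, 1]], xs[nbrs[, 2]])
        nbrs <- nbrs[!(nbrs[, 1] == cur[1] & nbrs[, 2] == cur[2]), , drop = FALSE]
        if (!is.null(prev))
          nbrs <- nbrs[!(nbrs[, 1] == prev[1] & nbrs[, 2] == prev[2]), , drop = FALSE]
        if (nrow(nbrs) == 0) break
        if (nrow(nbrs) > 1 || cnt[nbrs[1, 1], nbrs[1, 2]] >= 3) { hit_branch <- TRUE; break }
        prev <- cur
        cur <- nbrs[1, ]
        path[[length(path) + 1L]] <- cur
      }
      if (hit_branch && length(path) < max_len) {
        for (p in path) cl[p[1], p[2]] <- FALSE
        removed_any <- TRUE
      }
    }
    if (!removed_any) break
  }
  cl
}

# Skeletonisation pass: reduce the thinned lines to minimal 8-connected
# paths.  Zhang-Suen leaves 4-connected staircases whose corner pixels have
# three neighbours and would read as branch points; a pixel with 2 or 3
# neighbours is deleted (sequentially, in scan order) when its neighbours
# remain mutually 8-connected without it.
skeleton_reduce <- function(cl) {
  h <- nrow(cl); w <- ncol(cl)
  repeat {
    removed <- FALSE
    px <- which(cl, arr.ind = TRUE)
    px <- px[order(px[, 1], px[, 2]), , drop = FALSE]
    for (i in seq_len(nrow(px))) {
      yy <- px[i, 1]; xx <- px[i, 2]
      if (!cl[yy, xx]) next
      ys <- max(1, yy - 1):min(h, yy + 1)
      xs <- max(1, xx - 1):min(w, xx + 1)
      nbrs <- which(cl[ys, xs, drop = FALSE], arr.ind = TRUE)
      nbrs <- cbind(ys[nbrs[, 1]], xs[nbrs[, 2]])
      nbrs <- nbrs[!(nbrs[, 1] == yy & nbrs[, 2] == xx), , drop = FALSE]
      k <- nrow(nbrs)
      if (k < 2 || k > 5) next
      # adjacency graph of the neighbours (Chebyshev distance 1)
      adj <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b)
        a != b && max(abs(nbrs[a, ] - nbrs[b, ])) <= 1))
      connected <- if (k == 2) adj[1, 2] else {
        reach <- adj[1, ] | seq_len(k) == 1
        for (r in 1:k) reach <- reach | (reach %*% adj > 0)
        all(reach)
      }
      if (connected) { cl[yy, xx] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  cl
}

# Knock out 2x2 all-true blocks left by thinning: delete a block pixel
# whose removal keeps its neighbourhood connected (crossing number 1).
squash_blocks <- function(cl) {
  repeat {
    blocks <- cl & shift_mat(cl, 0, -1) & shift_mat(cl, -1, 0) & shift_mat(cl, -1, -1)
    if (!any(blocks)) break
    cnt <- neighbour_count(cl)
    nb <- neighbour_stack(cl * 1)
    A <- (nb$n == 0 & nb$ne == 1) + (nb$ne == 0 & nb$e == 1) + (nb$e == 0 & nb$se == 1) +
         (nb$se == 0 & nb$s == 1) + (nb$s == 0 & nb$sw == 1) + (nb$sw == 0 & nb$w == 1) +
         (nb$w == 0 & nb$nw == 1) + (nb$nw == 0 & nb$n == 1)
    cand <- which(blocks & A == 1 & cnt > 1, arr.ind = TRUE)
    if (nrow(cand) == 0) break
    cl[cand[1, 1], cand[1, 2]] <- FALSE
  }
  cl
}

#' Extract the one-pixel vessel centreline
#'
#' Zhang-Suen thinning to quasi-one-pixel lines, removal of residual 2x2
#' blocks, and pruning of spurs shorter than 3 pixels.  The 8-connected
#' component count of the input is preserved.
#'
#' @param mask Logical segmentation mask.
#' @return Logical centreline matrix (subset of `mask`).
#' @export
centreline <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(mask)
  cl <- zhang_suen(mask)
  cl <- squash_blocks(cl)
  cl <- skeleton_reduce(cl)
  prune_spurs(cl, max_len = 3)
}

#' Enumerate the valid 3x3 measurement windows
#'
#' All unordered pairs of distinct 8-neighbour offsets such that the
#' three-pixel path (offset, centre, offset) has pairwise-distinct
#' coordinates along exactly one image axis.  There are 14 such windows.
#'
#' @return A data.frame with columns `dx1, dy1, dx2, dy2` (the two offsets)
#'   and `axis` (`"x"` or `"y"`, the axis along which the coordinates are
#'   distinct).
#' @export
enumerate_window_configs <- function() {
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  out <- NULL
  for (i in seq_len(nrow(offs) - 1)) for (j in (i + 1):nrow(offs)) {
    dx1 <- offs$dx[i]; dy1 <- offs$dy[i]
    dx2 <- offs$dx[j]; dy2 <- offs$dy[j]
    x_distinct <- length(unique(c(dx1, 0, dx2))) == 3
    y_distinct <- length(unique(c(dy1, 0, dy2))) == 3
    if (xor(x_distinct, y_distinct))
      out <- rbind(out, data.frame(dx1 = dx1, dy1 = dy1, dx2 = dx2, dy2 = dy2,
                                   axis = if (x_distinct) "x" else "y"))
  }
  out
}

#' Detect width-measurement candidate points on the centreline
#'
#' A centreline pixel is a candidate when it has exactly two centreline
#' neighbours whose offsets form a three-pixel path with distinct
#' coordinates along at least one axis.  When the path is distinct along
#' both axes (a straight diagonal) both orientation groups match and the
#' tie-break keeps the configuration, which leaves the measurement
#' direction unchanged.  Branch pixels (3 or more neighbours) and
#' endpoints are rejected.  The direction is the unit vector from the
#' first to the last pixel of the path.
#'
#' @param cl Logical centreline matrix.
#' @return A data.frame `x, y, dir_x, dir_y` in scan order (row-major).
#' @export
detect_candidates <- function(cl) {
  assert_mask(cl, "cl")
  cnt <- neighbour_count(cl)
  cand <- which(cl & cnt == 2, arr.ind = TRUE)
  if (nrow(cand) == 0)
    return(data.frame(x = integer(0), y = integer(0),
                      dir_x = numeric(0), dir_y = numeric(0)))
  ord <- order(cand[, 1], cand[, 2])           # scan order: row-major
  cand <- cand[ord, , drop = FALSE]
  res_x <- res_y <- integer(0); res_dx <- res_dy <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    yy <- cand[i, 1]; xx <- cand[i, 2]
    ys <- max(1, yy - 1):min(nrow(cl), yy + 1)
    xs <- max(1, xx - 1):min(ncol(cl), xx + 1)
    nbrs <- which(cl[ys, xs, drop = FALSE], arr.ind = TRUE)
    nbrs <- cbind(y = ys[nbrs[, 1]], x = xs[nbrs[, 2]])
    nbrs <- nbrs[!(nbrs[, 1] == yy & nbrs[, 2] == xx), , drop = FALSE]
    if (nrow(nbrs) != 2) next
    dx1 <- nbrs[1, 2] - xx; dy1 <- nbrs[1, 1] - yy
    dx2 <- nbrs[2, 2] - xx; dy2 <- nbrs[2, 1] - yy
    x_distinct <- length(unique(c(dx1, 0, dx2))) == 3
    y_distinct <- length(unique(c(dy1, 0, dy2))) == 3
    # paths distinct along both axes (straight diagonals) are kept: the two
    # orientation groups both match and the tie-break selects one of them,
    # which leaves the measurement direction unchanged
    if (!x_distinct && !y_distinct) next
    vx <- dx2 - dx1; vy <- dy2 - dy1
    nn <- sqrt(vx^2 + vy^2)
    res_x <- c(res_x, xx); res_y <- c(res_y, yy)
    res_dx <- c(res_dx, vx / nn); res_dy <- c(res_dy, vy / nn)
  }
  data.frame(x = res_x, y = res_y, dir_x = res_dx, dir_y = res_dy)
}

#' Measure the vessel width at a centre point
#'
#' The centreline direction is rotated 90 degrees counter-clockwise
#' (`(dx, dy) -> (dy, -dx)`) and the perpendicular profile is rasterized
#' from the centre outward in both senses, stepping one pixel along the
#' dominant axis, until the first background pixel (or the image edge).
#' The edge points are the outermost foreground pixels reached and the
#' width is their Euclidean distance plus one.
#'
#' @param mask Logical segmentation mask.
#' @param centre `c(x, y)` centre pixel (must be foreground).
#' @param direction `c(dx, dy)` unit vector along the local centreline.
#' @param gap_tolerance Number of consecutive background pixels the profile
#'   may step across (default 0).
#' @return A one-row data.frame: `x, y, dir_x, dir_y, edge_ax, edge_ay,
#'   edge_bx, edge_by, width, clipped`.
#' @export
measure_width <- function(mask, centre, direction, gap_tolerance = 0) {
  assert_mask(mask)
  xx <- centre[1]; yy <- centre[2]
  if (!mask[yy, xx]) validation_error("centre must be a foreground pixel")
  pdx <- direction[2]; pdy <- -direction[1]    # 90 deg CCW, y down
  s <- max(abs(pdx), abs(pdy))
  if (s < 1e-12) validation_error("direction must be a nonzero unit vector")
  pdx <- pdx / s; pdy <- pdy / s
  h <- nrow(mask); w <- ncol(mask)
  walk <- function(sign) {
    last <- c(xx, yy); clipped <- FALSE; gaps <- 0L
    t <- 1
    repeat {
      px <- round(xx + sign * t * pdx); py <- round(yy + sign * t * pdy)
      if (px < 1 || px > w || py < 1 || py > h) { clipped <- TRUE; break }
      if (mask[py, px]) { last <- c(px, py); gaps <- 0L }
      else { gaps <- gaps + 1L; if (gaps > gap_tolerance) break }
      t <- t + 1
    }
    list(edge = last, clipped = clipped)
  }
  a <- walk(+1); b <- walk(-1)
  width <- sqrt(sum((a$edge - b$edge)^2)) + 1
  data.frame(x = xx, y = yy, dir_x = direction[1], dir_y = direction[2],
             edge_ax = a$edge[1], edge_ay = a$edge[2],
             edge_bx = b$edge[1], edge_by = b$edge[2],
             width = width, clipped = a$clipped || b$clipped)
}

#' Measure widths at every candidate point of a mask
#'
#' Extracts the centreline, detects candidates, and measures the width at
#' each; records are returned in scan order.
#'
#' @param mask Logical segmentation mask.
#' @param gap_tolerance Passed to [measure_width()].
#' @return A data.frame of width records (possibly empty).
#' @export
profile_vessel <- function(mask, gap_tolerance = 0) {
  assert_mask(mask)
  empty <- data.frame(x = integer(0), y = integer(0),
                      dir_x = numeric(0), dir_y = numeric(0),
                      edge_ax = integer(0), edge_ay = integer(0),
                      edge_bx = integer(0), edge_by = integer(0),
                      width = numeric(0), clipped = logical(0))
  if (!any(mask)) return(empty)
  cl <- centreline(mask)
  cand <- detect_candidates(cl)
  if (nrow(cand) == 0) return(empty)
  recs <- lapply(seq_len(nrow(cand)), function(i)
    measure_width(mask, c(cand$x[i], cand$y[i]),
                  c(cand$dir_x[i], cand$dir_y[i]), gap_tolerance))
  do.call(rbind, recs)
}
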