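# Pixel-level segmentation metrics, improvement percentages, tri-colour
# overlays, and the edge-point width-validation protocol.

#' Confusion counts and rates between a predicted and gold mask
#'
#' Counts are restricted to the FOV.  `TPR = TP/(TP+FN)`,
#' `FPR = FP/(FP+TN)`, `ACC = (TP+TN)/(TP+FP+TN+FN)`.
#'
#' @param pred,gold Logical masks.
#' @param fov Logical FOV mask (default: everywhere).
#' @return An `eval_metrics` list: `tp, fp, tn, fn, tpr, fpr, acc`.
#' @export
confusion <- function(pred, gold, fov = NULL) {
  assert_mask(pred, "pred"); assert_mask(gold, "gold")
  assert_same_shape(pred, gold, "pred and gold")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(pred), ncol(pred))
  assert_mask(fov, "fov")
  assert_same_shape(pred, fov, "pred and fov")
  if (!any(fov)) validation_error("FOV is empty")
  p <- pred[fov]; g <- gold[fov]
  tp <- sum(p & g); fp <- sum(p & !g); tn <- sum(!p & !g); fn <- sum(!p & g)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                 fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
                 acc = (tp + tn) / (tp + fp + tn + fn)),
            class = "eval_metrics")
}

#' Percentage improvement of a metric over a literature value
#'
#' `100 * (m_our - m_lit) / m_lit`.
#'
#' @param m_our Our metric value.
#' @param m_lit Literature metric value (nonzero).
#' @return Improvement in percent.
#' @export
improvement <- function(m_our, m_lit) {
  if (any(m_lit == 0)) validation_error("literature metric must be nonzero")
  100 * (m_our - m_lit) / m_lit
}

#' Tri-colour overlay of a prediction against a gold mask
#'
#' Blue = overlap (`pred & gold`), yellow = false positives
#' (`pred & !gold`), green = false negatives (`!pred & gold`), black
#' elsewhere.
#'
#' @param pred,gold Logical masks.
#' @return A `fundus_image` whose channels encode the overlay.
#' @export
overlay_masks <- function(pred, gold) {
  assert_mask(pred, "pred"); assert_mask(gold, "gold")
  assert_same_shape(pred, gold, "pred and gold")
  h <- nrow(pred); w <- ncol(pred)
  px <- array(0, c(h, w, 3))
  both <- pred & gold; fp <- pred & !gold; fn <- !pred & gold
  px[, , 1][fp] <- 1                           # yellow = R + G
  px[, , 2][fp] <- 1
  px[, , 2][fn] <- 1                           # green
  px[, , 3][both] <- 1                         # blue
  fundus_image(px, source_path = "<overlay>")
}

#' Close ground-truth edge points into a solid segment mask
#'
#' Renders the points onto a blank grid and closes with a square
#' structuring element of side `s`; if the result has more 8-connected
#' components than vessels declared, `s` is increased by 1 (up to `cap`)
#' until each vessel forms a single component.
#'
#' @param edge_points Data.frame or matrix with columns `x, y` (at least 2
#'   points).
#' @param s Initial element side (default 3).
#' @param size Output grid size `c(H, W)`; default fits the points.
#' @param n_vessels Number of vessel segments the points describe
#'   (default 1).
#' @param cap Maximum element side (default 15).
#' @return Logical mask with attributes `s` (final element side) and
#'   `unconnected` (TRUE when the cap was reached before connecting).
#' @export
close_gt_edges <- function(edge_points, s = 3, size = NULL, n_vessels = 1, cap = 15) {
  pts <- as.matrix(edge_points[, 1:2])
  if (nrow(pts) < 2) validation_error("need at least 2 edge points")
  if (s < 1) validation_error("s must be >= 1")
  if (is.null(size)) size <- c(max(round(pts[, 2])) + 5, max(round(pts[, 1])) + 5)
  h <- size[1]; w <- size[2]
  base <- matrix(FALSE, h, w)
  xi <- pmin(pmax(round(pts[, 1]), 1), w)
  yi <- pmin(pmax(round(pts[, 2]), 1), h)
  base[cbind(yi, xi)] <- TRUE
  repeat {
    closed <- close_binary(base, matrix(1, s, s))
    ncomp <- max(label8(closed))
    # segments must be solid: a pair of parallel edge chains closed with a
    # too-small element leaves a hollow core (still one component)
    solid <- !any(xor(mat_from_eb(EBImage::fillHull(eb_from_mat(closed * 1))) > 0.5,
                      closed))
    if ((ncomp <= n_vessels && solid) || s >= cap) break
    s <- s + 1
  }
  attr(closed, "s") <- s
  attr(closed, "unconnected") <- ncomp > n_vessels
  closed
}

#' Width-measurement evaluation against edge-point ground truth
#'
#' Implements the edge-point validation protocol: ground-truth edge-point
#' pairs are closed into segments; a ground-truth centre location counts as
#' a success when its nearest predicted centre lies within the local true
#' width and inside the closed ground-truth segment.  The mean width is the
#' foreground pixel count of the closed predicted-edge segment divided by
#' the pixel count of its thinned centreline.  The error standard deviation
#' is computed from the per-cross-section error-pixel counts along the
#' straight lines joining each ground-truth edge-point pair:
#' `sqrt(sum(e_l^2) / n_lines)`.
#'
#' @param pred_records Width records from [profile_vessel()].
#' @param gt_pairs Data.frame with columns `x1, y1, x2, y2`: ground-truth
#'   edge-point pairs (one cross-section each).
#' @param size Grid size `c(H, W)` for rendering.
#' @param n_vessels Vessel count for the closing escalation.
#' @return A `width_eval` list: `success_pct`, `mean_width`, `error_std`,
#'   `n_locations`, `s_gt`, `s_pred`.
#' @export
width_protocol <- function(pred_records, gt_pairs, size, n_vessels = 1) {
  if (nrow(pred_records) == 0 || nrow(gt_pairs) == 0)
    validation_error("pred_records and gt_pairs must be nonempty")
  gcx <- (gt_pairs$x1 + gt_pairs$x2) / 2
  gcy <- (gt_pairs$y1 + gt_pairs$y2) / 2
  gw <- sqrt((gt_pairs$x1 - gt_pairs$x2)^2 + (gt_pairs$y1 - gt_pairs$y2)^2) + 1

  gt_pts <- rbind(cbind(gt_pairs$x1, gt_pairs$y1), cbind(gt_pairs$x2, gt_pairs$y2))
  gt_mask <- close_gt_edges(gt_pts, size = size, n_vessels = n_vessels)
  pred_pts <- rbind(cbind(pred_records$edge_ax, pred_records$edge_ay),
                    cbind(pred_records$edge_bx, pred_records$edge_by))
  pred_mask <- close_gt_edges(pred_pts, size = size, n_vessels = n_vessels)

  # association: nearest predicted centre per ground-truth location
  # (nearest-first, smallest index on ties)
  ok <- logical(length(gcx))
  for (i in seq_along(gcx)) {
    d <- sqrt((pred_records$x - gcx[i])^2 + (pred_records$y - gcy[i])^2)
    j <- which.min(d)
    px <- pred_records$x[j]; py <- pred_records$y[j]
    inside <- gt_mask[pmin(pmax(round(py), 1), nrow(gt_mask)),
                      pmin(pmax(round(px), 1), ncol(gt_mask))]
    ok[i] <- d[j] <= gw[i] && inside
  }
  success_pct <- 100 * mean(ok)
  if (!any(ok)) {
    return(structure(list(success_pct = 0, mean_width = NA_real_,
                          error_std = NA_real_, n_locations = length(gcx),
                          s_gt = attr(gt_mask, "s"), s_pred = attr(pred_mask, "s")),
                     class = "width_eval"))
  }

  cl <- centreline(pred_mask)
  mean_width <- sum(pred_mask) / max(1L, sum(cl))

  err <- xor(pred_mask, gt_mask)
  e <- numeric(nrow(gt_pairs))
  for (i in seq_len(nrow(gt_pairs))) {
    # the cross-section line goes *through* the pair, extended by half the
    # pair distance on each side, so that a prediction wider than the
    # ground truth still intersects it
    ddx <- (gt_pairs$x2[i] - gt_pairs$x1[i]) / 2
    ddy <- (gt_pairs$y2[i] - gt_pairs$y1[i]) / 2
    ln <- raster_line(round(gt_pairs$x1[i] - ddx), round(gt_pairs$y1[i] - ddy),
                      round(gt_pairs$x2[i] + ddx), round(gt_pairs$y2[i] + ddy))
    ln[, 1] <- pmin(pmax(ln[, 1], 1), ncol(err))
    ln[, 2] <- pmin(pmax(ln[, 2], 1), nrow(err))
    e[i] <- sum(err[cbind(ln[, 2], ln[, 1])])
  }
  error_std <- sqrt(sum(e^2) / length(e))
  structure(list(success_pct = success_pct, mean_width = mean_width,
                 error_std = error_std, n_locations = length(gcx),
                 s_gt = attr(gt_mask, "s"), s_pred = attr(pred_mask, "s")),
            class = "width_eval")
}
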