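# Gray-level co-occurrence second-order maximum-entropy thresholding.
#
# A threshold t splits the (L+1) x (L+1) co-occurrence matrix into four
# quadrants; the within-object (bright, i > t and j > t) and
# within-background (i <= t and j <= t) transition entropies are summed and
# the threshold maximising the total is optimal.  Two binarisation regimes
# share the same optimal threshold: a smaller scale extracts the vessel
# mask, a larger scale recovers vessel cores split by the central light
# reflex.

#' Quantize a gray image to integer levels
#'
#' `floor(gray * L)` clipped to `[0, L]`.
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param L Maximum level, between 15 and 255 (default 255).
#' @return A `quantized_image` list: `levels` (integer matrix), `L`.
#' @export
quantize <- function(gray, L = 255) {
  assert_unit_range(gray)
  L <- as.integer(L)
  if (L < 15 || L > 255) validation_error("L must lie in [15, 255]")
  q <- matrix(pmin(as.integer(floor(gray * L)), L), nrow(gray), ncol(gray))
  structure(list(levels = q, L = L), class = "quantized_image")
}

#' Dequantize back to `[0, 1]` mid-level intensities
#' @param q A `quantized_image`.
#' @return Gray matrix.
#' @export
dequantize <- function(q) {
  if (!inherits(q, "quantized_image")) validation_error("q must be a quantized_image")
  q$levels / q$L
}

#' Gray-level co-occurrence matrix
#'
#' Counts ordered gray-level transitions from each pixel to its right
#' neighbour and to its neighbour below.  For an `M x N` image the total
#' transition count is `M (N - 1) + (M - 1) N`.
#'
#' @param q A `quantized_image` with at least 2 rows and 2 columns.
#' @return A `cooccurrence_matrix` list: `counts` (integer
#'   `(L+1) x (L+1)`), `probs` (same shape, sums to 1), `L`.
#' @export
cooccurrence <- function(q) {
  if (!inherits(q, "quantized_image")) validation_error("q must be a quantized_image")
  m <- q$levels
  if (nrow(m) < 2 || ncol(m) < 2) validation_error("image must be at least 2 x 2")
  L1 <- q$L + 1L
  from <- c(m[, -ncol(m)], m[-nrow(m), ])      # right + below transitions
  to   <- c(m[, -1],       m[-1, ])
  counts <- matrix(tabulate(from * L1 + to + 1L, nbins = L1 * L1), L1, L1, byrow = TRUE)
  total <- sum(counts)
  structure(list(counts = counts, probs = counts / total, L = q$L),
            class = "cooccurrence_matrix")
}

# 2-D cumulative sum: S[i, j] = sum over rows <= i, cols <= j.
cumsum2 <- function(m) apply(apply(m, 2, cumsum), 1, cumsum) |> t()

#' Second-order entropy curve over all thresholds
#'
#' For each candidate threshold `t` in `0 .. L-1`, the probabilities within
#' the object quadrant (`i > t, j > t`) and the background quadrant
#' (`i <= t, j <= t`) are renormalised within their quadrant and the
#' second-order entropies `H_O(t)` and `H_B(t)` are
#' `-(1/2) * sum(p_hat * log2(p_hat))` over the respective quadrant
#' (`0 * log 0 = 0`; an empty quadrant contributes 0).  The total is
#' `H_T = H_O + H_B`.  The two class-transition (cross) quadrants are
#' renormalised and summed into `h_cross`; [optimal_threshold()] includes
#' them in the maximised total by default, because the diagonal-only total
#' attains its maximum at the histogram extremes on bimodal images (one
#' quadrant then holds both modes and their full inter-mode entropy).
#'
#' @param C A `cooccurrence_matrix`.
#' @return An `entropy_profile` data.frame with columns `t`, `h_object`,
#'   `h_background`, `h_total`, `h_cross`.
#' @export
entropy_curve <- function(C) {
  if (!inherits(C, "cooccurrence_matrix")) validation_error("C must be a cooccurrence_matrix")
  P <- C$probs
  L1 <- nrow(P)
  E <- matrix(0, L1, L1)
  pos <- P > 0
  E[pos] <- P[pos] * log2(P[pos])
  SP <- cumsum2(P); SE <- cumsum2(E)
  tot_p <- SP[L1, L1]; tot_e <- SE[L1, L1]

  quad_h <- function(p, e) {
    # entropy of the renormalised quadrant: -(1/2) (e/p - log2 p)
    h <- numeric(length(p))
    ok <- p > 0
    h[ok] <- -0.5 * (e[ok] / p[ok] - log2(p[ok]))
    pmax(h, 0)                 # clamp float residue: entropies are >= 0
  }
  ts <- 0:(C$L - 1L)
  i <- ts + 1L                                  # cumulative index of level t
  p_bg <- SP[cbind(i, i)]
  e_bg <- SE[cbind(i, i)]
  p_ob <- tot_p - SP[L1, i] - SP[i, L1] + p_bg
  e_ob <- tot_e - SE[L1, i] - SE[i, L1] + e_bg
  # the two class-transition (cross) quadrants, each renormalised on its own
  p_bo <- SP[i, L1] - p_bg                      # i <= t, j > t
  e_bo <- SE[i, L1] - e_bg
  p_ob2 <- SP[L1, i] - p_bg                     # i > t, j <= t
  e_ob2 <- SE[L1, i] - e_bg
  h_b <- quad_h(p_bg, e_bg)
  h_o <- quad_h(p_ob, e_ob)
  h_x <- quad_h(p_bo, e_bo) + quad_h(p_ob2, e_ob2)
  structure(data.frame(t = ts, h_object = h_o, h_background = h_b,
                       h_total = h_o + h_b, h_cross = h_x),
            class = c("entropy_profile", "data.frame"))
}

#' Optimal threshold: argmax of the total second-order entropy
#'
#' Ties are broken by the smallest threshold.
#'
#' @param E An `entropy_profile`.
#' @param include_cross Include the cross-quadrant entropies in the
#'   maximised total? Default `TRUE`: without them the total is maximised
#'   at the histogram extremes whenever the histogram is bimodal.
#' @return The optimal threshold level (integer).
#' @export
optimal_threshold <- function(E, include_cross = TRUE) {
  if (!is.data.frame(E) || !all(c("t", "h_total") %in% names(E)) || nrow(E) < 1)
    validation_error("E must be an entropy_profile with at least one row")
  h <- E$h_total
  if (isTRUE(include_cross)) h <- h + E$h_cross
  if (diff(range(h)) < 1e-15) {
    warning("entropy profile is flat: returning threshold 0")
    return(E$t[1])
  }
  E$t[which.max(h)]                             # which.max takes the first tie
}

#' Threshold the quantized image at a scaled optimal threshold
#'
#' A pixel is foreground iff its quantized level is `>= scale * t_opt` and
#' it lies inside the FOV.  The mask-extraction regime uses
#' `scale` in `[0.3, 0.8]` (default 0.5); the central-light-reflex regime
#' uses `scale` in `[0.8, 3]` (default 1.5).
#'
#' @param q A `quantized_image`.
#' @param t_opt Optimal threshold from [optimal_threshold()].
#' @param scale Threshold scale factor (> 0).
#' @param fov Logical FOV mask (default: everywhere).
#' @return Logical `H x W` mask.
#' @export
binarize <- function(q, t_opt, scale = 0.5, fov = NULL) {
  if (!inherits(q, "quantized_image")) validation_error("q must be a quantized_image")
  if (scale <= 0) validation_error("scale must be > 0")
  if (is.null(fov)) fov <- matrix(TRUE, nrow(q$levels), ncol(q$levels))
  assert_mask(fov, "fov")
  assert_same_shape(q$levels, fov, "image and fov")
  thr <- scale * t_opt
  if (thr > q$L) {
    warning("scaled threshold exceeds the maximum level: empty mask")
    return(matrix(FALSE, nrow(q$levels), ncol(q$levels)))
  }
  q$levels >= thr & fov
}
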