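# Internal helpers shared across modules.
#
# Image convention: a gray image is a plain numeric H x W matrix with
# rows = y (increasing downward) and columns = x.  EBImage stores images
# transposed (first dimension = x), so every call into EBImage goes through
# eb_from_mat() / mat_from_eb().

retseg_error <- function(msg, class) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

validation_error <- function(msg) retseg_error(msg, "retseg_validation_error")
io_error <- function(msg) retseg_error(msg, "retseg_io_error")

assert_gray <- function(gray, name = "gray") {
  if (!is.matrix(gray) || !is.numeric(gray))
    validation_error(sprintf("%s must be a numeric matrix", name))
  if (any(!is.finite(gray)))
    validation_error(sprintf("%s contains non-finite values", name))
  invisible(gray)
}

assert_unit_range <- function(gray, name = "gray") {
  assert_gray(gray, name)
  if (min(gray) < -1e-9 || max(gray) > 1 + 1e-9)
    validation_error(sprintf("%s must lie in [0, 1]", name))
  invisible(gray)
}

assert_mask <- function(mask, name = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    validation_error(sprintf("%s must be a logical matrix", name))
  invisible(mask)
}

assert_same_shape <- function(a, b, what = "inputs") {
  if (!identical(dim(a)[1:2], dim(b)[1:2]))
    validation_error(sprintf("%s must have matching shapes", what))
  invisible(NULL)
}

eb_from_mat <- function(m) EBImage::Image(t(m))

mat_from_eb <- function(img) t(EBImage::imageData(img))

#' @noRd
disk_brush <- function(radius) {
  size <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# Morphological closing / opening of a numeric matrix with a brush.
close_gray <- function(m, brush) {
  lo <- min(m); hi <- max(m)
  if (hi <= lo) return(m)                     # constant: closing is identity
  sc <- (m - lo) / (hi - lo)                  # EBImage morphology wants [0,1]
  out <- mat_from_eb(EBImage::closing(eb_from_mat(sc), brush))
  out * (hi - lo) + lo
}

# Binary morphology via explicit shifts (safe for arbitrary small
# structuring elements, including line kernels).
se_offsets <- function(se) {
  cy <- (nrow(se) + 1) %/% 2; cx <- (ncol(se) + 1) %/% 2
  w <- which(se > 0, arr.ind = TRUE)
  cbind(dy = w[, 1] - cy, dx = w[, 2] - cx)
}

dilate_binary <- function(mask, se) {
  offs <- se_offsets(se)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out | shift_mat(mask, offs[i, 1], offs[i, 2], fill = FALSE)
  out
}

erode_binary <- function(mask, se) {
  offs <- se_offsets(se)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(offs)))
    out <- out & shift_mat(mask, -offs[i, 1], -offs[i, 2], fill = TRUE)
  out
}

close_binary <- function(mask, se) {
  erode_binary(dilate_binary(mask, se), se)
}

# 2-D correlation with replicated borders (EBImage filter2 is FFT-based).
# Kernels larger than the image are cropped centrally to fit.
filter_same <- function(m, kernel) {
  kd <- dim(kernel); md <- dim(m)
  if (any(kd > md)) {
    keep <- function(k, n) {
      c <- (k + 1) %/% 2
      r <- min((n - 1) %/% 2, (k - 1) %/% 2)
      (c - r):(c + r)
    }
    kernel <- kernel[keep(kd[1], md[1]), keep(kd[2], md[2]), drop = FALSE]
  }
  mat_from_eb(EBImage::filter2(eb_from_mat(m), t(kernel), boundary = "replicate"))
}

# Shift a matrix by (dy, dx), padding with `fill`.
shift_mat <- function(m, dy, dx, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  ys <- max(1, 1 + dy):min(h, h + dy)
  xs <- max(1, 1 + dx):min(w, w + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# 8-connected component labelling: EBImage::bwlabel() is 4-connected, so
# labels touching diagonally are merged with a union-find pass.
label8 <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- mat_from_eb(EBImage::bwlabel(eb_from_mat(mask * 1)))
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (off in list(c(1L, 1L), c(1L, -1L))) {
    sh <- shift_mat(lab, off[1], off[2], fill = 0L)
    sel <- lab > 0L & sh > 0L & lab != sh
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], sh[sel]))
      for (r in seq_len(nrow(pairs))) union2(pairs[r, 1], pairs[r, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

# Rasterize a straight segment between two pixel coordinates (x, y),
# stepping one pixel along the dominant axis (Bresenham-style).
raster_line <- function(x1, y1, x2, y2) {
  n <- max(abs(x2 - x1), abs(y2 - y1))
  if (n == 0) return(cbind(x = x1, y = y1))
  t <- 0:n / n
  cbind(x = round(x1 + t * (x2 - x1)), y = round(y1 + t * (y2 - y1)))
}

rescale01 <- function(m) {
  hi <- max(m)
  if (hi > 0) m / hi else m
}

# Otsu threshold of a numeric vector (256-bin histogram); used where the
# threshold must be computed over a pixel subset (e.g. inside the FOV).
otsu_values <- function(v) {
  v <- v[is.finite(v)]
  if (!length(v) || diff(range(v)) < 1e-12) return(Inf)
  lo <- min(v); hi <- max(v)
  b <- pmin(as.integer((v - lo) / (hi - lo) * 255), 255L)
  h <- tabulate(b + 1L, nbins = 256L)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mt <- mu[256]
  sb <- (mt * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  t <- which.max(sb) - 1L
  lo + (t + 0.5) / 255 * (hi - lo)
}
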