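#' Read a colour fundus photograph
#'
#' Reads a raster image (TIFF, PNG or JPEG) and returns a 3-channel colour
#' fundus image with intensities in `[0, 1]`.  Single-channel inputs are
#' replicated across the three channels; integer bit depths are rescaled by
#' their maximum representable value (this is what the underlying readers
#' do for 8- and 16-bit rasters).
#'
#' @param path Path to the image file.
#' @return An object of class `fundus_image`: a list with `pixels`
#'   (an `H x W x 3` array, rows = y, columns = x) and `source_path`.
#' @export
read_fundus <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path))
    io_error(sprintf("cannot read image: '%s'", path))
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) io_error(sprintf("cannot decode image '%s': %s",
                                                       path, conditionMessage(e))))
  px <- EBImage::imageData(img)
  if (length(dim(px)) == 2) px <- array(px, c(dim(px), 1L))
  if (dim(px)[3] == 1L) px <- px[, , c(1L, 1L, 1L), drop = FALSE]
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  px <- aperm(px, c(2, 1, 3))                  # EBImage is x-major
  fundus_image(px, source_path = path)
}

#' Construct a colour fundus image from an array
#'
#' @param pixels `H x W x 3` numeric array with values in `[0, 1]`.
#' @param source_path Optional provenance string.
#' @return A `fundus_image` object.
#' @export
fundus_image <- function(pixels, source_path = "<in-memory>") {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    validation_error("pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 32 || d[2] < 32)
    validation_error("fundus images must be at least 32 x 32 pixels")
  if (any(!is.finite(pixels)) || min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    validation_error("pixel values must be finite and within [0, 1]")
  structure(list(pixels = pixels, source_path = source_path),
            class = "fundus_image")
}

#' Write a colour fundus image or gray image to disk
#'
#' @param img A `fundus_image`, a gray matrix, or a logical mask.
#' @param path Output path; format chosen by extension (.png/.tif/.tiff/.jpg).
#' @return `path`, invisibly.
#' @export
write_fundus <- function(img, path) {
  px <- if (inherits(img, "fundus_image")) aperm(img$pixels, c(2, 1, 3))
        else if (is.logical(img)) t(img * 1)
        else t(img)
  ext <- tolower(tools::file_ext(path))
  type <- switch(ext, png = "png", tif = , tiff = "tiff", jpg = , jpeg = "jpeg",
                 io_error(sprintf("unsupported image extension: '%s'", path)))
  EBImage::writeImage(EBImage::Image(px,
                        colormode = if (length(dim(px)) == 3) "Color" else "Grayscale"),
                      path, type = type)
  invisible(path)
}

#' Extract the green channel
#'
#' The green channel of a fundus photograph exhibits the best contrast
#' between vessels and background and is used as the analysis channel.
#'
#' @param img A `fundus_image`.
#' @return A gray `H x W` matrix in `[0, 1]`.
#' @export
extract_green <- function(img) {
  if (!inherits(img, "fundus_image")) validation_error("img must be a fundus_image")
  img$pixels[, , 2]
}

#' Luminance (gray level) of a colour fundus image
#'
#' Alternative analysis channel for the reflex-recovery binarisation.
#'
#' @param img A `fundus_image`.
#' @return A gray `H x W` matrix in `[0, 1]`.
#' @export
extract_luma <- function(img) {
  if (!inherits(img, "fundus_image")) validation_error("img must be a fundus_image")
  0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] + 0.114 * img$pixels[, , 3]
}

#' Top-hat contrast preprocessing
#'
#' Black top-hat transform (morphological closing minus the image) with a
#' disk structuring element.  Vessels are dark in the green channel, so the
#' black top-hat renders them bright on a dark background, the polarity the
#' downstream ridge enhancement and entropy binarisation assume.  The
#' result is rescaled to `[0, 1]` by its maximum.
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param radius Disk radius in pixels, between 10 and 60 (default 30).
#'   May also be a vector of radii, in which case the pixelwise maximum of
#'   the individual top-hats is returned.
#' @return Gray matrix in `[0, 1]` with vessels bright.
#' @export
tophat_preprocess <- function(gray, radius = 30) {
  assert_unit_range(gray)
  if (any(radius < 10 | radius > 60))
    validation_error("tophat radius must lie in [10, 60]")
  if (any(radius > min(dim(gray)) / 2))
    validation_error("tophat radius exceeds half the image size")
  th <- matrix(0, nrow(gray), ncol(gray))
  for (r in radius) {
    bt <- close_gray(gray, disk_brush(r)) - gray
    th <- pmax(th, bt)
  }
  th[th < 0] <- 0
  rescale01(th)
}

#' Compute the field-of-view mask
#'
#' Sobel gradient magnitude is thresholded (Otsu by default), closed
#' successively with 12 line structuring elements of length 3 at angles
#' `k * 15` degrees, and hole-filled; the largest filled component is the
#' field of view (FOV).
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param sobel_threshold `"auto"` (Otsu on the gradient magnitude) or a
#'   numeric threshold on the `[0, 1]`-normalised gradient.
#' @return Logical `H x W` matrix, `TRUE` inside the FOV.
#' @export
compute_fov_mask <- function(gray, sobel_threshold = "auto") {
  assert_unit_range(gray)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- filter_same(gray, kx)
  gy <- filter_same(gray, t(kx))
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) <= 1e-12) {
    warning("blank image: returning all-true FOV mask")
    return(matrix(TRUE, nrow(gray), ncol(gray)))
  }
  mag <- mag / max(mag)
  thr <- if (identical(sobel_threshold, "auto"))
    EBImage::otsu(eb_from_mat(mag)) else as.numeric(sobel_threshold)
  edges <- mag >= thr
  for (k in 0:11) {                     # length-3 line elements, 12 angles
    th <- k * 15 * pi / 180
    dx <- round(cos(th)); dy <- round(sin(th))
    se <- matrix(0, 3, 3); se[2, 2] <- 1
    se[2 + dy, 2 + dx] <- 1; se[2 - dy, 2 - dx] <- 1
    edges <- close_binary(edges, se)
  }
  filled <- mat_from_eb(EBImage::fillHull(eb_from_mat(edges * 1))) > 0.5
  lab <- label8(filled)
  if (max(lab) == 0) {
    warning("no FOV component found: returning all-true mask")
    return(matrix(TRUE, nrow(gray), ncol(gray)))
  }
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}
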