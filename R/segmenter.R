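# Pipeline orchestration: steps 1-5 of the segmentation flow, routed by
# image class.
#
#   step 1  texture partition (fine/coarse map)
#   step 2  top-hat -> Hessian ridge enhancement -> entropy mask ->
#           multiplication -> global threshold
#   step 3  texture-adaptive connectivity filtering
#   step 4  reflex-regime entropy binarisation (larger threshold)
#   step 5  fusion: OR with the reflex segmentation + radius-2 disk closing,
#           final FOV clip
#
# Class routing: class1 -> steps {2,5}; class2 -> {2,3,5};
# class3 -> {1,2,3,4,5}.

#' Multiply the enhanced image with the entropy mask
#'
#' @param vessel A `vesselness_image`.
#' @param mask Logical entropy mask.
#' @return Gray matrix (elementwise product).
#' @export
combine_enhanced_mask <- function(vessel, mask) {
  if (!inherits(vessel, "vesselness_image"))
    validation_error("vessel must be a vesselness_image")
  assert_mask(mask)
  assert_same_shape(vessel$pixels, mask, "vesselness and mask")
  vessel$pixels * mask
}

#' Global intensity threshold on the combined image
#'
#' @param img Gray matrix.
#' @param t Threshold in `[0.04, 0.2]` (default 0.1); pixels strictly above
#'   `t` are foreground.
#' @return Logical mask.
#' @export
global_threshold <- function(img, t = 0.1) {
  assert_gray(img, "img")
  if (t < 0.04 || t > 0.2)
    validation_error("global threshold must lie in [0.04, 0.2]")
  img > t
}

#' Texture-adaptive connectivity filtering
#'
#' Each 8-connected component of the mask is assigned to the texture label
#' covering the majority of its pixels; components whose pixel count is not
#' larger than that label's connectivity threshold are removed.  Without a
#' partition (classes 1-2) the single global threshold `min_fine` applies.
#'
#' @param mask Logical mask.
#' @param partition A `texture_partition` or `NULL`.
#' @param min_fine,min_coarse Connectivity thresholds in pixels,
#'   `5 <= min_fine <= min_coarse <= 16` (defaults 5 and 16).
#' @return Logical mask (subset of the input).
#' @export
connectivity_filter <- function(mask, partition = NULL, min_fine = 5, min_coarse = 16) {
  assert_mask(mask)
  if (min_fine < 5 || min_coarse > 16 || min_fine > min_coarse)
    validation_error("need 5 <= min_fine <= min_coarse <= 16")
  lab <- label8(mask)
  n <- max(lab)
  if (n == 0) return(mask)
  sizes <- tabulate(lab[lab > 0], nbins = n)
  if (is.null(partition)) {
    thr <- rep(min_fine, n)
  } else {
    if (!inherits(partition, "texture_partition"))
      validation_error("partition must be a texture_partition")
    assert_same_shape(mask, partition$labels, "mask and partition")
    plab <- partition$labels
    fine_cnt <- tabulate(lab[lab > 0 & plab == 1L], nbins = n)
    coarse_cnt <- tabulate(lab[lab > 0 & plab == 2L], nbins = n)
    thr <- ifelse(fine_cnt >= coarse_cnt, min_fine, min_coarse)
  }
  keep <- sizes > thr
  mask & matrix(c(FALSE, keep)[lab + 1L], nrow(mask), ncol(mask))
}

#' Recover vessels split by the central light reflex
#'
#' Class 1: morphological closing of the curvature segmentation with a
#' radius-2 disk.  Classes 2-3: pixelwise OR of the curvature and
#' reflex-regime segmentations, then one radius-2 disk closing.  The result
#' always contains the curvature input.
#'
#' @param curv_seg Logical curvature-based segmentation.
#' @param reflex_seg Logical reflex-regime segmentation (ignored for
#'   class 1; may be `NULL`).
#' @param image_class `"class1"`, `"class2"` or `"class3"`.
#' @return Logical mask.
#' @export
recover_central_reflex <- function(curv_seg, reflex_seg = NULL,
                                   image_class = "class3") {
  assert_mask(curv_seg, "curv_seg")
  image_class <- match.arg(image_class, c("class1", "class2", "class3"))
  comb <- if (image_class == "class1" || is.null(reflex_seg)) curv_seg
          else { assert_same_shape(curv_seg, reflex_seg); curv_seg | reflex_seg }
  close_binary(comb, disk_brush(2)) | curv_seg
}

#' Segment the retinal vasculature of a fundus image
#'
#' Runs the steps of the class routing (Table-style: class1 = 2+5,
#' class2 = 2+3+5, class3 = 1-5) and returns the final mask with
#' provenance.
#'
#' @param color A `fundus_image`.
#' @param params A resolved configuration from [load_config()] (defaults
#'   when omitted).
#' @param image_class `"class1"`, `"class2"` or `"class3"` (manual
#'   assignment, as in routine screening practice).
#' @return A `retseg_segmentation` list: `mask`, `steps_applied`, `params`,
#'   `fov`, `partition` (or `NULL`), `t_opt`, `vesselness`.
#' @export
segment_retina <- function(color, params = load_config(), image_class = "class3") {
  if (!inherits(color, "fundus_image")) validation_error("color must be a fundus_image")
  image_class <- match.arg(image_class, c("class1", "class2", "class3"))
  p <- params
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  gray <- stage("green", extract_green(color))
  fov <- stage("fov", compute_fov_mask(gray, p[["fov.sobel_threshold"]]))
  tophat <- stage("tophat", tophat_preprocess(gray, p[["preprocess.tophat_radius"]]))

  steps <- switch(image_class, class1 = c(2L, 5L), class2 = c(2L, 3L, 5L),
                  class3 = 1:5)

  partition <- NULL
  if (1L %in% steps)
    partition <- stage("texture_partition",
      partition_texture(tophat, fov,
                        levels = p[["texture.levels"]], k = p[["texture.k"]],
                        hminima = p[["texture.hminima"]],
                        hminima_radius = p[["texture.hminima_radius"]],
                        median_size = p[["texture.median_size"]],
                        pool_sigma = p[["texture.pool_sigma"]],
                        min_fine = p[["segment.min_fine"]],
                        min_coarse = p[["segment.min_coarse"]],
                        override = p[["texture.override"]]))

  # step 2: ridge enhancement x entropy mask, global threshold
  eig <- stage("hessian", hessian_eigen(tophat, p[["enhance.sigma"]]))
  ves <- stage("vesselness", vesselness(eig, p[["enhance.beta"]], p[["enhance.c"]]))
  q <- stage("quantize", quantize(tophat, p[["entropy.L"]]))
  prof <- stage("entropy", entropy_curve(cooccurrence(q)))
  t_opt <- stage("entropy", optimal_threshold(prof))
  mask_e <- stage("entropy_mask", binarize(q, t_opt, p[["entropy.mask_scale"]], fov))
  comb <- stage("combine", combine_enhanced_mask(ves, mask_e))
  curv_seg <- stage("global_threshold",
                    global_threshold(comb, p[["segment.global_threshold"]]))

  if (3L %in% steps)
    curv_seg <- stage("connectivity_filter",
      connectivity_filter(curv_seg, partition,
                          p[["segment.min_fine"]], p[["segment.min_coarse"]]))

  reflex_seg <- NULL
  want_reflex <- 4L %in% steps ||
    (image_class == "class2" && isTRUE(p[["segment.class2_reflex"]]))
  if (want_reflex) {
    src <- if (identical(p[["entropy.reflex_channel"]], "luma"))
      tophat_preprocess(extract_luma(color), p[["preprocess.tophat_radius"]])
    else tophat
    qr <- quantize(src, p[["entropy.L"]])
    reflex_seg <- stage("reflex_binarize",
                        binarize(qr, t_opt, p[["entropy.reflex_scale"]], fov))
    # clean the reflex segmentation with the coarse connectivity constraint
    # before fusing, so it cannot reintroduce small noise blobs
    reflex_seg <- connectivity_filter(reflex_seg, NULL,
                                      min_fine = p[["segment.min_coarse"]],
                                      min_coarse = p[["segment.min_coarse"]])
  }

  final <- stage("reflex_recovery",
                 recover_central_reflex(curv_seg, reflex_seg, image_class))
  final <- final & fov

  structure(list(mask = final, steps_applied = steps, params = p,
                 fov = fov, partition = partition, t_opt = t_opt,
                 vesselness = ves),
            class = "retseg_segmentation")
}
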