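# Single-scale Hessian eigenvalue ridge enhancement.
#
# Vessels appear as ridges in the top-hat preprocessed image; the local
# second-order structure at each pixel is captured by the 2x2 Hessian of
# Gaussian derivatives at a single scale sigma, and the Frangi vesselness
# response built from its eigenvalues enhances elongated bright structures
# while suppressing blobs and flat background.

gauss_deriv_kernels <- function(sigma) {
  r <- max(2L, as.integer(ceiling(4 * sigma)))
  x <- -r:r
  g <- exp(-x^2 / (2 * sigma^2)); g <- g / sum(g)
  g1 <- -x / sigma^2 * g
  g2 <- (x^2 - sigma^2) / sigma^4 * g
  # renormalise the sampled kernels so the discrete operators are exact on
  # quadratics: sum(g2) = 0, sum(x^2 g2) = 2, sum(x g1) = -1
  g2 <- g2 - mean(g2)
  g2 <- g2 * 2 / sum(x^2 * g2)
  g1 <- g1 / abs(sum(x * g1))
  list(g = g, g1 = g1, g2 = g2)
}

#' Hessian eigen-decomposition at a single scale
#'
#' Gaussian-derivative Hessian (`Ixx`, `Ixy`, `Iyy`) at scale `sigma`,
#' gamma-normalised by `sigma^2`, with the closed-form eigendecomposition
#' of the symmetric 2x2 matrix at every pixel.  Eigenvalues are ordered by
#' magnitude, `|lambda1| <= |lambda2|`; `v1` is the unit eigenvector of the
#' smaller-magnitude eigenvalue and points along the local ridge.
#'
#' @param gray Gray matrix in `[0, 1]`.
#' @param sigma Gaussian scale in pixels, `>= 0.5` (default 1.5).
#' @return An `eigen_field` list: `lambda1`, `lambda2` (matrices),
#'   `v1x`, `v1y` (unit eigenvector components), `sigma`.
#' @export
hessian_eigen <- function(gray, sigma = 1.5) {
  assert_gray(gray)
  if (sigma < 0.5) validation_error("sigma must be >= 0.5")
  k <- gauss_deriv_kernels(sigma)
  # separable convolutions: rows = y, cols = x
  hxx <- filter_same(gray, outer(k$g, k$g2))   # d2/dx2
  hyy <- filter_same(gray, outer(k$g2, k$g))   # d2/dy2
  hxy <- filter_same(gray, outer(k$g1, k$g1))  # d2/dxdy
  s2 <- sigma^2
  hxx <- s2 * hxx; hyy <- s2 * hyy; hxy <- s2 * hxy

  tr <- (hxx + hyy) / 2
  disc <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
  mu_hi <- tr + disc
  mu_lo <- tr - disc
  swap <- abs(mu_hi) >= abs(mu_lo)             # pick smaller |.| as lambda1
  lambda1 <- ifelse(swap, mu_lo, mu_hi)
  lambda2 <- ifelse(swap, mu_hi, mu_lo)

  # eigenvector for lambda1: (hxy, lambda1 - hxx), fallback to axis vectors
  vx <- hxy
  vy <- lambda1 - hxx
  degen <- abs(vx) < 1e-12 & abs(vy) < 1e-12
  # hxy ~ 0: Hessian already diagonal; eigenvector is a coordinate axis
  vx[degen] <- ifelse(abs(hxx - lambda1)[degen] <= abs(hyy - lambda1)[degen], 1, 0)
  vy[degen] <- 1 - vx[degen]
  nrm <- sqrt(vx^2 + vy^2)
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 v1x = vx / nrm, v1y = vy / nrm, sigma = sigma),
            class = "eigen_field")
}

#' Frangi vesselness response (single scale, 2-D)
#'
#' `exp(-Rb^2 / 2 beta^2) * (1 - exp(-S^2 / 2 c^2))` with
#' `Rb = lambda1 / lambda2` (blobness) and `S = sqrt(lambda1^2 + lambda2^2)`
#' (second-order structure strength), set to 0 where `lambda2 >= 0`
#' (vessels are bright on a dark background after the top-hat, so ridge
#' pixels have strongly negative `lambda2`).  The response is rescaled to
#' `[0, 1]` by its maximum.
#'
#' @param eig An `eigen_field` from [hessian_eigen()].
#' @param beta Blobness sensitivity (default 0.5).
#' @param c Structure-strength scale, or `"auto"` = half the maximum
#'   Frobenius norm of the Hessian over the image.
#' @return A `vesselness_image` list: `pixels` in `[0, 1]`, `beta`, `c`.
#' @export
vesselness <- function(eig, beta = 0.5, c = "auto") {
  if (!inherits(eig, "eigen_field")) validation_error("eig must be an eigen_field")
  if (beta <= 0) validation_error("beta must be > 0")
  S <- sqrt(eig$lambda1^2 + eig$lambda2^2)
  if (identical(c, "auto")) c <- max(S) / 2
  if (!is.numeric(c) || c <= 0) {
    # flat image: S is 0 everywhere, response is 0 regardless of c
    return(structure(list(pixels = matrix(0, nrow(S), ncol(S)),
                          beta = beta, c = NA_real_),
                     class = "vesselness_image"))
  }
  rb <- ifelse(abs(eig$lambda2) > 1e-12, eig$lambda1 / eig$lambda2, 0)
  resp <- exp(-rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * c^2)))
  resp[eig$lambda2 >= 0] <- 0
  structure(list(pixels = rescale01(resp), beta = beta, c = c),
            class = "vesselness_image")
}
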