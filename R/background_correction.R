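# Stage 2: removal of the non-uniform haze of large cleared spherical
# samples before segmentation. Two families: Gaussian high-pass (subtract a
# blurred copy) and sliding-paraboloid opening (grayscale morphology).

#' Gaussian blur with replicated borders
#'
#' @param plane Numeric matrix.
#' @param sigma_px Gaussian sigma in pixels (> 0).
#' @return Blurred matrix of the same size.
#' @export
gaussian_blur <- function(plane, sigma_px) {
  stopifnot(sigma_px > 0)
  size <- 2L * ceiling(3 * sigma_px) + 1L
  size <- min(size, 2L * (min(dim(plane)) %/% 2L) - 1L)
  if (size < 3L) return(plane)
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma_px)
  out <- EBImage::imageData(EBImage::filter2(plane, brush, boundary = "replicate"))
  dim(out) <- dim(plane)
  out
}

#' Blur-subtraction background correction
#'
#' `max(0, raw - gaussian_blur(raw, sigma))`: the blurred copy estimates the
#' slowly varying haze; the clipped difference keeps features smaller than
#' the blur scale. A constant image maps to zeros.
#'
#' @param plane Numeric matrix (one confocal plane).
#' @param blur_sigma_px Blur sigma in pixels (> 0).
#' @return Corrected matrix, >= 0 everywhere.
#' @export
subtract_blur <- function(plane, blur_sigma_px) {
  out <- plane - gaussian_blur(plane, blur_sigma_px)
  out[out < 0] <- 0
  out
}

#' Gaussian high-pass with per-channel widths
#'
#' Identical contract to [subtract_blur()]; named for the workflow step in
#' which channel-specific smoothing widths are subtracted from the raw
#' images to isolate cells from background (soma-scale channels commonly
#' use a 10 px width and finer filamentous channels 5 px).
#'
#' @param plane Numeric matrix.
#' @param width_px Gaussian width (sigma) in pixels.
#' @return Corrected matrix, >= 0.
#' @export
gaussian_highpass <- function(plane, width_px) {
  subtract_blur(plane, width_px)
}

#' Parabolic grayscale erosion / dilation / opening
#'
#' Morphology with the paraboloid structuring function `-kappa * |u|^2`
#' (height profile `kappa * r^2`): erosion is
#' `min_u f(x + u) + kappa |u|^2`, dilation its max-plus adjoint, opening
#' the composition dilation(erosion(f)). Computed separably (1-D min-plus
#' lower-envelope transforms per axis) in O(n) per pixel row/column, which
#' is exactly the 2-D operation because the paraboloid is additively
#' separable across axes.
#'
#' @param mat Numeric matrix.
#' @param kappa Paraboloid curvature in abu per squared pixel (> 0).
#' @return Matrix of the same size.
#' @export
parabolic_erode <- function(mat, kappa) {
  stopifnot(is.matrix(mat), kappa > 0)
  .cpp_parabolic_erode(mat, kappa)
}

#' @rdname parabolic_erode
#' @export
parabolic_dilate <- function(mat, kappa) {
  -parabolic_erode(-mat, kappa)
}

#' @rdname parabolic_erode
#' @export
parabolic_opening <- function(mat, kappa) {
  parabolic_dilate(parabolic_erode(mat, kappa), kappa)
}

#' Sliding-parabola background correction
#'
#' Slides a paraboloid under the intensity surface: the background is the
#' grayscale opening of the plane with a paraboloid structuring element of
#' height profile `kappa * r^2`, and the output is `raw - background`. The
#' opening is anti-extensive, so the output is >= 0 and <= raw pointwise;
#' structures narrower than the paraboloid (nuclei) survive while wide
#' domes (haze) are removed.
#'
#' The `curvature` setting follows high-content-screening convention as a
#' dimensionless dial; it maps to `kappa = curvature / 1000` abu/px². The
#' mapping is this package's own definition: numeric equivalence with any
#' proprietary screening software is not claimed, only the role of the step
#' (local contrast enhancement preserving sub-nuclear-scale features).
#' `kappa` can be given directly to bypass the mapping.
#'
#' @param plane Numeric matrix (one confocal plane).
#' @param curvature Curvature setting (> 0); typical values are 2 for
#'   nuclear-marker channels and 10 for dim filamentous/apoptosis channels.
#' @param kappa Optional direct curvature in abu/px²; overrides `curvature`.
#' @return Corrected matrix: `plane - opening(plane)`, >= 0.
#' @export
sliding_parabola <- function(plane, curvature = 2, kappa = NULL) {
  if (is.null(kappa)) {
    stopifnot(curvature > 0)
    kappa <- curvature / 1000
  }
  stopifnot(kappa > 0)
  bg <- parabolic_opening(plane, kappa)
  out <- plane - bg
  out[out < 0] <- 0
  out
}

#' Apply a configured background-correction method to a plane
#'
#' Dispatch helper used by the quantification pipeline; `method` selects
#' [sliding_parabola()] (`"parabola"`), [subtract_blur()] (`"blur"`) or
#' [gaussian_highpass()] (`"highpass"`), or `"none"` for identity.
#'
#' @param plane Numeric matrix.
#' @param method One of `"parabola"`, `"blur"`, `"highpass"`, `"none"`.
#' @param curvature Curvature for the parabola method.
#' @param width_px Sigma/width for the blur and highpass methods.
#' @return Corrected matrix.
#' @export
background_correct <- function(plane,
                               method = c("parabola", "blur", "highpass", "none"),
                               curvature = 2, width_px = 5) {
  method <- match.arg(method)
  switch(method,
         parabola = sliding_parabola(plane, curvature = curvature),
         blur = subtract_blur(plane, width_px),
         highpass = gaussian_highpass(plane, width_px),
         none = plane)
}
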