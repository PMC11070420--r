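#' Segmentation parameters
#'
#' Defaults target capillary-scale vessels at 5.7 um/pixel: Frangi scales
#' sigma in {1, 1.5, 2} px cover vessels roughly 1-2 px wide, beta = 0.5 and
#' gamma = 15 are the classic sensitivity constants (gamma on a 0-255
#' intensity footing), and the hysteresis thresholds act on the vesselness
#' response normalised to \[0, 1\].
#'
#' @param frangi_scales Ascending positive Gaussian scales (pixels).
#' @param frangi_beta Blob-suppression constant.
#' @param frangi_gamma Structure-suppression constant (on 0-255 intensities).
#' @param hyst_low,hyst_high Hysteresis thresholds on normalised vesselness,
#'   `0 <= low < high <= 1`.
#' @param morph_close_radius_px Radius of the binary-closing structuring
#'   element used to bridge small gaps.
#' @param min_hole_px Background components (4-connected holes fully
#'   enclosed by vessel) smaller than this many pixels are filled.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(frangi_scales = c(1, 1.5, 2),
                                frangi_beta = 0.5,
                                frangi_gamma = 15,
                                hyst_low = 0.05,
                                hyst_high = 0.15,
                                morph_close_radius_px = 1,
                                min_hole_px = 9) {
  stopifnot(
    length(frangi_scales) >= 1, all(frangi_scales > 0),
    !is.unsorted(frangi_scales),
    frangi_beta > 0, frangi_gamma > 0,
    hyst_low >= 0, hyst_high <= 1, hyst_low < hyst_high,
    morph_close_radius_px >= 0, min_hole_px >= 0
  )
  structure(list(
    frangi_scales = frangi_scales,
    frangi_beta = frangi_beta,
    frangi_gamma = frangi_gamma,
    hyst_low = hyst_low,
    hyst_high = hyst_high,
    morph_close_radius_px = morph_close_radius_px,
    min_hole_px = min_hole_px
  ), class = "segmentation_params")
}

# Gaussian second-derivative kernels sampled on an odd grid of radius
# ceiling(3.5 sigma); used to build the scale-space Hessian.
gaussian_hessian_kernels <- function(sigma) {
  rad <- max(2L, as.integer(ceiling(3.5 * sigma)))
  x <- matrix(rep(-rad:rad, each = 2 * rad + 1), 2 * rad + 1)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  xx <- g * (x^2 - sigma^2) / sigma^4
  yy <- g * (y^2 - sigma^2) / sigma^4
  # truncation leaves a tiny DC component; remove it so flat regions give
  # an exactly zero Hessian (xy is antisymmetric, already zero-sum)
  list(
    xx = xx - mean(xx),
    yy = yy - mean(yy),
    xy = g * x * y / sigma^4,
    radius = rad
  )
}

#' Frangi vesselness filter
#'
#' Hessian-eigenvalue tubularity response for bright curvilinear structures,
#' taken as the per-pixel maximum over scales and normalised to \[0, 1\].
#' At each scale sigma the image is convolved with Gaussian second-derivative
#' kernels, the Hessian is scale-normalised (multiplied by sigma^2), and with
#' eigenvalues `|l1| <= |l2|` the response is
#' `exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-(l1^2 + l2^2) / (2 gamma^2)))`
#' where `l2 < 0` (bright ridge) and 0 elsewhere.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param params A [segmentation_params()] object.
#' @return Numeric matrix in \[0, 1\], same shape as `image`.
#' @export
frangi_vesselness <- function(image, params = segmentation_params()) {
  check_image(image)
  stopifnot(inherits(params, "segmentation_params"))
  img <- clamp01(image) * 255  # gamma's conventional 8-bit footing
  best <- matrix(0, nrow(image), ncol(image))
  for (sigma in params$frangi_scales) {
    k <- gaussian_hessian_kernels(sigma)
    if (2 * k$radius + 1 > min(dim(image)))
      stop("image smaller than the kernel support of scale ", sigma,
           call. = FALSE)
    hxx <- EBImage::filter2(img, k$xx, boundary = "replicate") * sigma^2
    hyy <- EBImage::filter2(img, k$yy, boundary = "replicate") * sigma^2
    hxy <- EBImage::filter2(img, k$xy, boundary = "replicate") * sigma^2
    half_tr <- (hxx + hyy) / 2
    root <- sqrt(((hxx - hyy) / 2)^2 + hxy^2)
    ea <- half_tr + root
    eb <- half_tr - root
    swap <- abs(ea) > abs(eb)
    l1 <- ifelse(swap, eb, ea)  # |l1| <= |l2|
    l2 <- ifelse(swap, ea, eb)
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    s2 <- l1^2 + l2^2
    v <- exp(-rb2 / (2 * params$frangi_beta^2)) *
      (1 - exp(-s2 / (2 * params$frangi_gamma^2)))
    v[l2 >= 0] <- 0
    best <- pmax(best, v)
  }
  # absolute floor before per-image normalisation: FFT round-off on flat
  # images is ~1e-30 while real vessel responses are O(0.1) on this footing
  m <- max(best)
  if (m > 1e-8) best <- best / m else best[] <- 0
  dim(best) <- dim(image)
  attributes(best)$pixel_pitch_um <- attr(image, "pixel_pitch_um")
  best
}

#' Hysteresis thresholding
#'
#' Keeps pixels at or above `high`, plus pixels at or above `low` that are
#' 8-connected to one, so faint vessel stretches survive only when anchored
#' to a confident response.
#'
#' @param vesselness Numeric matrix (typically in \[0, 1\]).
#' @param low,high Thresholds with `low < high`.
#' @return Logical vessel mask, same shape.
#' @export
hysteresis_threshold <- function(vesselness, low, high) {
  if (!is.matrix(vesselness) || !is.numeric(vesselness))
    stop("vesselness must be a numeric matrix", call. = FALSE)
  if (low >= high) stop("low threshold must be below high", call. = FALSE)
  weak <- vesselness >= low
  lab <- .cc_label(weak, 8L)
  strong_labels <- unique(lab[vesselness >= high])
  strong_labels <- strong_labels[strong_labels > 0]
  out <- matrix(lab %in% strong_labels, nrow(vesselness), ncol(vesselness))
  attributes(out)$pixel_pitch_um <- attr(vesselness, "pixel_pitch_um")
  out
}

#' Morphological cleanup of a vessel mask
#'
#' Binary closing (radius `morph_close_radius_px`) bridges small gaps, then
#' enclosed background holes (4-connected components not touching the image
#' border) smaller than `min_hole_px` pixels are filled. The output always
#' contains the input (the operation is extensive). Radius-1 closing uses
#' the 3x3 square, the discrete unit disc of the Chebyshev metric, so 1-px
#' gaps are bridged in any direction; larger radii use a Euclidean disc.
#'
#' @param mask Logical vessel mask.
#' @param params A [segmentation_params()] object.
#' @return Cleaned logical mask.
#' @export
morphological_cleanup <- function(mask, params = segmentation_params()) {
  mask <- as_binary_mask(mask)
  out <- mask
  r <- params$morph_close_radius_px
  if (r >= 1 && any(mask)) {
    brush <- if (r == 1) matrix(1, 3, 3) else EBImage::makeBrush(2 * r + 1, "disc")
    closed <- EBImage::imageData(EBImage::closing(
      EBImage::Image(mask * 1), brush)) > 0.5
    out <- out | closed
  }
  if (params$min_hole_px > 0 && any(out) && !all(out)) {
    holes <- .cc_label(!out, 4L)
    border <- unique(c(holes[1, ], holes[nrow(out), ],
                       holes[, 1], holes[, ncol(out)]))
    sizes <- tabulate(holes)
    fill <- which(sizes < params$min_hole_px)
    fill <- setdiff(fill, border)
    if (length(fill)) out[holes %in% fill] <- TRUE
  }
  attributes(out)$pixel_pitch_um <- attr(mask, "pixel_pitch_um")
  out
}

#' Segment vessels in a preprocessed en face image
#'
#' Composition of [frangi_vesselness()], [hysteresis_threshold()] and
#' [morphological_cleanup()]; fully deterministic.
#'
#' @param image Numeric matrix in \[0, 1\] (preprocessed).
#' @param params A [segmentation_params()] object.
#' @return Logical vessel mask, same shape as `image`.
#' @export
#' @examples
#' p <- synth_params(image_size = 128, noise_level = 0, seed = 3)
#' r <- render_image(generate_vessel_graph(p), p)
#' mask <- segment_vessels(r$image)
#' mean(mask)  # vessel density of the segmentation
segment_vessels <- function(image, params = segmentation_params()) {
  v <- frangi_vesselness(image, params)
  m <- hysteresis_threshold(v, params$hyst_low, params$hyst_high)
  morphological_cleanup(m, params)
}
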