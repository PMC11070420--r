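#' Match an image's histogram to a reference image
#'
#' Monotone intensity remapping: each pixel is replaced by the reference
#' quantile at its own empirical CDF value, so the output's intensity
#' distribution approximates the reference's while spatial structure is
#' untouched (the mapping is a per-pixel function of intensity only). This
#' compensates for illumination differences between acquisitions so that one
#' set of segmentation hyperparameters fits different scans.
#'
#' @param image Numeric matrix of intensities.
#' @param reference Numeric matrix whose intensity distribution is the
#'   target; typically a good-quality scan, see [reference_image()].
#' @return Matrix of the same shape as `image` with remapped intensities.
#'   A constant-valued input has a degenerate CDF and is returned unchanged
#'   with a warning.
#' @export
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' ref <- matrix(rbeta(256, 2, 5), 16, 16)
#' out <- match_histogram(img, ref)
#' range(out)
match_histogram <- function(image, reference) {
  check_image(image)
  check_image(reference)
  if (length(image) == 0 || length(reference) == 0)
    stop("images must be non-empty", call. = FALSE)
  if (diff(range(image)) == 0) {
    warning("constant-valued input: histogram matching skipped")
    return(image)
  }
  probs <- ecdf(image)(image)
  out <- quantile(reference, probs = probs, type = 1, names = FALSE)
  dim(out) <- dim(image)
  attributes(out)$pixel_pitch_um <- attr(image, "pixel_pitch_um")
  out
}

#' Contrast-limited adaptive histogram equalisation (CLAHE)
#'
#' Tile-wise histogram equalisation with clipping, used to boost local
#' vessel contrast before vesselness filtering. `clip_limit` follows the
#' fraction-of-tile-histogram convention: the per-bin histogram count is
#' clipped at `clip_limit` times the tile pixel count (so with 256 bins the
#' default 0.01 corresponds to ~2.6x the uniform bin height).
#'
#' @param image Numeric matrix with intensities in \[0, 1\].
#' @param clip_limit Positive clipping fraction; larger means more contrast.
#' @param tile_grid Integer vector of length 1 or 2: number of tiles per
#'   image side.
#' @return Equalised matrix, same shape, values in \[0, 1\]. Constant input
#'   is returned unchanged (there is no contrast to enhance).
#' @export
clahe_enhance <- function(image, clip_limit = 0.01, tile_grid = c(8, 8)) {
  check_image(image)
  if (clip_limit <= 0) stop("clip_limit must be positive", call. = FALSE)
  tile_grid <- rep(as.integer(tile_grid), length.out = 2)
  if (any(tile_grid < 1)) stop("tile_grid must be >= 1", call. = FALSE)
  if (diff(range(image)) == 0) return(image)
  bins <- 256L
  out <- EBImage::imageData(EBImage::clahe(
    EBImage::Image(clamp01(image)),
    nx = tile_grid[1], ny = tile_grid[2],
    bins = bins, limit = clip_limit * bins, keep.range = FALSE
  ))
  out <- clamp01(out)
  dim(out) <- dim(image)
  attributes(out)$pixel_pitch_um <- attr(image, "pixel_pitch_um")
  out
}

# Cache for the canonical synthetic reference image.
.octaperf_cache <- new.env(parent = emptyenv())

#' Canonical reference image for histogram matching
#'
#' The package ships no clinical data, so the role of the "good-quality
#' reference scan" is played by a canonical synthetic image: a fixed-seed,
#' zero-dropout capillary network rendered at the default parameters. Any
#' user-supplied image can be used instead wherever a reference is accepted.
#'
#' @param params Generator parameters; only the defaults are cached.
#' @return Numeric matrix in \[0, 1\].
#' @export
reference_image <- function(params = synth_params(seed = 101L,
                                                  dropout_prob = 0)) {
  key <- paste0("ref_", rlang::hash(unclass(params)))
  if (!is.null(.octaperf_cache[[key]])) return(.octaperf_cache[[key]])
  g <- generate_vessel_graph(params)
  img <- render_image(g, params)$image
  .octaperf_cache[[key]] <- img
  img
}

#' Preprocess an en face image (histogram matching then CLAHE)
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param reference Reference image for histogram matching; defaults to the
#'   canonical synthetic reference.
#' @param clip_limit,tile_grid CLAHE parameters, see [clahe_enhance()].
#' @return Preprocessed matrix, same shape as `image`.
#' @export
preprocess_image <- function(image, reference = reference_image(),
                             clip_limit = 0.01, tile_grid = c(8, 8)) {
  matched <- match_histogram(image, reference)
  clahe_enhance(matched, clip_limit = clip_limit, tile_grid = tile_grid)
}
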