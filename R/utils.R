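# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every generator a pure function of
# (seed, parameters) without clobbering the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Pixel pitch attached to a matrix, falling back to the package default
# (5.7 um/pixel, the lateral sampling of 15 x 15 degree macular scans on a
# 512-pixel grid).
px_pitch <- function(x, default = 5.7) {
  p <- attr(x, "pixel_pitch_um", exact = TRUE)
  if (is.null(p)) default else p
}

set_pitch <- function(x, pitch) {
  attr(x, "pixel_pitch_um") <- pitch
  x
}

as_binary_mask <- function(mask) {
  if (is.logical(mask)) {
    m <- mask
  } else if (is.numeric(mask)) {
    m <- mask > 0.5
    attributes(m) <- attributes(mask)[c("dim", "pixel_pitch_um")]
  } else stop("mask must be a logical or numeric matrix", call. = FALSE)
  if (!is.matrix(m)) stop("mask must be a matrix", call. = FALSE)
  if (anyNA(m)) stop("mask contains missing values", call. = FALSE)
  m
}

check_image <- function(image) {
  if (!is.matrix(image) || !is.numeric(image))
    stop("image must be a numeric matrix", call. = FALSE)
  if (!all(is.finite(image)) || any(image < 0))
    stop("image intensities must be finite and non-negative", call. = FALSE)
  invisible(image)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)
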