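#' Two-chamber robustness fixture
#'
#' A deterministic toy mask illustrating why deficit areas computed from the
#' perfusion-distance map are robust where raw intercapillary areas are
#' not: a rectangular frame of vessel encloses two chambers separated by a
#' vertical vessel wall. With `gap = TRUE` a single wall pixel is removed,
#' emulating a small segmentation error. The two intercapillary areas then
#' merge into one of roughly double the area, while the perfusion-distance
#' values barely move (only pixels near the gap see a shorter distance).
#'
#' @param size Side length in pixels (default 41).
#' @param gap If `TRUE`, open a 1-pixel hole in the separating wall.
#' @return Logical vessel mask.
#' @export
#' @examples
#' intact <- fixture_two_chamber()
#' broken <- fixture_two_chamber(gap = TRUE)
#' n_regions(intercapillary_areas(intact))
#' n_regions(intercapillary_areas(broken))
fixture_two_chamber <- function(size = 41, gap = FALSE) {
  stopifnot(size >= 9, size %% 2 == 1)
  m <- matrix(FALSE, size, size)
  m[1, ] <- TRUE; m[size, ] <- TRUE
  m[, 1] <- TRUE; m[, size] <- TRUE
  mid <- (size + 1) %/% 2
  m[, mid] <- TRUE
  if (gap) m[mid, mid] <- FALSE
  set_pitch(m, 5.7)
}

#' Toy grid masks used in examples and tests
#'
#' `fixture_cross()`: a 5x5 mask whose middle row and column are vessel,
#' splitting the background into four 2x2 corners. `fixture_ring()`: a
#' one-pixel vessel ring enclosing an `inner x inner` cavity.
#'
#' @return Logical mask.
#' @export
fixture_cross <- function() {
  m <- matrix(FALSE, 5, 5)
  m[3, ] <- TRUE
  m[, 3] <- TRUE
  m
}

#' @rdname fixture_cross
#' @param inner Cavity side length (default 11).
#' @export
fixture_ring <- function(inner = 11) {
  n <- inner + 2
  m <- matrix(TRUE, n, n)
  m[2:(n - 1), 2:(n - 1)] <- FALSE
  m
}
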