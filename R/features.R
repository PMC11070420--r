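#' Vessel density
#'
#' Fraction of image pixels classified as vessel: the classic OCTA perfusion
#' biomarker.
#'
#' @param mask Logical vessel mask.
#' @return Scalar in \[0, 1\].
#' @export
vessel_density <- function(mask) {
  mask <- as_binary_mask(mask)
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  mean(mask)
}

# Internal constructor for labelled region sets.
new_region_set <- function(labels, connectivity) {
  areas <- tabulate(labels, nbins = max(labels, 0L))
  structure(list(labels = labels, areas = as.integer(areas),
                 connectivity = as.integer(connectivity)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %d regions (%d-connectivity), %d labelled pixels\n",
              length(x$areas), x$connectivity, sum(x$areas)))
  invisible(x)
}

#' Number of regions in a region set
#' @param regions A `region_set`.
#' @return Integer count.
#' @export
n_regions <- function(regions) length(regions$areas)

#' Tidy a region set into a tibble of per-region areas
#'
#' @param x A `region_set`.
#' @param pixel_pitch_um Pixel pitch used for the `area_um2` column.
#' @param ... Unused.
#' @return A tibble with columns `region`, `area_px`, `area_um2`.
#' @export
tidy.region_set <- function(x, pixel_pitch_um = 5.7, ...) {
  tibble::tibble(
    region = seq_along(x$areas),
    area_px = x$areas,
    area_um2 = x$areas * pixel_pitch_um^2
  )
}

# Drop regions whose pixels touch the image border (optional policy).
drop_border_regions <- function(rs) {
  lb <- rs$labels
  border <- unique(c(lb[1, ], lb[nrow(lb), ], lb[, 1], lb[, ncol(lb)]))
  border <- border[border > 0]
  if (length(border)) {
    lb[lb %in% border] <- 0L
    keep <- sort(unique(lb[lb > 0]))
    lb[] <- match(lb, keep, nomatch = 0L)
  }
  new_region_set(lb, rs$connectivity)
}

#' Intercapillary (non-perfused) areas
#'
#' Inverts the vessel mask and labels connected components of the non-vessel
#' pixels; each component is one intercapillary area. Sensitive to
#' segmentation gaps by construction, which is exactly the weakness the
#' perfusion-deficit features are designed to avoid.
#'
#' @param mask Logical vessel mask.
#' @param connectivity 4 or 8 (default 8: dark lacunae are treated as
#'   diagonally continuous).
#' @param exclude_border Drop regions touching the image border.
#' @return A `region_set`.
#' @export
#' @examples
#' m <- matrix(FALSE, 5, 5); m[3, ] <- TRUE; m[, 3] <- TRUE
#' intercapillary_areas(m)$areas
intercapillary_areas <- function(mask, connectivity = 8,
                                 exclude_border = FALSE) {
  mask <- as_binary_mask(mask)
  if (length(mask) == 0) stop("empty mask", call. = FALSE)
  if (!any(mask))
    message("mask has no vessel pixels: whole image is one region")
  rs <- new_region_set(.cc_label(!mask, as.integer(connectivity)),
                       connectivity)
  if (exclude_border) rs <- drop_border_regions(rs) else rs
}

#' Perfusion-distance map
#'
#' Exact Euclidean distance transform of the vessel segmentation: each pixel
#' carries the distance (in pixels) to its nearest vessel pixel, zero exactly
#' on vessels. Distances change only slightly when small gaps open in the
#' segmentation, which makes everything derived from this map robust to
#' segmentation errors.
#'
#' @param mask Logical vessel mask with at least one vessel pixel.
#' @return Numeric matrix of distances (pixels), carrying the mask's
#'   `pixel_pitch_um` attribute.
#' @export
perfusion_distance_map <- function(mask) {
  mask <- as_binary_mask(mask)
  if (!any(mask)) stop("no vessel pixels; distance undefined", call. = FALSE)
  d <- EBImage::imageData(EBImage::distmap(
    EBImage::Image(1 - (mask * 1)), metric = "euclidean"))
  dim(d) <- dim(mask)
  set_pitch(d, px_pitch(mask))
}

#' Distribution summary features (maximum, mean, std, kurtosis)
#'
#' The four summary statistics used for every feature family that describes
#' a distribution. Conventions, fixed for reproducibility: population
#' (biased) moments for the standard deviation, Fisher excess kurtosis
#' (`m4 / m2^2 - 3`, normal = 0). Degenerate inputs (no values, or a single
#' value, or zero variance) yield 0 for the undefined statistics, with a
#' warning, so downstream feature vectors stay finite.
#'
#' @param values Numeric vector (region areas, distances, ...).
#' @return One-row tibble with columns `maximum`, `mean`,
#'   `standard_deviation`, `kurtosis`.
#' @export
#' @examples
#' distribution_features(c(1, 2, 3, 4))
distribution_features <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0) {
    warning("no values: distribution features set to 0")
    return(tibble::tibble(maximum = 0, mean = 0,
                          standard_deviation = 0, kurtosis = 0))
  }
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (length(values) == 1 || m2 == 0) {
    if (length(values) == 1)
      warning("single value: standard deviation and kurtosis set to 0")
    return(tibble::tibble(maximum = max(values), mean = m,
                          standard_deviation = 0, kurtosis = 0))
  }
  m4 <- mean((values - m)^4)
  tibble::tibble(maximum = max(values), mean = m,
                 standard_deviation = sqrt(m2),
                 kurtosis = m4 / m2^2 - 3)
}

#' Perfusion-distance features
#'
#' Distribution features of the perfusion distances, computed over the
#' non-vessel pixels (distance > 0); the zeros on vessel pixels are not part
#' of the gap-length distribution.
#'
#' @param pd_map A [perfusion_distance_map()].
#' @return One-row tibble (see [distribution_features()]).
#' @export
perfusion_distance_features <- function(pd_map) {
  stopifnot(is.matrix(pd_map), is.numeric(pd_map))
  v <- pd_map[pd_map > 0]
  if (length(v) == 0)
    warning("no non-vessel pixels: perfusion-distance features are 0")
  distribution_features(v)
}

#' Perfusion-deficit areas
#'
#' Binarises the perfusion-distance map by keeping pixels whose distance is
#' strictly greater than `threshold_px` and labels the connected components:
#' each component is one perfusion-deficit area. At threshold 0 this
#' partition coincides with the intercapillary areas.
#'
#' @param pd_map A [perfusion_distance_map()].
#' @param threshold_px Non-negative distance threshold in pixels.
#' @param connectivity 4 or 8 (default 8).
#' @param exclude_border Drop regions touching the image border.
#' @return A `region_set` (possibly with zero regions).
#' @export
perfusion_deficit_areas <- function(pd_map, threshold_px,
                                    connectivity = 8,
                                    exclude_border = FALSE) {
  stopifnot(is.matrix(pd_map), is.numeric(pd_map), threshold_px >= 0)
  rs <- new_region_set(.cc_label(pd_map > threshold_px,
                                 as.integer(connectivity)), connectivity)
  if (exclude_border) drop_border_regions(rs) else rs
}

#' Geometric perfusion deficit percentage (GPDP)
#'
#' Fraction of reference-area pixels whose perfusion distance exceeds the
#' threshold: total deficit area over total reference area, expressed as a
#' fraction in \[0, 1\].
#'
#' @param pd_map A [perfusion_distance_map()].
#' @param threshold_px Non-negative distance threshold in pixels.
#' @param reference_mask Optional logical matrix restricting the reference
#'   area; default is the whole image.
#' @return Scalar fraction in \[0, 1\].
#' @export
gpdp <- function(pd_map, threshold_px, reference_mask = NULL) {
  stopifnot(is.matrix(pd_map), is.numeric(pd_map), threshold_px >= 0)
  if (is.null(reference_mask)) {
    mean(pd_map > threshold_px)
  } else {
    reference_mask <- as_binary_mask(reference_mask)
    if (!any(reference_mask))
      stop("reference area is empty", call. = FALSE)
    mean(pd_map[reference_mask] > threshold_px)
  }
}

#' Deficit-area distribution features
#'
#' Distribution features of the per-region pixel areas of a deficit (or
#' intercapillary) region set: the proposed descriptors of the area
#' probability density function.
#'
#' @param regions A `region_set`.
#' @return One-row tibble (see [distribution_features()]).
#' @export
pda_distribution_features <- function(regions) {
  stopifnot(inherits(regions, "region_set"))
  if (n_regions(regions) == 0)
    warning("no regions: area-distribution features are 0")
  distribution_features(regions$areas)
}

#' Extract all five biomarker families from a vessel mask
#'
#' Computes, from one binary vessel mask, the feature record of each method:
#' `VD` (vessel density, 1 value), `GPDP` (geometric perfusion deficit
#' percentage, 1 value), `IA` (intercapillary-area distribution, 4 values),
#' `PD` (perfusion-distance distribution, 4 values) and `PDA`
#' (perfusion-deficit-area distribution, 4 values).
#'
#' @param mask Logical vessel mask.
#' @param pixel_pitch_um Pixel pitch in um/pixel (defaults to the mask's
#'   attribute, else 5.7).
#' @param threshold_um Distance threshold for PDA/GPDP in micrometres;
#'   converted to pixels via `threshold_um / pixel_pitch_um`. Default 30 um,
#'   a conventional capillary-spacing scale.
#' @param connectivity Region connectivity, 4 or 8.
#' @param exclude_border Drop deficit/intercapillary regions touching the
#'   image border.
#' @param image_id,patient_id,label Identifiers carried into the output.
#' @return A long tibble with one row per (method, feature): columns
#'   `image_id`, `patient_id`, `label`, `method`, `feature`, `value`,
#'   `threshold_px`, `connectivity`.
#' @export
#' @examples
#' m <- matrix(FALSE, 32, 32); m[seq(4, 32, 7), ] <- TRUE; m[, seq(4, 32, 7)] <- TRUE
#' feats <- extract_features(m, image_id = "toy")
#' dplyr::count(feats, method)
extract_features <- function(mask,
                             pixel_pitch_um = px_pitch(mask),
                             threshold_um = 30,
                             connectivity = 8,
                             exclude_border = FALSE,
                             image_id = NA_character_,
                             patient_id = NA_character_,
                             label = NA_character_) {
  mask <- as_binary_mask(mask)
  threshold_px <- threshold_um / pixel_pitch_um
  vd <- vessel_density(mask)
  if (all(mask)) {
    # no non-vessel pixels at all: every distribution method degenerates
    warning("all-vessel mask: distribution features are 0")
    ia_f <- pd_f <- pda_f <- tibble::tibble(
      maximum = 0, mean = 0, standard_deviation = 0, kurtosis = 0)
    gp <- 0
  } else {
    ia <- intercapillary_areas(mask, connectivity, exclude_border)
    ia_f <- pda_distribution_features(ia)
    pdm <- perfusion_distance_map(mask)
    pd_f <- perfusion_distance_features(pdm)
    pda <- perfusion_deficit_areas(pdm, threshold_px, connectivity,
                                   exclude_border)
    pda_f <- pda_distribution_features(pda)
    gp <- gpdp(pdm, threshold_px)
  }
  dist_names <- c("maximum", "mean", "standard_deviation", "kurtosis")
  rec <- function(method, feature, value) {
    tibble::tibble(method = method, feature = feature, value = value)
  }
  out <- dplyr::bind_rows(
    rec("VD", "percentage", vd),
    rec("GPDP", "percentage", gp),
    rec("IA", dist_names, as.numeric(ia_f[1, ])),
    rec("PD", dist_names, as.numeric(pd_f[1, ])),
    rec("PDA", dist_names, as.numeric(pda_f[1, ]))
  )
  tibble::tibble(
    image_id = image_id, patient_id = patient_id, label = label,
    out, threshold_px = threshold_px,
    connectivity = as.integer(connectivity)
  )
}
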