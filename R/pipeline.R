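#' Run the full analysis pipeline on a cohort
#'
#' For every manifest row: read the image, preprocess (histogram matching to
#' the reference, then CLAHE), segment vessels (Frangi + hysteresis +
#' cleanup), and extract all five feature families; then compare the feature
#' families by patient-grouped k-fold SVM cross-validation. Unreadable
#' images are skipped with a warning and reported in the result. The run is
#' deterministic given the configuration seed.
#'
#' @param manifest Cohort manifest (see [read_manifest()]); rows with a
#'   `plexus` column are evaluated per plexus.
#' @param config A [default_config()]-style `pipeline_config`.
#' @param use_truth_masks If `TRUE`, segmentation is bypassed and features
#'   are computed on the masks in the manifest's `mask_path` column.
#' @param reference Reference image for histogram matching; defaults to
#'   `config$preprocess$reference_path` if set, else the canonical synthetic
#'   reference.
#' @param pixel_pitch_um Pixel pitch of the cohort images.
#' @param keep_masks If `TRUE`, the per-image segmentation masks are
#'   returned as well.
#' @return A list of class `octa_pipeline`: `features` (long tibble),
#'   `cv` (an `octa_cv` result), `skipped` (character vector of image ids),
#'   `config_hash`, and optionally `masks`.
#' @export
run_pipeline <- function(manifest, config = default_config(),
                         use_truth_masks = FALSE, reference = NULL,
                         pixel_pitch_um = 5.7, keep_masks = FALSE) {
  manifest <- tibble::as_tibble(manifest)
  if (is.null(reference) && !use_truth_masks) {
    rp <- config$preprocess$reference_path
    reference <- if (!is.null(rp) && nzchar(rp))
      read_image(rp, pixel_pitch_um) else reference_image()
  }
  seg_params <- config_segmentation_params(config)
  feats <- vector("list", nrow(manifest))
  masks <- if (keep_masks) vector("list", nrow(manifest)) else NULL
  skipped <- character()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    mask <- tryCatch({
      if (use_truth_masks) {
        read_mask(row$mask_path, pixel_pitch_um)
      } else {
        img <- read_image(row$image_path, pixel_pitch_um)
        pre <- preprocess_image(img, reference,
                                clip_limit = config$preprocess$clip_limit,
                                tile_grid = config$preprocess$tile_grid)
        segment_vessels(pre, seg_params)
      }
    }, error = function(e) {
      warning("skipping ", row$image_id, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(mask)) {
      skipped <- c(skipped, row$image_id)
      next
    }
    if (keep_masks) masks[[i]] <- mask
    f <- extract_features(
      mask, pixel_pitch_um = pixel_pitch_um,
      threshold_um = config$features$threshold_um,
      connectivity = config$features$connectivity,
      exclude_border = config$features$exclude_border_regions,
      image_id = row$image_id, patient_id = row$patient_id,
      label = row$label
    )
    f$plexus <- row$plexus %||% "Retina"
    feats[[i]] <- f
  }
  features <- dplyr::bind_rows(feats)
  if (nrow(features) == 0)
    stop("no usable images in the cohort", call. = FALSE)
  cv <- cross_validate(features, k = config$classify$k,
                       seed = config$classify$seed)
  out <- list(features = features, cv = cv, skipped = skipped,
              config_hash = config_hash(config))
  if (keep_masks) {
    names(masks) <- manifest$image_id
    out$masks <- masks[!vapply(masks, is.null, logical(1))]
  }
  structure(out, class = "octa_pipeline")
}

#' @export
print.octa_pipeline <- function(x, ...) {
  cat(sprintf("<octa_pipeline> %d eyes, %d skipped, config %s\n",
              length(unique(x$features$image_id)), length(x$skipped),
              x$config_hash))
  print(glance(x$cv))
  invisible(x)
}

#' @export
glance.octa_pipeline <- function(x, ...) glance(x$cv)

#' @export
tidy.octa_pipeline <- function(x, ...) tidy(x$cv)
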