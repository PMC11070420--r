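#' Pipeline configuration
#'
#' Fully materialised nested configuration for the end-to-end pipeline.
#' `load_config()` overlays a YAML file on these defaults (missing keys keep
#' their default), and `save_config()`/`load_config()` round-trip
#' losslessly. [config_hash()] gives a stable digest of the resolved
#' configuration for run logging.
#'
#' @return A nested list of class `pipeline_config` with sections
#'   `preprocess` (`clip_limit`, `tile_grid`, `reference_path`), `segment`
#'   (Frangi/hysteresis/morphology parameters), `features` (`threshold_um`,
#'   `connectivity`, `exclude_border_regions`), `classify` (`k`, `seed`) and
#'   `synth` (generator defaults).
#' @export
default_config <- function() {
  structure(list(
    preprocess = list(
      clip_limit = 0.01,
      tile_grid = c(8L, 8L),
      reference_path = ""  # empty = canonical synthetic reference
    ),
    segment = list(
      frangi_scales = c(1, 1.5, 2),
      frangi_beta = 0.5,
      frangi_gamma = 15,
      hyst_low = 0.05,
      hyst_high = 0.15,
      morph_close_radius_px = 1,
      min_hole_px = 9
    ),
    features = list(
      threshold_um = 30,
      connectivity = 8L,
      exclude_border_regions = FALSE
    ),
    classify = list(
      k = 5L,
      seed = 1L
    ),
    synth = unclass(synth_params())
  ), class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' @rdname default_config
#' @param path YAML file; keys present override the defaults.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- structure(merge_config(unclass(cfg), user),
                     class = "pipeline_config")
  }
  cfg
}

#' @rdname default_config
#' @param config A `pipeline_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname default_config
#' @export
config_hash <- function(config) {
  rlang::hash(unclass(config))
}

config_segmentation_params <- function(config) {
  s <- config$segment
  segmentation_params(
    frangi_scales = s$frangi_scales, frangi_beta = s$frangi_beta,
    frangi_gamma = s$frangi_gamma, hyst_low = s$hyst_low,
    hyst_high = s$hyst_high,
    morph_close_radius_px = s$morph_close_radius_px,
    min_hole_px = s$min_hole_px
  )
}
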