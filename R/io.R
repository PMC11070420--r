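#' Read a grayscale en face image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF into a numeric matrix scaled
#' to \[0, 1\]. Multi-channel files are averaged to grayscale with a warning.
#'
#' @param path File path (`.png`, `.tif`/`.tiff`).
#' @param pixel_pitch_um Pixel pitch attached to the result.
#' @return Numeric matrix in \[0, 1\] with a `pixel_pitch_um` attribute.
#' @export
read_image <- function(path, pixel_pitch_um = 5.7) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", path, call. = FALSE)
  )
  if (length(dim(x)) == 3) {
    warning("multi-channel image averaged to grayscale: ", path)
    x <- apply(x, c(1, 2), mean)
  }
  if (!is.matrix(x) || anyNA(x))
    stop("unsupported bit depth or malformed image: ", path, call. = FALSE)
  set_pitch(x, pixel_pitch_um)
}

#' Write a grayscale image
#'
#' PNG output is 8-bit; for 16-bit output use a `.tif`/`.tiff` path, written
#' with 16 bits per sample.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @param bit_depth 8 or 16 (16 requires a TIFF path).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bit_depth = 8) {
  stopifnot(bit_depth %in% c(8, 16))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    if (bit_depth != 8)
      stop("16-bit output requires a .tif path: ", path, call. = FALSE)
    png::writePNG(clamp01(image), path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(clamp01(image), path, bits.per.sample = bit_depth)
  } else {
    stop("unsupported image format: ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write / read a binary vessel mask as a 0/255 PNG
#'
#' Round-trip exact: `read_mask(write_mask(m, p))` equals `m`.
#'
#' @param mask Logical matrix.
#' @param path File path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   logical matrix.
#' @export
write_mask <- function(mask, path) {
  mask <- as_binary_mask(mask)
  png::writePNG(mask * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @param pixel_pitch_um Pixel pitch attached to the result.
#' @export
read_mask <- function(path, pixel_pitch_um = 5.7) {
  set_pitch(read_image(path, pixel_pitch_um) > 0.5, pixel_pitch_um)
}

#' Read / write a cohort manifest CSV
#'
#' RFC 4180 CSV with header
#' `image_id,patient_id,eye,plexus,label,image_path,mask_path`.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_manifest <- function(path) {
  man <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  required <- c("image_id", "patient_id", "eye", "plexus", "label",
                "image_path")
  missing <- setdiff(required, names(man))
  if (length(missing))
    stop("manifest lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(man$image_id))
    stop("manifest image_id values must be unique", call. = FALSE)
  bad <- setdiff(unique(man$label), c("control", "glaucoma"))
  if (length(bad))
    stop("unknown labels: ", paste(bad, collapse = ", "), call. = FALSE)
  man
}

#' @rdname read_manifest
#' @param manifest Data frame to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' Write a results table as CSV
#'
#' @param table Data frame.
#' @param path Output path.
#' @export
write_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}
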