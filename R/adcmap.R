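#' ADC map and ROI mask containers
#'
#' An `adc_map` wraps a single 2D apparent diffusion coefficient image at one
#' timepoint. Pixel values are in units of 10^-3 mm^2/s, the conventional
#' display scale for rectal ADC maps (typical tumor values lie near 1.0).
#'
#' @param pixels numeric matrix of ADC values (10^-3 mm^2/s); all finite and
#'   non-negative.
#' @param spacing pixel size in mm (scalar, isotropic in-plane).
#' @param patient_id patient identifier.
#' @param timepoint `"pre"` or `"post"` treatment.
#' @return An object of class `adc_map`.
#' @export
adc_map <- function(pixels, spacing = 1, patient_id = NA_character_,
                    timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("`pixels` must be a numeric matrix")
  if (!all(is.finite(pixels)))
    stop("ADC map contains non-finite pixels")
  if (any(pixels < 0))
    stop("ADC map contains negative pixels")
  structure(
    list(pixels = pixels, spacing = spacing,
         patient_id = patient_id, timepoint = timepoint),
    class = "adc_map"
  )
}

#' @param mask logical (or 0/1) matrix marking region-of-interest pixels.
#' @param reader reader identifier for dual-delineation workflows.
#' @param pixel_floor minimum number of foreground pixels a usable ROI must
#'   contain. Below this, histogram statistics are too unstable to report.
#' @rdname adc_map
#' @export
roi_mask <- function(mask, reader = "reader1", pixel_floor = 16) {
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) stop("numeric mask must be 0/1")
    mask <- array(mask == 1, dim = dim(mask))
  }
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix")
  structure(
    list(mask = mask, reader = reader, pixel_floor = pixel_floor),
    class = "roi_mask"
  )
}

#' @export
print.adc_map <- function(x, ...) {
  cat(sprintf("<adc_map> %s/%s  %dx%d px, spacing %.3g mm, range [%.3f, %.3f] x10^-3 mm^2/s\n",
              x$patient_id, x$timepoint, nrow(x$pixels), ncol(x$pixels),
              x$spacing, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %s  %dx%d px, %d foreground\n",
              x$reader, nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

#' Extract ROI pixel values
#'
#' Returns the ADC values at mask-foreground positions in stable row-major
#' order (matching how image toolchains scan pixels), after validating shapes
#' and the pixel floor.
#'
#' @param map an [adc_map].
#' @param mask an [roi_mask] of identical shape.
#' @return Numeric vector of masked ADC values.
#' @export
masked_pixels <- function(map, mask) {
  stopifnot(inherits(map, "adc_map"), inherits(mask, "roi_mask"))
  if (!identical(dim(map$pixels), dim(mask$mask)))
    stop(sprintf("shape mismatch: map %s vs mask %s",
                 paste(dim(map$pixels), collapse = "x"),
                 paste(dim(mask$mask), collapse = "x")))
  n_fg <- sum(mask$mask)
  if (n_fg < mask$pixel_floor)
    stop(sprintf("mask below pixel floor (%d < %d foreground pixels)",
                 n_fg, mask$pixel_floor))
  as.numeric(t(map$pixels)[t(mask$mask)])
}

#' Read and write ADC maps and masks
#'
#' Images travel either as NIfTI (via RNifti) or as 16-bit grayscale PNG with
#' a JSON sidecar holding the pixel spacing (mm) and the intensity scale
#' factor that maps stored integers back to 10^-3 mm^2/s.
#'
#' @param path file path; format chosen by extension (`.nii`/`.nii.gz` or
#'   `.png`).
#' @param map an [adc_map] to write.
#' @name adc_io
NULL

#' @rdname adc_io
#' @export
write_adc_image <- function(map, path) {
  stopifnot(inherits(map, "adc_map"))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::asNifti(map$pixels, pixdim = c(map$spacing, map$spacing))
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.png$", path)) {
    scale <- max(map$pixels)
    if (scale <= 0) scale <- 1
    write_png16(map$pixels / scale, path)
    sidecar <- sub("\\.png$", ".json", path)
    jsonlite::write_json(
      list(spacing_mm = map$spacing, intensity_scale = scale,
           units = "1e-3 mm^2/s"),
      sidecar, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported image format: ", path)
  invisible(path)
}

#' @param patient_id,timepoint metadata attached to the map on read.
#' @rdname adc_io
#' @export
read_adc_image <- function(path, patient_id = NA_character_,
                           timepoint = c("pre", "post")) {
  timepoint <- match.arg(timepoint)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    px <- as.matrix(drop(img[, , drop = FALSE]))
    spacing <- RNifti::pixdim(img)[1]
  } else if (grepl("\\.png$", path)) {
    px <- png::readPNG(path)
    if (length(dim(px)) == 3) px <- px[, , 1]
    sidecar <- sub("\\.png$", ".json", path)
    meta <- jsonlite::read_json(sidecar)
    px <- px * meta$intensity_scale
    spacing <- meta$spacing_mm
  } else stop("unsupported image format: ", path)
  adc_map(px, spacing = spacing, patient_id = patient_id, timepoint = timepoint)
}

#' @param reader,pixel_floor metadata attached to the mask on read.
#' @rdname adc_io
#' @export
write_roi_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- array(as.numeric(mask$mask), dim = dim(mask$mask))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    RNifti::writeNifti(RNifti::asNifti(m), path)
  } else if (grepl("\\.png$", path)) {
    png::writePNG(m, path)
  } else stop("unsupported mask format: ", path)
  invisible(path)
}

#' @rdname adc_io
#' @export
read_roi_mask <- function(path, reader = "reader1", pixel_floor = 16) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    m <- as.matrix(drop(RNifti::readNifti(path)[, , drop = FALSE]))
  } else if (grepl("\\.png$", path)) {
    m <- png::readPNG(path)
    if (length(dim(m)) == 3) m <- m[, , 1]
  } else stop("unsupported mask format: ", path)
  roi_mask(array(m > 0.5, dim = dim(m)), reader = reader,
           pixel_floor = pixel_floor)
}
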